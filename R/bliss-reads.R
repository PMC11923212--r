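# Processing of sBLISS break reads: prefix parsing/demultiplexing,
# mapping-quality filtering, and mismatch-tolerant UMI deduplication.

#' Hamming distance between two equal-length strings
#' @param a,b character scalars of equal length.
#' @return integer number of mismatching positions.
#' @export
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("hamming: unequal lengths")
  sum(ra != rb)
}

#' Parse the sBLISS read prefix (8 nt UMI + 8 nt sample barcode)
#'
#' The first `umi_length` nucleotides are the UMI, the next
#' `barcode_length` the sample barcode, matched to the whitelist
#' allowing at most `max_bc_mismatch` substitutions. The prefix is
#' clipped from the returned sequence.
#'
#' @param read_sequence read sequence (character scalar).
#' @param barcode_whitelist named character vector of barcodes (names =
#'   sample ids; unnamed barcodes are their own ids). Whitelist entries
#'   must be pairwise more than `2 * max_bc_mismatch` apart for matching
#'   to be unambiguous.
#' @param max_bc_mismatch maximum barcode substitutions (default 1).
#' @param umi_length,barcode_length prefix layout in nt.
#' @return list with `umi`, `sample_id`, `clipped_sequence`, or `NULL`
#'   when the observed barcode matches no whitelist entry within
#'   tolerance (read rejected).
#' @section Errors: signals a condition of class `trcmap_short_read`
#'   when the read is shorter than the prefix, and
#'   `trcmap_ambiguous_barcode` when two whitelist entries are tied at
#'   the minimal distance within tolerance.
#' @examples
#' parse_prefix(paste0("AAAACCCC", "GGGGTTTT", "ACGT"),
#'              c(s1 = "GGGGTTTT"))
#' @export
parse_prefix <- function(read_sequence, barcode_whitelist,
                         max_bc_mismatch = 1L,
                         umi_length = 8L, barcode_length = 8L) {
  plen <- umi_length + barcode_length
  if (nchar(read_sequence) < plen)
    stop(structure(class = c("trcmap_short_read", "error", "condition"),
                   list(message = sprintf(
                     "read of length %d shorter than %d nt prefix",
                     nchar(read_sequence), plen), call = sys.call())))
  if (is.null(names(barcode_whitelist)))
    names(barcode_whitelist) <- barcode_whitelist
  umi <- substr(read_sequence, 1L, umi_length)
  bc <- substr(read_sequence, umi_length + 1L, plen)
  d <- vapply(barcode_whitelist, hamming, numeric(1), b = bc)
  dmin <- min(d)
  if (dmin > max_bc_mismatch) return(NULL)
  if (sum(d == dmin) > 1L)
    stop(structure(class = c("trcmap_ambiguous_barcode", "error", "condition"),
                   list(message = sprintf(
                     "barcode %s equidistant from %d whitelist entries",
                     bc, sum(d == dmin)), call = sys.call())))
  list(umi = umi,
       sample_id = names(barcode_whitelist)[which.min(d)],
       clipped_sequence = substr(read_sequence, plen + 1L,
                                 nchar(read_sequence)))
}

#' Demultiplex a vector of prefix-carrying read sequences
#'
#' Vectorized front-end to [parse_prefix()]: short and ambiguous reads
#' are counted as rejected (with a reason) instead of raising.
#'
#' @inheritParams parse_prefix
#' @param read_sequences character vector.
#' @return data frame with one row per read: `umi`, `sample_id`,
#'   `clipped_sequence`, `status` (`"ok"`, `"no_match"`, `"short"`,
#'   `"ambiguous"`).
#' @export
demultiplex_reads <- function(read_sequences, barcode_whitelist,
                              max_bc_mismatch = 1L,
                              umi_length = 8L, barcode_length = 8L) {
  out <- data.frame(umi = NA_character_, sample_id = NA_character_,
                    clipped_sequence = NA_character_, status = "no_match",
                    stringsAsFactors = FALSE)[rep(1, length(read_sequences)), ]
  rownames(out) <- NULL
  for (i in seq_along(read_sequences)) {
    res <- tryCatch(
      parse_prefix(read_sequences[i], barcode_whitelist, max_bc_mismatch,
                   umi_length, barcode_length),
      trcmap_short_read = function(e) "short",
      trcmap_ambiguous_barcode = function(e) "ambiguous")
    if (is.null(res)) next
    if (is.character(res)) { out$status[i] <- res; next }
    out$umi[i] <- res$umi
    out$sample_id[i] <- res$sample_id
    out$clipped_sequence[i] <- res$clipped_sequence
    out$status[i] <- "ok"
  }
  out
}

#' Filter break records by mapping quality
#'
#' Records with mapping quality below `min_mapq` are removed; a MAPQ of
#' exactly `min_mapq` is kept. Input order is preserved.
#'
#' @param records break-record data frame with a `mapq` column.
#' @param min_mapq minimum mapping quality retained (default 30).
#' @return the retained records.
#' @export
filter_mapq <- function(records, min_mapq = 30L) {
  stopifnot("mapq" %in% names(records))
  records[records$mapq >= min_mapq, , drop = FALSE]
}

# Single-linkage clustering of one chromosome's reads: an edge joins two
# reads iff their positions differ by at most pos_window AND their UMIs
# differ by at most max_umi_mismatch. Returns cluster labels (integers).
cluster_chrom <- function(pos, umi_raw, pos_window, max_umi_mismatch) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(pos)
  for (a in seq_len(n)) {
    i <- ord[a]
    b <- a - 1L
    while (b >= 1L && pos[i] - pos[ord[b]] <= pos_window) {
      j <- ord[b]
      if (sum(umi_raw[, i] != umi_raw[, j]) <= max_umi_mismatch) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      b <- b - 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse PCR duplicates into unique DSB events
#'
#' Reads are clustered per chromosome by single linkage, where two reads
#' are linked iff they map at most `pos_window` bp apart and their UMIs
#' differ by at most `max_umi_mismatch` substitutions; linkage is
#' transitive, so chains of adjacent duplicates collapse together. Each
#' cluster contributes one unique event at its representative position
#' (the smallest position in the cluster); events at the same position
#' are aggregated into a per-position UMI count, so the total UMI count
#' equals the number of clusters.
#'
#' @param records break records for one sample (`chrom`, `pos`, `umi`;
#'   `strand` used only when `strand_aware`).
#' @param pos_window maximum genomic distance between duplicate reads
#'   (default 10 bp).
#' @param max_umi_mismatch maximum UMI substitutions between duplicate
#'   reads (default 1).
#' @param strand_aware when TRUE, reads on different strands never
#'   cluster (default FALSE: break ends are strand-agnostic).
#' @return data frame of unique events: `chrom`, `pos`, `umi_count`,
#'   and `sample_id` when present in the input, sorted by chromosome
#'   and position.
#' @export
deduplicate <- function(records, pos_window = 10L, max_umi_mismatch = 1L,
                        strand_aware = FALSE) {
  stopifnot(all(c("chrom", "pos", "umi") %in% names(records)))
  if ("sample_id" %in% names(records) &&
      length(unique(records$sample_id)) > 1)
    stop("deduplicate expects records from a single sample; ",
         "split by sample_id first")
  if (nrow(records) == 0) {
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      umi_count = integer(0))
    if ("sample_id" %in% names(records)) out$sample_id <- character(0)
    return(out)
  }
  groups <- if (strand_aware) paste(records$chrom, records$strand)
            else records$chrom
  res <- list()
  for (g in unique(groups)) {
    sel <- which(groups == g)
    sub <- records[sel, , drop = FALSE]
    umi_raw <- vapply(sub$umi, charToRaw, raw(nchar(sub$umi[1])))
    lab <- cluster_chrom(sub$pos, umi_raw, pos_window, max_umi_mismatch)
    rep_pos <- tapply(sub$pos, lab, min)
    tab <- table(rep_pos)
    res[[g]] <- data.frame(chrom = sub$chrom[1],
                           pos = as.numeric(names(tab)),
                           umi_count = as.integer(tab))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if ("sample_id" %in% names(records))
    out$sample_id <- records$sample_id[1]
  out
}

#' Deduplicate a multi-sample break table
#'
#' Applies [filter_mapq()] then [deduplicate()] per sample.
#'
#' @inheritParams deduplicate
#' @param records break records with a `sample_id` column.
#' @param min_mapq minimum mapping quality (default 30); `NULL` skips
#'   the filter.
#' @return named list of per-sample unique-event data frames.
#' @export
deduplicate_samples <- function(records, pos_window = 10L,
                                max_umi_mismatch = 1L, min_mapq = 30L,
                                strand_aware = FALSE) {
  stopifnot("sample_id" %in% names(records))
  if (!is.null(min_mapq)) records <- filter_mapq(records, min_mapq)
  samples <- sort(unique(records$sample_id))
  stats::setNames(lapply(samples, function(s)
    deduplicate(records[records$sample_id == s, , drop = FALSE],
                pos_window, max_umi_mismatch, strand_aware)), samples)
}
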