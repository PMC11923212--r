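# Internal interval helpers: the package stores intervals as data frames
# with 0-based half-open coordinates (BED convention); GenomicRanges is
# 1-based closed, so conversion is confined to these two functions.

#' Convert a 0-based half-open interval table to a GRanges
#'
#' @param df data frame with columns `chrom`, `start`, `end` and
#'   optionally `strand`; any further columns become metadata columns.
#' @param chrom_sizes optional chromosome-sizes data frame
#'   (columns `chrom`, `size`) used to set sequence lengths.
#' @return a [GenomicRanges::GRanges] with the same intervals, 1-based.
#' @keywords internal
#' @noRd
df_to_gr <- function(df, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  seqlen <- NULL
  if (!is.null(chrom_sizes)) {
    seqlen <- stats::setNames(chrom_sizes$size, chrom_sizes$chrom)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand,
    seqlengths = seqlen
  )
  meta <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(meta)) S4Vectors::mcols(gr) <- df[meta]
  gr
}

#' @keywords internal
#' @noRd
gr_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) df$strand <- s
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

# TRUE per row of `a` when it overlaps (>= 1 bp, after expanding `b` by
# `slack` on both sides) at least one interval of `b`. Both 0-based
# half-open; empty `b` gives all FALSE.
overlaps_any <- function(a, b, slack = 0) {
  if (is.null(b) || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  if (nrow(a) == 0) return(logical(0))
  b2 <- b
  b2$start <- pmax(0, b$start - slack)
  b2$end <- b$end + slack
  # suppress the harmless Seqinfo-merge warning when a and b mention
  # different chromosome sets
  suppressWarnings(
    GenomicRanges::countOverlaps(df_to_gr(a), df_to_gr(b2),
                                 ignore.strand = TRUE) > 0)
}

# Fast scalar clash test used by the simulator's rejection sampler:
# does `cand` (one row) overlap any row of `others` within `margin` bp?
clashes_any <- function(cand, others, margin = 0) {
  if (is.null(others) || nrow(others) == 0) return(FALSE)
  any(others$chrom == cand$chrom &
        others$start - margin < cand$end &
        others$end + margin > cand$start)
}

# Distance from each interval midpoint in `a` to the nearest interval in
# `b` (0 when the midpoint falls inside), with the index of that interval.
nearest_feature <- function(mid_chrom, mid_pos, b) {
  n <- length(mid_pos)
  idx <- rep(NA_integer_, n)
  dist <- rep(Inf, n)
  if (is.null(b) || nrow(b) == 0) return(list(index = idx, distance = dist))
  for (i in seq_len(n)) {
    same <- which(b$chrom == mid_chrom[i])
    if (!length(same)) next
    d <- pmax(b$start[same] - mid_pos[i], mid_pos[i] - (b$end[same] - 1L), 0)
    j <- which.min(d)
    idx[i] <- same[j]
    dist[i] <- d[j]
  }
  list(index = idx, distance = dist)
}
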