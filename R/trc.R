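# Transcription-replication conflict (TRC) classification: replication
# origins are located from the EdU-HU signal inside each ERR, fork
# direction at a position follows from its side of the origin (forks
# move outward), and a break region is head-on when the incoming fork
# and the transcription direction of the nearest expressed gene oppose.

#' Locate the replication origin of an ERR from the EdU-HU signal
#'
#' The origin is the position of the maximum of the smoothed EdU-HU
#' signal inside the ERR (moving average over `smooth_bins` track
#' bins). Ties are resolved to the midpoint of the tied plateau, so a
#' flat non-zero profile yields the ERR midpoint.
#'
#' @param edu_hu a [signal_track].
#' @param err one-row data frame (`chrom`, `start`, `end`).
#' @param smooth_bins moving-average window in bins (default 5).
#' @param fallback on all-zero signal: `"error"` (default) or
#'   `"midpoint"` to return the ERR midpoint.
#' @return origin position in bp (numeric).
#' @export
locate_origin <- function(edu_hu, err, smooth_bins = 5L,
                          fallback = c("error", "midpoint")) {
  fallback <- match.arg(fallback)
  step <- edu_hu$step
  b0 <- floor(err$start / step) + 1L
  b1 <- floor((err$end - 1) / step) + 1L
  v <- edu_hu$values[[err$chrom]]
  if (is.null(v) || b0 > length(v)) v_err <- numeric(0)
  else v_err <- v[b0:min(b1, length(v))]
  if (!length(v_err) || all(v_err == 0)) {
    if (fallback == "midpoint") return(floor((err$start + err$end) / 2))
    stop(structure(class = c("trcmap_zero_signal", "error", "condition"),
                   list(message = paste0("no EdU-HU signal inside ERR ",
                                         err$chrom, ":", err$start, "-",
                                         err$end), call = sys.call())))
  }
  if (smooth_bins > 1 && length(v_err) >= smooth_bins) {
    # centered moving average with shrinking windows at the edges
    half <- smooth_bins %/% 2
    nb <- length(v_err)
    v_err <- vapply(seq_len(nb), function(j)
      mean(v_err[max(1, j - half):min(nb, j + half)]), numeric(1))
  }
  tied <- which(v_err == max(v_err))
  mid_idx <- mean(range(tied))
  # center of the (possibly fractional) winning bin on the absolute grid
  (b0 + mid_idx - 1.5) * step
}

#' Replication-fork direction at a position
#'
#' Forks move outward from the origin: positions to the right of the
#' origin are replicated by a right-moving fork, positions to the left
#' by a left-moving one. A position exactly at the origin is degenerate.
#'
#' @param position position in bp.
#' @param origin_pos origin position in bp.
#' @return `"left"` or `"right"`.
#' @export
fork_direction_at <- function(position, origin_pos) {
  if (position == origin_pos)
    stop(structure(class = c("trcmap_at_origin", "error", "condition"),
                   list(message = "position coincides with the origin",
                        call = sys.call())))
  if (position > origin_pos) "right" else "left"
}

#' Head-on / co-directional rule
#'
#' Pure 2x2 mapping of fork direction and gene strand: co-directional
#' when replication and transcription move the same way (`right`/`+` or
#' `left`/`-`), head-on when they oppose (`right`/`-` or `left`/`+`).
#'
#' @param fork_direction `"left"` or `"right"` (vectorized).
#' @param gene_strand `"+"` or `"-"` (vectorized).
#' @return character vector: `"head_on"` or `"co_directional"`.
#' @export
classify_direction <- function(fork_direction, gene_strand) {
  stopifnot(all(fork_direction %in% c("left", "right")),
            all(gene_strand %in% c("+", "-")))
  ifelse((fork_direction == "right") == (gene_strand == "+"),
         "co_directional", "head_on")
}

#' Classify break regions as head-on or co-directional TRCs
#'
#' Each region is associated with the nearest ERR and the nearest
#' expressed gene within `assoc_window` bp of its midpoint. The
#' replication origin of the associated ERR is located from the EdU-HU
#' track ([locate_origin()]); the fork direction at the region midpoint
#' and the gene strand then decide the class
#' ([classify_direction()]). Regions lacking either association, or
#' spanning the origin itself, are unclassified.
#'
#' @param regions region data frame.
#' @param errs ERR table (`chrom`, `start`, `end`, `err_id`).
#' @param edu_hu EdU-HU [signal_track].
#' @param genes gene table with `strand`, `gene_id` and logical
#'   `expressed`.
#' @param assoc_window association window in bp (default 10000).
#' @param smooth_bins passed to [locate_origin()].
#' @return data frame: region coordinates plus `err_id`, `gene_id`,
#'   `gene_strand`, `fork_direction`, `trc_class` (`head_on`,
#'   `co_directional` or `unclassified`).
#' @export
classify_trc <- function(regions, errs, edu_hu, genes,
                         assoc_window = 10000L, smooth_bins = 5L) {
  n <- nrow(regions)
  out <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    err_id = NA_character_, gene_id = NA_character_,
    gene_strand = NA_character_, fork_direction = NA_character_,
    trc_class = rep("unclassified", n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  expressed <- genes[isTRUE_vec(genes$expressed), , drop = FALSE]
  mid <- floor((regions$start + regions$end) / 2)
  near_err <- nearest_feature(regions$chrom, mid, errs)
  near_gene <- nearest_feature(regions$chrom, mid, expressed)
  # cache origins per ERR
  origin_cache <- rep(NA_real_, nrow(errs))
  for (i in seq_len(n)) {
    ei <- near_err$index[i]
    gi <- near_gene$index[i]
    if (is.na(ei) || near_err$distance[i] > assoc_window) next
    if (is.na(gi) || near_gene$distance[i] > assoc_window) next
    if (is.na(origin_cache[ei]))
      origin_cache[ei] <- locate_origin(edu_hu, errs[ei, ],
                                        smooth_bins = smooth_bins,
                                        fallback = "midpoint")
    origin <- origin_cache[ei]
    # regions spanning the origin get no single fork direction
    if (regions$start[i] <= origin && origin < regions$end[i]) next
    if (mid[i] == origin) next
    fd <- fork_direction_at(mid[i], origin)
    out$err_id[i] <- errs$err_id[ei]
    out$gene_id[i] <- expressed$gene_id[gi]
    out$gene_strand[i] <- expressed$strand[gi]
    out$fork_direction[i] <- fd
    out$trc_class[i] <- classify_direction(fd, expressed$strand[gi])
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Summarize TRC calls per cluster
#'
#' @param calls output of [classify_trc()].
#' @param clusters optional per-region cluster labels (NA allowed);
#'   `NULL` summarizes all calls together.
#' @return data frame per cluster: `cluster`, `n_classified`,
#'   `n_head_on`, `n_co_directional`, `frac_head_on`,
#'   `frac_co_directional` (fractions are `NA` when nothing was
#'   classified).
#' @export
summarize_trc <- function(calls, clusters = NULL) {
  if (is.null(clusters)) clusters <- rep("all", nrow(calls))
  stopifnot(length(clusters) == nrow(calls))
  labs <- sort(unique(clusters[!is.na(clusters)]))
  rows <- lapply(labs, function(l) {
    sub <- calls$trc_class[!is.na(clusters) & clusters == l]
    ho <- sum(sub == "head_on")
    cd <- sum(sub == "co_directional")
    ncl <- ho + cd
    data.frame(cluster = as.character(l), n_classified = ncl,
               n_head_on = ho, n_co_directional = cd,
               frac_head_on = if (ncl) ho / ncl else NA_real_,
               frac_co_directional = if (ncl) cd / ncl else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
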