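# Genomic annotation of break-enriched regions: promoter / intragenic /
# extragenic categories, overlap with ERRs and S-phase transcripts,
# cluster assignment, and metagene signal profiles.

# Strand-aware promoter windows around each gene's TSS, 0-based
# half-open, clipped at 0.
promoter_windows <- function(genes, upstream, downstream) {
  if (nrow(genes) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  start <- ifelse(plus, tss - upstream, tss - downstream)
  end <- ifelse(plus, tss + downstream, tss + upstream)
  data.frame(chrom = genes$chrom, start = pmax(0, start), end = end)
}

#' Annotate regions as promoter, intragenic or extragenic
#'
#' A region overlapping (>= 1 bp) any strand-aware TSS window is a
#' promoter region; otherwise a region overlapping any gene body is
#' intragenic; everything else is extragenic. Precedence is
#' promoter > intragenic > extragenic.
#'
#' @param regions region data frame (`chrom`, `start`, `end`).
#' @param genes gene table with `chrom`, `start`, `end`, `strand`.
#' @param promoter_upstream,promoter_downstream TSS window in bp,
#'   upstream/downstream relative to the gene's strand (defaults
#'   2000 / 500).
#' @return character vector, one category per region.
#' @export
annotate_category <- function(regions, genes, promoter_upstream = 2000L,
                              promoter_downstream = 500L) {
  stopifnot(promoter_upstream >= 0, promoter_downstream >= 0)
  prom <- promoter_windows(genes, promoter_upstream, promoter_downstream)
  is_prom <- overlaps_any(regions, prom)
  is_body <- overlaps_any(regions, genes)
  ifelse(is_prom, "promoter", ifelse(is_body, "intragenic", "extragenic"))
}

#' Flag region overlap with ERRs and transcripts
#'
#' A region is flagged when it overlaps a feature by >= 1 bp;
#' `proximal_distance` expands the features by a slack window on both
#' sides before testing (default 0), accommodating "proximal to"
#' semantics.
#'
#' @param regions region data frame.
#' @param errs early-replicated region intervals.
#' @param transcripts transcript intervals (typically the expressed
#'   genes).
#' @param proximal_distance slack in bp added around features.
#' @return list with `flags` (data frame `overlaps_err`,
#'   `overlaps_transcript`) and `fractions` (named numeric: fraction of
#'   regions with each flag set).
#' @export
flag_overlaps <- function(regions, errs, transcripts,
                          proximal_distance = 0L) {
  f <- data.frame(
    overlaps_err = overlaps_any(regions, errs, slack = proximal_distance),
    overlaps_transcript = overlaps_any(regions, transcripts,
                                       slack = proximal_distance))
  fr <- c(err = if (nrow(regions)) mean(f$overlaps_err) else NA_real_,
          transcript = if (nrow(regions)) mean(f$overlaps_transcript)
                       else NA_real_)
  list(flags = f, fractions = fr)
}

#' Assign regions to overlap-defined clusters
#'
#' Regions are partitioned by their two overlap flags. The default
#' mapping is: both flags -> cluster 1, ERR-only -> 2, transcript-only
#' -> 3, neither -> `NA` (unclustered). The published four-cluster
#' scheme splits the double-positive class in two; because the split
#' rule is not derivable from the flags alone it is exposed as
#' configuration: supply per-region `trc_class` and set `split_both` to
#' the class that should be relabelled cluster 4.
#'
#' @param flags data frame with `overlaps_err`, `overlaps_transcript`.
#' @param trc_class optional per-region character vector of TRC classes
#'   (see [classify_trc()]).
#' @param split_both optional TRC class (e.g. `"co_directional"`) whose
#'   double-positive regions are assigned cluster 4 instead of 1.
#' @return integer vector of cluster labels (NA = unclustered).
#' @export
assign_cluster <- function(flags, trc_class = NULL, split_both = NULL) {
  e <- flags$overlaps_err
  t <- flags$overlaps_transcript
  cl <- rep(NA_integer_, nrow(flags))
  cl[e & t] <- 1L
  cl[e & !t] <- 2L
  cl[!e & t] <- 3L
  if (!is.null(split_both) && !is.null(trc_class)) {
    stopifnot(length(trc_class) == nrow(flags))
    cl[e & t & trc_class == split_both] <- 4L
  }
  cl
}

#' Metagene signal profiles over region sets
#'
#' Each region contributes a window of `2 * flank` bp anchored at its
#' midpoint, resampled to `n_points` equally spaced positions; profiles
#' are averaged per cluster. Positions beyond chromosome bounds (or off
#' the stored track) contribute 0, and such truncated regions are
#' flagged in the `truncated` attribute.
#'
#' @param track a [signal_track].
#' @param regions region data frame.
#' @param flank half-window in bp (> 0).
#' @param n_points number of sampled positions per window.
#' @param clusters optional per-region labels; `NULL` averages all
#'   regions together (label `"all"`).
#' @param chrom_sizes optional chromosome sizes used to flag truncated
#'   windows.
#' @return matrix (clusters x n_points) of mean signal, with attribute
#'   `n` (regions per cluster) and `truncated` (logical per region).
#' @export
metagene_profile <- function(track, regions, flank, n_points = 100L,
                             clusters = NULL, chrom_sizes = NULL) {
  stopifnot(flank > 0, n_points > 0)
  n <- nrow(regions)
  if (is.null(clusters)) clusters <- rep("all", n)
  stopifnot(length(clusters) == n)
  # midpoint-anchored sample positions, half-step offset inside the window
  offs <- (seq_len(n_points) - 0.5) / n_points * 2 * flank - flank
  prof <- matrix(0, n, n_points)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    pos <- floor(mid + offs)
    prof[i, ] <- track_value(track, regions$chrom[i], pos)
    lim <- if (!is.null(chrom_sizes))
      chrom_sizes$size[match(regions$chrom[i], chrom_sizes$chrom)]
    else Inf
    truncated[i] <- any(pos < 0) || any(pos >= lim)
  }
  keep <- !is.na(clusters)
  labs <- sort(unique(clusters[keep]))
  out <- t(vapply(labs, function(l)
    colMeans(prof[keep & clusters == l, , drop = FALSE]),
    numeric(n_points)))
  rownames(out) <- as.character(labs)
  attr(out, "n") <- stats::setNames(
    vapply(labs, function(l) sum(keep & clusters == l), numeric(1)),
    as.character(labs))
  attr(out, "truncated") <- truncated
  out
}
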