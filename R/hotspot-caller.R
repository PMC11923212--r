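# Break-enriched ("BLISS+") region calling: library down-sampling,
# fixed-width binning of unique-event UMI counts, coverage thresholding,
# gap merging, replicate union and cross-condition overlap.

#' Down-sample libraries to the smallest total UMI count
#'
#' Sequencing depth varies widely between BLISS libraries; before
#' comparing conditions, every sample is down-sampled so its total UMI
#' count matches the sample with the fewest. The sampling unit is the
#' individual UMI: an event with `umi_count = k` contributes `k`
#' sampleable units, drawn uniformly without replacement.
#'
#' @param events_by_sample named list of unique-event data frames
#'   (`chrom`, `pos`, `umi_count`).
#' @param seed integer seed making the draw reproducible.
#' @return named list of down-sampled event data frames; every sample's
#'   total UMI count equals the pre-existing minimum, and events whose
#'   count drops to 0 are removed.
#' @export
downsample <- function(events_by_sample, seed = 1L) {
  stopifnot(is.list(events_by_sample), length(events_by_sample) >= 1)
  totals <- vapply(events_by_sample, function(e) sum(e$umi_count), numeric(1))
  target <- min(totals)
  with_seed(seed, {
    lapply(events_by_sample, function(e) {
      tot <- sum(e$umi_count)
      if (tot == target) return(e)
      units <- rep(seq_len(nrow(e)), e$umi_count)
      keep <- sample(units, target, replace = FALSE)
      cnt <- tabulate(keep, nbins = nrow(e))
      out <- e[cnt > 0, , drop = FALSE]
      out$umi_count <- cnt[cnt > 0]
      rownames(out) <- NULL
      out
    })
  })
}

#' Bin UMI events into fixed-width genomic bins
#'
#' Each chromosome is tiled with `bin_size` bins anchored at coordinate
#' 0 (the trailing bin may be short); an event at position `p` falls in
#' bin `floor(p / bin_size)` and contributes its UMI count to that
#' bin's coverage.
#'
#' @param events unique-event data frame (`chrom`, `pos`, `umi_count`).
#' @param chrom_sizes data frame with `chrom`, `size`.
#' @param bin_size bin width in bp (default 2000).
#' @return data frame of all bins: `chrom`, `bin_index` (0-based),
#'   `start`, `end`, `coverage`.
#' @export
bin_coverage <- function(events, chrom_sizes, bin_size = 2000L) {
  stopifnot(bin_size > 0)
  bad_chrom <- !events$chrom %in% chrom_sizes$chrom
  if (any(bad_chrom))
    stop("event on unknown chromosome: ",
         paste(utils::head(paste0(events$chrom[bad_chrom], ":",
                                  events$pos[bad_chrom]), 3), collapse = ", "))
  sz <- stats::setNames(chrom_sizes$size, chrom_sizes$chrom)
  beyond <- events$pos >= sz[events$chrom] | events$pos < 0
  if (any(beyond))
    stop("event beyond chromosome end: ",
         paste(utils::head(paste0(
           events$chrom[beyond], ":",
           format(events$pos[beyond], scientific = FALSE, trim = TRUE)), 3),
           collapse = ", "))
  res <- lapply(seq_len(nrow(chrom_sizes)), function(k) {
    ch <- chrom_sizes$chrom[k]
    n_bins <- as.integer(ceiling(chrom_sizes$size[k] / bin_size))
    sel <- events$chrom == ch
    cov <- numeric(n_bins)
    if (any(sel)) {
      idx <- floor(events$pos[sel] / bin_size) + 1L
      cov <- vapply(split(events$umi_count[sel], factor(idx, levels = seq_len(n_bins))),
                    sum, numeric(1))
    }
    i <- seq_len(n_bins)
    data.frame(chrom = ch, bin_index = i - 1L,
               start = (i - 1L) * as.numeric(bin_size),
               end = pmin(i * as.numeric(bin_size), chrom_sizes$size[k]),
               coverage = as.integer(cov))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call BLISS+ bins by coverage threshold
#'
#' Bins whose coverage is strictly above the threshold are called
#' positive (a bin at exactly the threshold is not called); set
#' `strict = FALSE` for a `>=` comparison.
#'
#' @param bins output of [bin_coverage()].
#' @param threshold coverage threshold (default 22).
#' @param strict use strict `>` (default) rather than `>=`.
#' @return the positive bins.
#' @export
call_positive_bins <- function(bins, threshold = 22L, strict = TRUE) {
  stopifnot(threshold >= 0)
  keep <- if (strict) bins$coverage > threshold else bins$coverage >= threshold
  out <- bins[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge positive bins into BLISS+ regions
#'
#' Consecutive positive bins on one chromosome join the same region iff
#' the gap between them (next start minus previous end) is at most
#' `max_gap` bp; region coordinates are the bounding span of member
#' bins.
#'
#' @param pos_bins positive bins from [call_positive_bins()].
#' @param max_gap maximum gap merged across, in bp (default 2000, i.e.
#'   one empty bin at the default bin size).
#' @return data frame of regions: `chrom`, `start`, `end`, `n_bins`,
#'   `total_coverage`.
#' @export
merge_bins <- function(pos_bins, max_gap = 2000L) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0),
                      total_coverage = integer(0))
  if (nrow(pos_bins) == 0) return(empty)
  res <- list()
  for (ch in unique(pos_bins$chrom)) {
    b <- pos_bins[pos_bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    cur_start <- b$start[1]; cur_end <- b$end[1]
    cur_n <- 1L; cur_cov <- b$coverage[1]
    for (i in seq_len(nrow(b))[-1]) {
      if (b$start[i] - cur_end <= max_gap) {
        cur_end <- b$end[i]
        cur_n <- cur_n + 1L
        cur_cov <- cur_cov + b$coverage[i]
      } else {
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = cur_start, end = cur_end,
          n_bins = cur_n, total_coverage = cur_cov)
        cur_start <- b$start[i]; cur_end <- b$end[i]
        cur_n <- 1L; cur_cov <- b$coverage[i]
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch, start = cur_start, end = cur_end,
      n_bins = cur_n, total_coverage = cur_cov)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of replicate region sets
#'
#' Per-condition regions are the interval union of the replicates:
#' overlapping or book-ended intervals coalesce, and the result is
#' sorted and disjoint.
#'
#' @param replicate_region_sets list of region data frames
#'   (`chrom`, `start`, `end`).
#' @return data frame with `chrom`, `start`, `end`.
#' @export
union_regions <- function(replicate_region_sets) {
  stopifnot(is.list(replicate_region_sets), length(replicate_region_sets) >= 1)
  all_df <- do.call(rbind, lapply(replicate_region_sets, function(d)
    d[, c("chrom", "start", "end"), drop = FALSE]))
  if (nrow(all_df) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  gr <- GenomicRanges::reduce(df_to_gr(all_df), ignore.strand = TRUE)
  out <- gr_to_df(gr)[, c("chrom", "start", "end")]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-condition overlap matrix of region sets
#'
#' Entry `(A, B)` is the fraction of regions in condition `A` that
#' overlap (>= 1 bp) at least one region in condition `B`. The matrix
#' is not symmetric in general; the diagonal is 1 for non-empty sets.
#'
#' @param region_sets named list (condition -> region data frame).
#' @return numeric matrix with condition names on both dimensions.
#' @export
overlap_matrix <- function(region_sets) {
  stopifnot(is.list(region_sets), length(region_sets) >= 2,
            !is.null(names(region_sets)))
  conds <- names(region_sets)
  m <- matrix(0, length(conds), length(conds),
              dimnames = list(conds, conds))
  for (a in conds) {
    if (nrow(region_sets[[a]]) == 0) {
      warning("condition ", a, " has no regions; overlap row set to 0")
      next
    }
    for (b in conds) {
      if (nrow(region_sets[[b]]) == 0) next
      m[a, b] <- mean(overlaps_any(region_sets[[a]], region_sets[[b]]))
    }
  }
  m
}
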