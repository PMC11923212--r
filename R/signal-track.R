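#' Fixed-step genomic signal track
#'
#' A lightweight container for fixed-step numeric coverage over a genome
#' (EdU-HU-seq, EU-seq or BLISS coverage). Bin `i` of chromosome `c`
#' covers positions `[(i-1)*step, i*step)` (0-based half-open).
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param step bin width in bp (positive integer).
#' @return an object of class `signal_track`.
#' @examples
#' tr <- signal_track(list(chr1 = c(0, 2, 5, 2, 0)), step = 100)
#' track_value(tr, "chr1", 250)  # inside bin 3 -> 5
#' @export
signal_track <- function(values, step) {
  stopifnot(is.list(values), !is.null(names(values)), step > 0)
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("signal_track values must be non-negative")
  structure(list(values = lapply(values, as.numeric), step = as.integer(step)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track: ", length(x$values), " chromosome(s), step ",
      x$step, " bp\n", sep = "")
  for (ch in names(x$values)) {
    v <- x$values[[ch]]
    cat("  ", ch, ": ", length(v), " bins, max ", format(max(v)), "\n", sep = "")
  }
  invisible(x)
}

#' Look up track values at genomic positions
#'
#' Positions outside the stored vectors (or on unknown chromosomes)
#' return 0, matching the treatment of missing signal elsewhere in the
#' pipeline.
#'
#' @param track a [signal_track].
#' @param chrom chromosome name (scalar or vector recycled against `pos`).
#' @param pos 0-based positions.
#' @return numeric vector of values.
#' @export
track_value <- function(track, chrom, pos) {
  stopifnot(inherits(track, "signal_track"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  out <- numeric(n)
  idx <- floor(pos / track$step) + 1L
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    v <- track$values[[ch]]
    if (is.null(v)) next
    i <- idx[sel]
    ok <- i >= 1L & i <= length(v) & pos[sel] >= 0
    val <- numeric(sum(sel))
    val[ok] <- v[i[ok]]
    out[sel] <- val
  }
  out
}

#' Convert a signal track to a bedGraph-style GRanges
#' @param track a [signal_track].
#' @param drop_zero drop zero-valued bins (default TRUE, as bedGraph
#'   files conventionally omit them).
#' @return GRanges with a `score` metadata column.
#' @export
track_to_granges <- function(track, drop_zero = TRUE) {
  stopifnot(inherits(track, "signal_track"))
  dfs <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    i <- seq_along(v)
    d <- data.frame(chrom = ch, start = (i - 1L) * track$step,
                    end = i * track$step, score = v)
    if (drop_zero) d <- d[d$score != 0, , drop = FALSE]
    d
  })
  df <- do.call(rbind, dfs)
  df_to_gr(df)
}

#' Build a fixed-step signal track from interval scores
#'
#' Rasterizes scored intervals (e.g. imported from a bedGraph file) onto
#' a fixed grid; each output bin takes the coverage-weighted mean of the
#' interval scores overlapping it, 0 where nothing overlaps.
#'
#' @param df data frame with `chrom`, `start`, `end`, `score`
#'   (0-based half-open).
#' @param chrom_sizes data frame with `chrom`, `size`.
#' @param step output bin width in bp.
#' @return a [signal_track].
#' @export
track_from_intervals <- function(df, chrom_sizes, step) {
  stopifnot(step > 0)
  values <- list()
  for (k in seq_len(nrow(chrom_sizes))) {
    ch <- chrom_sizes$chrom[k]
    nb <- ceiling(chrom_sizes$size[k] / step)
    acc <- numeric(nb)
    wt <- numeric(nb)
    sub <- df[df$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      b0 <- floor(sub$start[r] / step)
      b1 <- floor((sub$end[r] - 1) / step)
      for (b in b0:b1) {
        if (b < 0 || b >= nb) next
        ov <- min(sub$end[r], (b + 1) * step) - max(sub$start[r], b * step)
        acc[b + 1L] <- acc[b + 1L] + ov * sub$score[r]
        wt[b + 1L] <- wt[b + 1L] + ov
      }
    }
    v <- numeric(nb)
    nz <- wt > 0
    v[nz] <- acc[nz] / wt[nz]
    values[[ch]] <- v
  }
  signal_track(values, step)
}
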