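# Spike-in based normalization of EU-seq / DRIP-seq count tables:
# extended gene intervals, spike-restricted median-of-ratios size
# factors, expressed-gene filtering, and the DEG / control-gene filters
# applied to an externally computed differential table.

#' Extend gene intervals by a fraction of their length
#'
#' Each gene `[s, e)` of length `L` becomes
#' `[s - fraction*L, e + fraction*L)`, extended at both ends regardless
#' of strand and clipped to chromosome bounds. Used to better capture
#' enrichment bordering transcripts (e.g. DRIP-seq signal at gene
#' flanks); the default extends by 10% before the TSS and after the
#' TES.
#'
#' @param genes gene table (`chrom`, `start`, `end`, other columns kept).
#' @param fraction extension as a fraction of gene length (default 0.10).
#' @param chrom_sizes optional (`chrom`, `size`) for right-side clipping.
#' @return the gene table with extended `start` / `end`.
#' @export
extend_gene_intervals <- function(genes, fraction = 0.10,
                                  chrom_sizes = NULL) {
  stopifnot(fraction >= 0)
  ext <- round(fraction * (genes$end - genes$start))
  out <- genes
  out$start <- pmax(0, genes$start - ext)
  out$end <- genes$end + ext
  if (!is.null(chrom_sizes)) {
    sz <- stats::setNames(chrom_sizes$size, chrom_sizes$chrom)
    out$end <- pmin(out$end, sz[out$chrom])
  }
  out
}

#' Spike-in size factors by median-of-ratios
#'
#' Size factors are computed from spike-in rows only, with the standard
#' median-of-ratios estimator: the reference for each spike row is its
#' geometric mean across samples (rows containing any zero are dropped
#' from the reference), and each sample's factor is the median over
#' spike rows of the count-to-reference ratio. Differences in host
#' material between conditions therefore do not distort normalization,
#' because only the constant-proportion spike-in drives the factors.
#'
#' @param counts non-negative count matrix (rows genes+spikes, columns
#'   samples).
#' @param spike_rows logical vector, or row names / indices, marking
#'   spike-in rows.
#' @param rescale_geomean rescale factors so their geometric mean is 1
#'   (default FALSE).
#' @return named numeric vector of per-sample size factors.
#' @export
spikein_size_factors <- function(counts, spike_rows,
                                 rescale_geomean = FALSE) {
  counts <- as.matrix(counts)
  if (is.logical(spike_rows)) {
    stopifnot(length(spike_rows) == nrow(counts))
    sp <- counts[spike_rows, , drop = FALSE]
  } else {
    sp <- counts[spike_rows, , drop = FALSE]
  }
  if (nrow(sp) == 0) stop("no spike-in rows supplied")
  usable <- apply(sp, 1, function(r) all(r > 0))
  if (!any(usable))
    stop("no usable spike-in row: every row contains a zero count")
  logsp <- log(sp[usable, , drop = FALSE])
  loggeo <- rowMeans(logsp)
  factors <- apply(logsp, 2, function(col) exp(median(col - loggeo)))
  if (rescale_geomean) factors <- factors / exp(mean(log(factors)))
  factors
}

#' Normalize counts and flag expressed genes
#'
#' Normalized counts are `count / size factor`; a gene's `baseMean` is
#' the mean of its normalized counts across samples, and the gene is
#' flagged expressed iff `baseMean` is strictly above `base_mean_min`.
#'
#' @param counts count matrix.
#' @param factors per-sample size factors (from
#'   [spikein_size_factors()]).
#' @param base_mean_min expression threshold on baseMean (default 32).
#' @return list with `normalized` (matrix), `base_mean` (numeric per
#'   row) and `expressed` (logical per row).
#' @export
normalize_and_filter <- function(counts, factors, base_mean_min = 32) {
  counts <- as.matrix(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  normalized <- sweep(counts, 2, factors, "/")
  base_mean <- rowMeans(normalized)
  list(normalized = normalized, base_mean = base_mean,
       expressed = base_mean > base_mean_min)
}

#' Partition a differential table into DEG up / down sets
#'
#' Interface contract on an externally computed differential-expression
#' (or differential DRIP enrichment) table: rows with adjusted p-value
#' strictly below `padj_max` are differential, split by the sign of the
#' fold change.
#'
#' @param de_table data frame with `gene_id`, `padj`,
#'   `log2FoldChange`.
#' @param padj_max adjusted p-value cutoff (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
deg_partition <- function(de_table, padj_max = 0.05) {
  sig <- !is.na(de_table$padj) & de_table$padj < padj_max
  list(up = de_table$gene_id[sig & de_table$log2FoldChange > 0],
       down = de_table$gene_id[sig & de_table$log2FoldChange < 0])
}

#' Sample a null control gene set
#'
#' Draws a uniform random sample, without replacement, of `n` genes
#' whose adjusted p-value is strictly above `padj_floor` — genes with no
#' evidence of change, used as a reference group.
#'
#' @param de_table data frame with `gene_id` and `padj`.
#' @param n control-set size (default 500).
#' @param padj_floor eligibility threshold (default 0.5).
#' @param seed integer seed.
#' @return character vector of `n` gene ids.
#' @export
select_control_genes <- function(de_table, n = 500L, padj_floor = 0.5,
                                 seed = 1L) {
  eligible <- de_table$gene_id[!is.na(de_table$padj) &
                               de_table$padj > padj_floor]
  if (length(eligible) < n)
    stop("only ", length(eligible), " genes have padj > ", padj_floor,
         "; cannot sample ", n)
  if (n == 0) return(character(0))
  with_seed(seed, sample(eligible, n, replace = FALSE))
}
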