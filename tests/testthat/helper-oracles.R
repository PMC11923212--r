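# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own algorithms: O(n^2) pairwise linkage, per-bp
# bitmaps, and direct enumeration.

# O(n^2) single-linkage connected components: edge iff same chrom,
# |pos diff| <= window and UMI Hamming distance <= mm. Returns a list
# with the number of clusters and the sorted representative positions
# (min position per cluster) with per-position cluster counts.
oracle_dedup <- function(chrom, pos, umi, window = 10, mm = 1) {
  n <- length(pos)
  if (n == 0) return(list(n_clusters = 0L,
                          events = data.frame(chrom = character(0),
                                              pos = numeric(0),
                                              umi_count = integer(0))))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (chrom[i] != chrom[j]) next
    if (abs(pos[i] - pos[j]) > window) next
    d <- sum(strsplit(umi[i], "")[[1]] != strsplit(umi[j], "")[[1]])
    if (d <= mm) adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  reps <- data.frame(chrom = tapply(chrom, comp, function(x) x[1]),
                     pos = tapply(pos, comp, min))
  tab <- aggregate(list(umi_count = rep(1L, nrow(reps))),
                   by = list(chrom = reps$chrom, pos = reps$pos), FUN = sum)
  tab <- tab[order(tab$chrom, tab$pos), ]
  rownames(tab) <- NULL
  list(n_clusters = k,
       events = data.frame(chrom = as.character(tab$chrom), pos = tab$pos,
                           umi_count = as.integer(tab$umi_count)))
}

# Per-bp bitmap union of interval sets on a toy genome.
oracle_bitmap_union <- function(dfs, chrom_sizes) {
  out <- list()
  for (k in seq_len(nrow(chrom_sizes))) {
    ch <- chrom_sizes$chrom[k]
    bits <- logical(chrom_sizes$size[k])
    for (d in dfs) {
      sub <- d[d$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(sub)))
        bits[(sub$start[r] + 1):sub$end[r]] <- TRUE
    }
    r <- rle(bits)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0)))
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# Brute-force pairwise interval intersection flags (0-based half-open).
oracle_overlap_flags <- function(a, b, slack = 0) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          (b$start - slack) < a$end[i] &
          (b$end + slack) > a$start[i])
  }, logical(1))
}

# Random break reads on a tiny genome for dedup fuzzing.
random_reads <- function(n, chrom = c("chrA", "chrB"), span = 500,
                         umi_len = 4) {
  data.frame(
    chrom = sample(chrom, n, replace = TRUE),
    pos = sample.int(span, n, replace = TRUE) - 1,
    strand = sample(c("+", "-"), n, replace = TRUE),
    mapq = sample(0:60, n, replace = TRUE),
    umi = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), umi_len, replace = TRUE),
            collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}

# A small reference simulation shared by several test files.
tiny_sim <- function(seed = 11L, ...) {
  cfg <- sim_config(n_chroms = 2L, chrom_length = 3e5, n_genes = 12L,
                    n_errs = 4L, n_hotspots = 6L,
                    err_length_range = c(30000L, 50000L),
                    gene_length_range = c(3000L, 8000L), seed = seed, ...)
  genome <- make_genome_and_annotation(cfg)
  list(cfg = cfg, genome = genome)
}
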