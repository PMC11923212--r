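# Synthetic-data generator: determinism, geometric validity of the
# planted annotation, signal-track construction, read noise model and
# count-matrix scaling.

test_that("empty gene request still produces ERRs and valid output", {
  cfg <- sim_config(n_genes = 0L, n_hotspots = 0L, seed = 3L)
  g <- make_genome_and_annotation(cfg)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$errs), cfg$n_errs)
  expect_true(all(g$errs$origin > g$errs$start & g$errs$origin < g$errs$end))
})

test_that("the same configuration yields byte-identical outputs", {
  cfg <- sim_config(seed = 42L)
  a <- make_genome_and_annotation(cfg)
  b <- make_genome_and_annotation(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  ra <- simulate_bliss_reads(a, cfg)
  rb <- simulate_bliss_reads(b, cfg)
  expect_identical(serialize(ra, NULL), serialize(rb, NULL))
})

test_that("genes lie within chromosome bounds and are pairwise disjoint", {
  cfg <- sim_config(n_chroms = 2L, chrom_length = 1e6, n_genes = 50L,
                    n_hotspots = 10L, seed = 5L)
  g <- make_genome_and_annotation(cfg)
  expect_equal(nrow(g$genes), 50)
  expect_true(all(g$genes$start >= 0))
  expect_true(all(g$genes$end <= 1e6))
  # exhaustive pairwise disjointness check
  for (ch in unique(g$genes$chrom)) {
    s <- g$genes[g$genes$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1)
      expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  # every hotspot lies within a chromosome and inside its ERR's span
  h <- g$truth$hotspots
  expect_true(all(h$start >= 0 & h$end <= 1e6))
  expect_true(all(h$trc_class %in% c("head_on", "co_directional")))
})

test_that("planted hotspot classes are consistent with strand and fork side", {
  g <- tiny_sim(seed = 21L)$genome
  h <- g$truth$hotspots
  for (i in seq_len(nrow(h))) {
    gene <- g$genes[g$genes$gene_id == h$gene_id[i], ]
    err <- g$errs[g$errs$err_id == h$err_id[i], ]
    # fork direction recorded in truth matches the side of the origin
    mid <- (h$start[i] + h$end[i]) / 2
    expect_equal(h$fork_direction[i], if (mid > err$origin) "right" else "left")
    expect_equal(h$trc_class[i],
                 classify_direction(h$fork_direction[i], gene$strand))
  }
})

test_that("EdU-HU track peaks at origins and is zero outside ERRs", {
  s <- tiny_sim(seed = 8L)
  tracks <- make_signal_tracks(s$genome$genes, s$genome$errs, 500L, s$cfg)
  edu <- tracks$edu_hu
  for (i in seq_len(nrow(s$genome$errs))) {
    e <- s$genome$errs[i, ]
    at_origin <- track_value(edu, e$chrom, e$origin)
    inside <- track_value(edu, e$chrom,
                          seq(e$start + 250, e$end - 250, by = 500))
    expect_equal(at_origin, max(inside))
    expect_gt(at_origin, 0)
  }
  # positions away from every ERR carry no signal
  far <- data.frame(chrom = s$genome$chrom_sizes$chrom[1],
                    start = 0, end = s$genome$chrom_sizes$size[1])
  outside_pos <- setdiff(seq(250, far$end - 250, by = 500) , unlist(
    lapply(seq_len(nrow(s$genome$errs)), function(i) {
      e <- s$genome$errs[i, ]
      if (e$chrom != far$chrom) return(numeric(0))
      seq(250, far$end, by = 500)[seq(250, far$end, by = 500) >= e$start - 500 &
                                  seq(250, far$end, by = 500) < e$end + 500]
    })))
  expect_true(all(track_value(edu, far$chrom, outside_pos) == 0))
})

test_that("EU track integrates to level x gene length within one step", {
  s <- tiny_sim(seed = 9L)
  step <- 500L
  tracks <- make_signal_tracks(s$genome$genes, s$genome$errs, step, s$cfg)
  eu <- tracks$eu
  g <- s$genome$genes
  # direct summation oracle over one expressed gene isolated from others
  for (i in which(g$expressed)[1:3]) {
    others <- g[-i, ]
    near <- any(others$chrom == g$chrom[i] &
                  others$start < g$end[i] + step &
                  others$end > g$start[i] - step)
    if (near) next
    bins <- seq(floor(g$start[i] / step), ceiling(g$end[i] / step)) * step + step / 2
    integral <- sum(track_value(eu, g$chrom[i], bins)) * step
    expect_lt(abs(integral - g$eu_level[i] * (g$end[i] - g$start[i])),
              g$eu_level[i] * step + 1e-9)
  }
})

test_that("without PCR duplication every read is a unique molecule", {
  s <- tiny_sim(seed = 13L, pcr_duplication_rate = 0, umi_error_rate = 0)
  sim <- simulate_bliss_reads(s$genome, s$cfg)
  expect_equal(nrow(sim$reads), nrow(sim$truth$molecules))
  expect_false(any(sim$reads$is_duplicate))
})

test_that("duplicates stay within the jitter window and one UMI mismatch", {
  s <- tiny_sim(seed = 14L, pcr_duplication_rate = 0.5, umi_error_rate = 0.5)
  sim <- simulate_bliss_reads(s$genome, s$cfg)
  dup <- sim$reads[sim$reads$is_duplicate, ]
  parents <- sim$truth$molecules
  expect_gt(nrow(dup), 0)
  for (i in seq_len(min(nrow(dup), 200))) {
    p <- parents[parents$molecule_id == dup$molecule_id[i], ]
    expect_lte(abs(dup$pos[i] - p$pos), s$cfg$pos_jitter_max)
    expect_lte(hamming(dup$umi[i], p$umi), 1)
  }
  # prefix sequence is UMI followed by barcode
  expect_identical(sim$reads$read_prefix_sequence,
                   paste0(sim$reads$umi, sim$reads$barcode))
})

test_that("unit hotspot multiplier leaves hotspot windows at background rate", {
  # Monte-Carlo rate-ratio check over 20 seeds
  ratios <- vapply(1:20, function(seed) {
    s <- tiny_sim(seed = seed, hotspot_rate_multiplier = 1,
                  pcr_duplication_rate = 0, n_samples = 1L)
    sim <- simulate_bliss_reads(s$genome, s$cfg)
    h <- s$genome$truth$hotspots
    hot_bp <- sum(h$end - h$start)
    genome_bp <- sum(s$genome$chrom_sizes$size)
    m <- sim$truth$molecules
    in_hot <- sum(m$in_hotspot)
    (in_hot / hot_bp) / ((nrow(m) - in_hot) / (genome_bp - hot_bp))
  }, numeric(1))
  ci <- mean(ratios) + c(-3, 3) * sd(ratios) / sqrt(length(ratios))
  expect_gt(ci[2], 1)
  expect_lt(ci[1], 1)
})

test_that("count simulation respects spike equality and exact scaling", {
  s <- tiny_sim(seed = 15L)
  # all factors 1, no noise: spike rows identical across samples
  cm1 <- simulate_counts(s$genome$genes, c(a = 1, b = 1), n_spike = 20,
                         s$cfg, noise = "none")
  sp <- cm1$counts[cm1$spike_rows, ]
  expect_true(all(sp[, 1] == sp[, 2]))
  # factors (1, 2), no noise: second sample exactly double
  cm2 <- simulate_counts(s$genome$genes, c(a = 1, b = 2), n_spike = 20,
                         s$cfg, noise = "none")
  expect_true(all(cm2$counts[, 2] == 2 * cm2$counts[, 1]))
  expect_true(all(cm2$counts >= 0))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(hotspot_rate_multiplier = 0.5), "multiplier")
  expect_error(sim_config(pcr_duplication_rate = 1.5), "must be in")
  expect_error(sim_config(n_hotspots = 10, n_genes = 5), "exceed")
  expect_error(sim_config(chrom_length = 0), "positive")
  # unsatisfiable placement requests fail with guidance, not hang
  expect_error(make_genome_and_annotation(
    sim_config(n_chroms = 1L, chrom_length = 1e4, n_genes = 50L,
               n_hotspots = 0L, n_errs = 0L,
               gene_length_range = c(3000L, 3000L))), "could not place")
})
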