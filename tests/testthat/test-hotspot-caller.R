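# Down-sampling, binning, thresholding, gap merging, union and overlap.

toy_sizes <- data.frame(chrom = c("chrA", "chrB"), size = c(100000L, 50000L))

test_that("down-sampling equalizes totals at the pre-existing minimum", {
  ev <- list(
    s1 = data.frame(chrom = "chrA", pos = seq(0, 990, 10), umi_count = 1L),
    s2 = data.frame(chrom = "chrA", pos = seq(0, 490, 10),
                    umi_count = rep(5L, 50)))
  # totals 100 and 250
  out <- downsample(ev, seed = 4)
  expect_equal(sum(out$s1$umi_count), 100)
  expect_equal(sum(out$s2$umi_count), 100)
  # the smallest sample is returned unchanged
  expect_identical(out$s1, ev$s1)
  # single sample: unchanged
  expect_identical(downsample(ev["s1"], seed = 1)$s1, ev$s1)
})

test_that("down-sampling draws UMIs uniformly", {
  ev <- list(
    small = data.frame(chrom = "chrA", pos = 0, umi_count = 40L),
    big = data.frame(chrom = "chrA", pos = seq(0, 99) * 10,
                     umi_count = 1L))
  p <- 40 / 100
  incl <- matrix(0, 20, 100)
  for (seed in 1:20) {
    out <- downsample(ev, seed = seed)
    kept <- out$big$pos / 10 + 1
    incl[seed, kept] <- 1
  }
  freq <- colMeans(incl)
  # mean inclusion over units matches p within 3 sigma of the mean
  expect_lt(abs(mean(freq) - p), 3 * sqrt(p * (1 - p) / (20 * 100)) + 1e-12)
})

test_that("bin coverage places events by floor division and conserves counts", {
  ev <- data.frame(chrom = "chrA", pos = c(1999, 2000, 0, 99999),
                   umi_count = c(1L, 2L, 3L, 4L))
  bins <- bin_coverage(ev, toy_sizes, bin_size = 2000)
  a <- bins[bins$chrom == "chrA", ]
  expect_equal(a$coverage[a$bin_index == 0], 1 + 3)
  expect_equal(a$coverage[a$bin_index == 1], 2)
  expect_equal(a$coverage[a$bin_index == 49], 4)
  expect_equal(sum(bins$coverage), sum(ev$umi_count))
  # bins tile both chromosomes without gaps
  expect_equal(nrow(bins), 50 + 25)
  expect_true(all(bins$end - bins$start <= 2000))
  # no events: all zero
  empty <- bin_coverage(ev[0, ], toy_sizes)
  expect_true(all(empty$coverage == 0))
})

test_that("bin coverage matches an independent histogram oracle", {
  set.seed(6)
  ev <- data.frame(chrom = sample(toy_sizes$chrom, 10000, TRUE,
                                  prob = c(2, 1)),
                   pos = NA_real_, umi_count = sample(1:3, 10000, TRUE))
  ev$pos <- floor(runif(10000) *
                    toy_sizes$size[match(ev$chrom, toy_sizes$chrom)])
  bins <- bin_coverage(ev, toy_sizes, bin_size = 2000)
  for (ch in toy_sizes$chrom) {
    sub <- ev[ev$chrom == ch, ]
    nb <- ceiling(toy_sizes$size[toy_sizes$chrom == ch] / 2000)
    oracle <- vapply(seq_len(nb) - 1, function(b)
      sum(sub$umi_count[sub$pos >= b * 2000 & sub$pos < (b + 1) * 2000]),
      numeric(1))
    expect_equal(bins$coverage[bins$chrom == ch], as.integer(oracle))
  }
})

test_that("events beyond the chromosome end are reported by name", {
  bad <- data.frame(chrom = "chrA", pos = 100000, umi_count = 1L)
  expect_error(bin_coverage(bad, toy_sizes), "chrA:100000")
  expect_error(bin_coverage(data.frame(chrom = "chrZ", pos = 5,
                                       umi_count = 1L), toy_sizes),
               "unknown chromosome")
})

test_that("positive-bin calling is strictly above the threshold", {
  bins <- data.frame(chrom = "chrA", bin_index = 0:3,
                     start = (0:3) * 2000, end = (1:4) * 2000,
                     coverage = c(22L, 23L, 0L, 100L))
  called <- call_positive_bins(bins, threshold = 22)
  expect_equal(called$coverage, c(23L, 100L))
  # >= comparison available but off by default
  expect_equal(nrow(call_positive_bins(bins, 22, strict = FALSE)), 3)
  # threshold 0 calls every non-zero bin
  expect_equal(call_positive_bins(bins, 0)$coverage, c(22L, 23L, 100L))
  # filter oracle on random coverages
  set.seed(7)
  rnd <- data.frame(chrom = "chrA", bin_index = 0:999,
                    start = (0:999) * 2000, end = (1:1000) * 2000,
                    coverage = rpois(1000, 20))
  expect_equal(call_positive_bins(rnd, 22)$bin_index,
               rnd$bin_index[rnd$coverage > 22])
})

test_that("bin merging respects the maximum gap exactly", {
  mk <- function(starts) data.frame(chrom = "chrA", bin_index = starts / 2000,
                                    start = starts, end = starts + 2000,
                                    coverage = 30L)
  # adjacent bins -> one 4 kb region
  r <- merge_bins(mk(c(0, 2000)), max_gap = 2000)
  expect_equal(nrow(r), 1)
  expect_equal(r$end - r$start, 4000)
  expect_equal(r$n_bins, 2L)
  expect_equal(r$total_coverage, 60L)
  # one empty 2 kb bin between (gap exactly 2000): merged
  expect_equal(nrow(merge_bins(mk(c(0, 4000)), 2000)), 1)
  # gap 2001: two regions
  g2 <- data.frame(chrom = "chrA", bin_index = c(0, 2),
                   start = c(0, 4001), end = c(2000, 6001),
                   coverage = 30L)
  expect_equal(nrow(merge_bins(g2, 2000)), 2)
  # no two output regions within max_gap of each other
  set.seed(8)
  pos <- sort(sample(0:199, 60)) * 2000
  r2 <- merge_bins(mk(pos), 2000)
  if (nrow(r2) > 1)
    expect_true(all(r2$start[-1] - r2$end[-nrow(r2)] > 2000))
  # merging is conservative on counts
  expect_equal(sum(r2$total_coverage), 60 * 30)
  expect_equal(sum(r2$n_bins), 60)
})

test_that("replicate union coalesces overlapping and book-ended intervals", {
  a <- data.frame(chrom = "chrA", start = 0, end = 2000)
  b <- data.frame(chrom = "chrA", start = 1000, end = 4000)
  u <- union_regions(list(a, b))
  expect_equal(u, data.frame(chrom = "chrA", start = 0, end = 4000))
  # book-ended
  u2 <- union_regions(list(a, data.frame(chrom = "chrA", start = 2000,
                                         end = 3000)))
  expect_equal(u2$end, 3000)
  # single replicate: identity
  expect_equal(union_regions(list(a)), a)
  # idempotent and commutative
  expect_equal(union_regions(list(u)), u)
  expect_equal(union_regions(list(b, a)), u)
})

test_that("union matches a base-pair bitmap oracle on a toy genome", {
  sizes <- data.frame(chrom = c("chrA", "chrB"), size = c(100000L, 100000L))
  set.seed(9)
  mk_set <- function() {
    n <- sample(5:15, 1)
    st <- sample(0:(100000 - 5000), n, replace = TRUE)
    data.frame(chrom = sample(sizes$chrom, n, TRUE), start = st,
               end = st + sample(500:5000, n, TRUE))
  }
  for (rep in 1:5) {
    sets <- list(mk_set(), mk_set(), mk_set())
    u <- union_regions(sets)
    o <- oracle_bitmap_union(sets, sizes)
    expect_equal(u, o)
  }
})

test_that("overlap matrix reports pairwise region-overlap fractions", {
  a <- data.frame(chrom = "chrA", start = c(0, 5000), end = c(1000, 6000))
  b <- data.frame(chrom = "chrA", start = 500, end = 700)
  d <- data.frame(chrom = "chrB", start = 0, end = 1000)
  m <- overlap_matrix(list(A = a, B = b, D = d))
  # hand computation: one of A's two regions hits B; B entirely in A;
  # D disjoint from both
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["B", "A"], 1)
  expect_equal(m["A", "D"], 0)
  expect_equal(m["D", "B"], 0)
  expect_equal(diag(m), c(A = 1, B = 1, D = 1))
  # identical sets -> all ones
  expect_true(all(overlap_matrix(list(x = a, y = a)) == 1))
  # empty set: zero row with a warning
  expect_warning(m0 <- overlap_matrix(list(x = a, z = a[0, ])), "no regions")
  expect_true(all(m0["z", ] == 0))
})
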