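# Synthetic genomes, annotations, signal tracks, BLISS read sets and
# count matrices with known ground truth. The generator reproduces the
# statistical structure the downstream analysis assumes: uniform Poisson
# background breaks, promoter-proximal break hotspots planted inside
# early-replicated regions (ERRs) on a chosen side of the replication
# origin, PCR duplicates with UMI errors and bounded positional jitter,
# fork-symmetric EdU-HU profiles decaying from origins, per-gene
# transcription signal, and spike-in scaled count matrices.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so simulation calls never perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Substitute exactly one random position of a DNA string.
substitute_one <- function(s) {
  v <- strsplit(s, "")[[1]]
  i <- sample.int(length(v), 1)
  v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe the reference simulation used throughout the package tests:
#' two 1 Mb chromosomes, 12 non-overlapping ERRs, 60 genes of which 20
#' are planted as promoter-proximal DSB hotspots inside ERRs, a uniform
#' background break rate of 0.002 breaks/bp (4 expected unique breaks
#' per 2 kb bin) and a 25-fold hotspot rate multiplier (100 expected
#' breaks per hotspot bin), so planted hotspots clear the default bin
#' coverage threshold of 22 by a wide margin while background bins
#' essentially never do.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param n_genes total number of genes (includes the hotspot genes).
#' @param gene_length_range length-2 vector, min/max gene length in bp.
#' @param n_errs number of early-replicated regions.
#' @param err_length_range length-2 vector, min/max ERR length in bp.
#' @param background_break_rate background break density, breaks per bp.
#' @param hotspot_rate_multiplier fold increase of the break rate inside
#'   planted hotspot windows (>= 1).
#' @param n_hotspots number of planted promoter-proximal hotspots; each
#'   is tied to a gene placed inside an ERR on one side of its origin.
#' @param hotspot_halfwidth half-width of the hotspot window around the
#'   TSS, in bp.
#' @param pcr_duplication_rate probability that a unique molecule is
#'   re-emitted once as a PCR duplicate.
#' @param umi_error_rate probability that a duplicate carries a single
#'   UMI substitution.
#' @param barcode_error_rate probability that a read's sample barcode
#'   carries a single substitution.
#' @param pos_jitter_max maximum absolute positional jitter of a
#'   duplicate relative to its parent, in bp.
#' @param umi_length UMI length in nt.
#' @param barcode_length sample barcode length in nt.
#' @param mapq_fail_rate fraction of reads drawn with mapping quality
#'   below 30.
#' @param n_samples number of samples (one barcode each).
#' @param seed integer seed; identical configurations give
#'   byte-identical outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 1e6,
                       n_genes = 60L,
                       gene_length_range = c(5000L, 20000L),
                       n_errs = 12L,
                       err_length_range = c(40000L, 80000L),
                       background_break_rate = 0.002,
                       hotspot_rate_multiplier = 25,
                       n_hotspots = 20L,
                       hotspot_halfwidth = 1000L,
                       pcr_duplication_rate = 0.3,
                       umi_error_rate = 0.05,
                       barcode_error_rate = 0.01,
                       pos_jitter_max = 10L,
                       umi_length = 8L,
                       barcode_length = 8L,
                       mapq_fail_rate = 0.05,
                       n_samples = 2L,
                       seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_errs = as.integer(n_errs),
    err_length_range = as.integer(err_length_range),
    background_break_rate = background_break_rate,
    hotspot_rate_multiplier = hotspot_rate_multiplier,
    n_hotspots = as.integer(n_hotspots),
    hotspot_halfwidth = as.integer(hotspot_halfwidth),
    pcr_duplication_rate = pcr_duplication_rate,
    umi_error_rate = umi_error_rate,
    barcode_error_rate = barcode_error_rate,
    pos_jitter_max = as.integer(pos_jitter_max),
    umi_length = as.integer(umi_length),
    barcode_length = as.integer(barcode_length),
    mapq_fail_rate = mapq_fail_rate,
    n_samples = as.integer(n_samples), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c("pcr_duplication_rate", "umi_error_rate", "barcode_error_rate",
             "mapq_fail_rate")
  for (r in rates)
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0,1]")
  if (cfg$background_break_rate < 0) stop("background_break_rate must be >= 0")
  if (cfg$hotspot_rate_multiplier < 1)
    stop("hotspot_rate_multiplier must be >= 1")
  lens <- c("n_chroms", "chrom_length", "umi_length", "barcode_length")
  for (l in lens) if (cfg[[l]] <= 0) stop(l, " must be positive")
  if (cfg$n_genes < 0 || cfg$n_errs < 0 || cfg$n_hotspots < 0 ||
      cfg$n_samples < 1)
    stop("feature counts must be non-negative and n_samples >= 1")
  if (cfg$n_hotspots > cfg$n_genes)
    stop("n_hotspots cannot exceed n_genes")
  if (cfg$n_hotspots > 0 && cfg$n_errs == 0)
    stop("hotspots require at least one ERR")
  if (any(diff(cfg$gene_length_range) < 0) ||
      any(diff(cfg$err_length_range) < 0))
    stop("length ranges must be non-decreasing")
  invisible(cfg)
}

# Place `n` non-overlapping intervals of lengths drawn from `len_range`
# on chromosomes of `chrom_sizes`, keeping `margin` bp clear between
# intervals and avoiding intervals in `avoid`. Bounded rejection
# sampling; errors when the request cannot be satisfied.
place_intervals <- function(n, len_range, chrom_sizes, margin = 0,
                            avoid = NULL, max_tries = 2000L) {
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- if (len_range[1] == len_range[2]) len_range[1] else
        sample(seq(len_range[1], len_range[2]), 1)
      k <- sample.int(nrow(chrom_sizes), 1)
      hi <- chrom_sizes$size[k] - len
      if (hi < 0) next
      s <- floor(runif(1, 0, hi + 1))
      cand <- data.frame(chrom = chrom_sizes$chrom[k], start = s, end = s + len)
      if (clashes_any(cand, placed, margin) ||
          (!is.null(avoid) && clashes_any(cand, avoid, margin))) next
      placed <- rbind(placed, cand)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place ", n, " non-overlapping intervals of ",
                  len_range[1], "-", len_range[2],
                  " bp; reduce counts or lengths")
  }
  placed
}

#' Generate a synthetic genome, gene annotation, ERRs and ground truth
#'
#' Builds the coordinate scaffold the rest of the simulator and the
#' pipeline operate on: equal-length chromosomes; non-overlapping ERRs,
#' each recording its replication origin at the interval midpoint; and
#' non-overlapping stranded genes. The first `n_hotspots` genes are
#' "conflict genes": each is placed wholly on one side of an ERR origin
#' so that the outward-moving replication fork at its promoter has a
#' known direction, and its strand is chosen to realize an alternating
#' sequence of head-on and co-directional transcription-replication
#' conflicts. The promoter-proximal window around each conflict gene's
#' TSS is recorded as a planted DSB hotspot in the truth table.
#'
#' @param config a [sim_config].
#' @return list with `chrom_sizes` (data frame `chrom`, `size`), `genes`
#'   (BED-like data frame with `strand`, `gene_id`, `expressed`,
#'   `eu_level`), `errs` (`chrom`, `start`, `end`, `err_id`, `origin`)
#'   and `truth` (list with `hotspots`, `barcode_whitelist` filled in by
#'   [simulate_bliss_reads()], and `true_scale_factors` used by
#'   [simulate_counts()]).
#' @export
make_genome_and_annotation <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    chrom_sizes <- data.frame(
      chrom = paste0("chr", seq_len(config$n_chroms)),
      size = as.integer(rep(config$chrom_length, config$n_chroms))
    )

    errs <- place_intervals(config$n_errs, config$err_length_range,
                            chrom_sizes, margin = 5000)
    if (nrow(errs)) {
      errs <- errs[order(errs$chrom, errs$start), , drop = FALSE]
      errs$err_id <- sprintf("err_%02d", seq_len(nrow(errs)))
      errs$origin <- floor((errs$start + errs$end) / 2)
      rownames(errs) <- NULL
    } else {
      errs <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), err_id = character(0),
                         origin = numeric(0))
    }

    genes <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0))
    hot <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), planted_rate = numeric(0),
                      err_id = character(0), gene_id = character(0),
                      trc_class = character(0), fork_direction = character(0))

    hw <- config$hotspot_halfwidth
    if (config$n_hotspots > 0) {
      # cycle over (ERR, side) slots; alternate planted conflict class
      slots <- expand.grid(err = seq_len(nrow(errs)), side = c("right", "left"),
                           stringsAsFactors = FALSE)
      for (h in seq_len(config$n_hotspots)) {
        slot <- slots[(h - 1L) %% nrow(slots) + 1L, ]
        e <- errs[slot$err, ]
        want_class <- if (h %% 2 == 1) "head_on" else "co_directional"
        fork <- slot$side
        # head-on: fork and transcription oppose
        strand <- if (fork == "right") {
          if (want_class == "head_on") "-" else "+"
        } else {
          if (want_class == "head_on") "+" else "-"
        }
        placed <- FALSE
        for (try in seq_len(500)) {
          len <- sample(seq(config$gene_length_range[1],
                            config$gene_length_range[2]), 1)
          margin <- hw + 200
          if (fork == "right") {
            lo <- e$origin + margin
            hi <- e$end - len
          } else {
            lo <- e$start
            hi <- e$origin - margin - len
          }
          if (hi < lo) {
            # gene too long for this half-ERR; shrink towards the minimum
            len_max <- max(config$gene_length_range[1],
                           floor((e$end - e$start) / 2 - 2 * margin))
            if (len_max < config$gene_length_range[1]) break
            next
          }
          s <- floor(runif(1, lo, hi + 1))
          cand <- data.frame(chrom = e$chrom, start = s, end = s + len)
          if (clashes_any(cand, genes, margin = 100)) next
          tss <- if (strand == "+") s else s + len
          win <- data.frame(chrom = e$chrom,
                            start = max(0, tss - hw), end = tss + hw)
          # hotspot window must stay on one side of the origin
          if (win$start <= e$origin && e$origin < win$end) next
          if (clashes_any(win, hot)) next
          genes <- rbind(genes, cbind(cand, strand = strand))
          hot <- rbind(hot, data.frame(
            chrom = win$chrom, start = win$start, end = win$end,
            planted_rate = config$background_break_rate *
              config$hotspot_rate_multiplier,
            err_id = e$err_id, gene_id = sprintf("gene_%03d", h),
            trc_class = want_class, fork_direction = fork))
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place hotspot gene ", h,
               " inside an ERR; enlarge ERRs or reduce n_hotspots")
      }
    }

    n_rest <- config$n_genes - config$n_hotspots
    if (n_rest > 0) {
      rest <- place_intervals(n_rest, config$gene_length_range, chrom_sizes,
                              margin = 100, avoid = genes)
      rest$strand <- sample(c("+", "-"), n_rest, replace = TRUE)
      genes <- rbind(genes, rest)
    }
    if (nrow(genes)) {
      genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))
      # conflict genes are always S-phase expressed; the rest: half
      genes$expressed <- c(rep(TRUE, config$n_hotspots),
                           runif(n_rest) < 0.5)
      genes$eu_level <- ifelse(genes$expressed,
                               round(exp(rnorm(nrow(genes), log(50), 0.4)), 2),
                               0)
      rownames(genes) <- NULL
    } else {
      genes <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          gene_id = character(0), expressed = logical(0),
                          eu_level = numeric(0))
    }

    truth <- list(
      hotspots = hot,
      true_scale_factors = stats::setNames(rep(1, config$n_samples),
                                           paste0("sample_", seq_len(config$n_samples)))
    )
    list(chrom_sizes = chrom_sizes, genes = genes, errs = errs, truth = truth)
  })
}

#' Build synthetic EdU-HU and EU signal tracks
#'
#' The EdU-HU track models newly synthesized DNA under hydroxyurea:
#' within each ERR the signal is maximal at the replication origin
#' (interval midpoint) and decays linearly to 0 at the ERR edges,
#' symmetrically on both sides, mirroring outward fork movement; outside
#' all ERRs it is 0. The EU track models nascent transcription: a
#' constant per-gene level (`eu_level`) over each expressed gene body
#' and 0 elsewhere.
#'
#' @param genes,errs as returned by [make_genome_and_annotation()].
#' @param step track bin width in bp.
#' @param config a [sim_config] (supplies chromosome sizes).
#' @param amplitude EdU-HU peak height at the origin (arbitrary units).
#' @return list with `edu_hu` and `eu`, both [signal_track]s.
#' @export
make_signal_tracks <- function(genes, errs, step, config, amplitude = 100) {
  stopifnot(step > 0)
  chrom_sizes <- data.frame(chrom = paste0("chr", seq_len(config$n_chroms)),
                            size = as.integer(rep(config$chrom_length,
                                                  config$n_chroms)))
  mk <- function() {
    stats::setNames(
      lapply(chrom_sizes$size, function(sz) numeric(ceiling(sz / step))),
      chrom_sizes$chrom)
  }
  edu <- mk()
  eu <- mk()
  for (i in seq_len(nrow(errs))) {
    e <- errs[i, ]
    b0 <- floor(e$start / step) + 1L
    b1 <- min(floor((e$end - 1) / step) + 1L, length(edu[[e$chrom]]))
    centers <- (seq(b0, b1) - 0.5) * step
    left <- pmax(0, (centers - e$start) / (e$origin - e$start))
    right <- pmax(0, (e$end - centers) / (e$end - e$origin))
    tri <- amplitude * pmin(left, right)
    tri[centers < e$start | centers >= e$end] <- 0
    edu[[e$chrom]][b0:b1] <- pmax(edu[[e$chrom]][b0:b1], tri)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!isTRUE(g$expressed) || g$eu_level <= 0) next
    b0 <- floor(g$start / step) + 1L
    b1 <- min(floor((g$end - 1) / step) + 1L, length(eu[[g$chrom]]))
    bins <- b0:b1
    # partial boundary bins contribute in proportion to their coverage
    frac <- (pmin(g$end, bins * step) - pmax(g$start, (bins - 1) * step)) / step
    eu[[g$chrom]][bins] <- eu[[g$chrom]][bins] + g$eu_level * frac
  }
  list(edu_hu = signal_track(edu, step), eu = signal_track(eu, step))
}

#' Simulate sBLISS break reads with PCR duplicates and prefix sequences
#'
#' Unique break molecules are drawn per chromosome as a uniform Poisson
#' process at `background_break_rate`; each planted hotspot window
#' receives additional molecules so that its total rate equals
#' `hotspot_rate_multiplier` times background. Every molecule gets a
#' random UMI and its sample's whitelist barcode; with probability
#' `pcr_duplication_rate` it is re-emitted once as a PCR duplicate with
#' uniform positional jitter in `[-pos_jitter_max, pos_jitter_max]` and,
#' with probability `umi_error_rate`, a single UMI substitution. Sample
#' barcodes carry a single substitution with probability
#' `barcode_error_rate`. Mapping qualities are a two-component mixture:
#' a `mapq_fail_rate` fraction falls in 0-29, the rest in 30-60.
#'
#' @param genome output of [make_genome_and_annotation()].
#' @param config a [sim_config].
#' @return list with `reads` (data frame: `chrom`, `pos`, `strand`,
#'   `mapq`, `umi`, `barcode`, `sample_id`, `molecule_id`,
#'   `is_duplicate`, `read_prefix_sequence`), `truth` (the input truth
#'   augmented with `molecules` and `barcode_whitelist`).
#' @export
simulate_bliss_reads <- function(genome, config) {
  validate_sim_config(config)
  chrom_sizes <- genome$chrom_sizes
  hot <- genome$truth$hotspots
  with_seed(config$seed + 1000L, {
    # whitelist with pairwise Hamming distance > 2 so 1-mismatch
    # demultiplexing is unambiguous
    whitelist <- character(0)
    while (length(whitelist) < config$n_samples) {
      cand <- random_dna(1, config$barcode_length)
      if (all(vapply(whitelist, function(w) hamming(w, cand), numeric(1)) > 4) ||
          !length(whitelist))
        whitelist <- c(whitelist, cand)
    }
    samples <- paste0("sample_", seq_len(config$n_samples))
    names(whitelist) <- samples

    mol_list <- list()
    for (s in samples) {
      for (k in seq_len(nrow(chrom_sizes))) {
        ch <- chrom_sizes$chrom[k]
        sz <- chrom_sizes$size[k]
        n_bg <- rpois(1, config$background_break_rate * sz)
        pos <- if (n_bg) floor(runif(n_bg, 0, sz)) else numeric(0)
        hot_ch <- hot[hot$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(hot_ch))) {
          w <- hot_ch$end[i] - hot_ch$start[i]
          extra_rate <- config$background_break_rate *
            (config$hotspot_rate_multiplier - 1)
          n_h <- rpois(1, extra_rate * w)
          if (n_h) pos <- c(pos, floor(runif(n_h, hot_ch$start[i], hot_ch$end[i])))
        }
        if (length(pos))
          mol_list[[paste(s, ch)]] <- data.frame(
            sample_id = s, chrom = ch, pos = as.numeric(pos))
      }
    }
    molecules <- if (length(mol_list)) do.call(rbind, mol_list) else
      data.frame(sample_id = character(0), chrom = character(0),
                 pos = numeric(0))
    rownames(molecules) <- NULL
    n_mol <- nrow(molecules)
    if (n_mol) {
      molecules$molecule_id <- sprintf("mol_%06d", seq_len(n_mol))
      molecules$umi <- random_dna(n_mol, config$umi_length)
      molecules$strand <- sample(c("+", "-"), n_mol, replace = TRUE)
      in_hot <- rep(FALSE, n_mol)
      if (nrow(hot))
        in_hot <- overlaps_any(
          data.frame(chrom = molecules$chrom, start = molecules$pos,
                     end = molecules$pos + 1), hot)
      molecules$in_hotspot <- in_hot
    } else {
      molecules$molecule_id <- character(0)
      molecules$umi <- character(0)
      molecules$strand <- character(0)
      molecules$in_hotspot <- logical(0)
    }

    draw_mapq <- function(n) {
      fail <- runif(n) < config$mapq_fail_rate
      q <- integer(n)
      q[fail] <- sample(0:29, sum(fail), replace = TRUE)
      q[!fail] <- sample(30:60, sum(!fail), replace = TRUE)
      q
    }
    draw_barcode <- function(sample_id) {
      bc <- unname(whitelist[sample_id])
      err <- runif(length(bc)) < config$barcode_error_rate
      bc[err] <- vapply(bc[err], substitute_one, character(1))
      bc
    }

    reads <- molecules[, c("chrom", "pos", "strand", "umi", "sample_id",
                           "molecule_id")]
    reads$mapq <- draw_mapq(n_mol)
    reads$barcode <- draw_barcode(reads$sample_id)
    reads$is_duplicate <- rep(FALSE, n_mol)

    dup_sel <- which(runif(n_mol) < config$pcr_duplication_rate)
    if (length(dup_sel)) {
      dup <- reads[dup_sel, , drop = FALSE]
      jit <- sample(seq(-config$pos_jitter_max, config$pos_jitter_max),
                    length(dup_sel), replace = TRUE)
      sz <- stats::setNames(chrom_sizes$size, chrom_sizes$chrom)
      dup$pos <- pmin(pmax(dup$pos + jit, 0), sz[dup$chrom] - 1)
      umi_err <- runif(length(dup_sel)) < config$umi_error_rate
      dup$umi[umi_err] <- vapply(dup$umi[umi_err], substitute_one, character(1))
      dup$mapq <- draw_mapq(length(dup_sel))
      dup$barcode <- draw_barcode(dup$sample_id)
      dup$is_duplicate <- TRUE
      reads <- rbind(reads, dup)
    }
    rownames(reads) <- NULL
    reads$read_prefix_sequence <- paste0(reads$umi, reads$barcode)
    reads <- reads[, c("chrom", "pos", "strand", "mapq", "umi", "barcode",
                       "sample_id", "molecule_id", "is_duplicate",
                       "read_prefix_sequence")]

    truth <- genome$truth
    truth$molecules <- molecules
    truth$barcode_whitelist <- whitelist
    list(reads = reads, truth = truth)
  })
}

#' Simulate a spike-in count matrix with known size factors
#'
#' Host-gene and spike-in rows get latent expected counts; every
#' sample's expectations are multiplied by its true scale factor, and
#' observed counts are Poisson draws around the scaled expectations (or
#' the exact scaled values with `noise = "none"`). Spike-in rows have
#' equal expectations across samples before scaling, which is what makes
#' spike-restricted median-of-ratios normalization recover the factors.
#'
#' @param genes gene table (row count and `gene_id` used).
#' @param true_scale_factors positive per-sample factors (named or not).
#' @param n_spike number of spike-in rows (>= 8).
#' @param config a [sim_config] (seed).
#' @param noise `"poisson"` or `"none"`.
#' @return list with `counts` (matrix, genes then spikes in rows),
#'   `spike_rows` (logical), `true_scale_factors`.
#' @export
simulate_counts <- function(genes, true_scale_factors, n_spike, config,
                            noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(n_spike >= 8, all(true_scale_factors > 0))
  n_samples <- length(true_scale_factors)
  if (is.null(names(true_scale_factors)))
    names(true_scale_factors) <- paste0("sample_", seq_len(n_samples))
  with_seed(config$seed + 3000L, {
    n_genes <- nrow(genes)
    mu_gene <- round(exp(rnorm(n_genes, log(100), 1)))
    mu_spike <- sample(100:1000, n_spike, replace = TRUE)
    mu <- c(mu_gene, mu_spike)
    expected <- outer(mu, true_scale_factors)
    counts <- if (noise == "poisson") {
      matrix(rpois(length(expected), expected), nrow = nrow(expected))
    } else {
      round(expected)
    }
    rn <- c(if (n_genes) genes$gene_id else character(0),
            sprintf("spike_%03d", seq_len(n_spike)))
    dimnames(counts) <- list(rn, names(true_scale_factors))
    list(counts = counts,
         spike_rows = c(rep(FALSE, n_genes), rep(TRUE, n_spike)),
         true_scale_factors = true_scale_factors)
  })
}
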