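# End-to-end orchestration: a single configuration drives
# dedup -> down-sample -> bin/call/merge -> replicate union -> annotate
# -> TRC classification -> summary, with per-stage record counts and a
# machine-readable run summary.

config_param_domains <- function() {
  # name = c(min, max); NA = unbounded
  list(
    bin_size = c(1, NA), threshold = c(0, NA), max_gap = c(0, NA),
    pos_window = c(0, NA), umi_mismatch = c(0, NA), min_mapq = c(0, NA),
    promoter_upstream = c(0, NA), promoter_downstream = c(0, NA),
    assoc_window = c(0, NA), smooth_bins = c(1, NA),
    base_mean_min = c(0, NA), padj_max = c(0, 1), padj_floor = c(0, 1),
    n_control_genes = c(0, NA), extend_fraction = c(0, NA),
    proximal_distance = c(0, NA), track_step = c(1, NA),
    downsample_seed = c(NA, NA)
  )
}

config_input_fields <- function() {
  c("breaks", "chrom_sizes", "genes", "errs", "edu_hu",
    "condition_by_sample", "outdir")
}

#' Default pipeline configuration
#'
#' Every analysis constant is a named entry: 2 kb bins, bin-coverage
#' threshold 22, 2 kb merge gap, 10 bp dedup window with 1 UMI
#' mismatch, MAPQ cutoff 30, TSS -2000/+500 promoter window, 10 kb TRC
#' association window, baseMean threshold 32, padj cutoffs 0.05 (DEG)
#' and 0.5 (controls), 500 control genes, 10% gene extension. Input
#' slots (`breaks`, `chrom_sizes`, `genes`, `errs`, `edu_hu`) accept
#' either in-memory objects or file paths (TSV / BED / bedGraph).
#'
#' @return a named list of class `trcmap_config`.
#' @export
default_config <- function() {
  cfg <- list(
    bin_size = 2000L, threshold = 22L, max_gap = 2000L,
    pos_window = 10L, umi_mismatch = 1L, min_mapq = 30L,
    promoter_upstream = 2000L, promoter_downstream = 500L,
    assoc_window = 10000L, smooth_bins = 5L,
    base_mean_min = 32, padj_max = 0.05, padj_floor = 0.5,
    n_control_genes = 500L, extend_fraction = 0.10,
    proximal_distance = 0L, track_step = 1000L, downsample_seed = 1L,
    breaks = NULL, chrom_sizes = NULL, genes = NULL, errs = NULL,
    edu_hu = NULL, condition_by_sample = NULL, outdir = NULL
  )
  class(cfg) <- "trcmap_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every stage parameter against its documented domain and
#' rejects unknown keys. Violations are returned, not raised.
#'
#' @param config a configuration list (see [default_config()]).
#' @return character vector of violations; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  domains <- config_param_domains()
  known <- c(names(domains), config_input_fields())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    v <- c(v, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  for (p in names(domains)) {
    if (!p %in% names(config) || is.null(config[[p]])) {
      v <- c(v, paste0("missing parameter: ", p))
      next
    }
    val <- config[[p]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val)) {
      v <- c(v, paste0(p, " must be a single number"))
      next
    }
    dom <- domains[[p]]
    if (!is.na(dom[1]) && val < dom[1])
      v <- c(v, paste0(p, " = ", val, " below minimum ", dom[1]))
    if (!is.na(dom[2]) && val > dom[2])
      v <- c(v, paste0(p, " = ", val, " above maximum ", dom[2]))
  }
  v
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly: scalar parameters and input paths are
#' preserved as written.
#'
#' @param path YAML file.
#' @return for `read_config`, a `trcmap_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  viol <- validate_config(cfg)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  cfg
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  keep <- config[!vapply(config, is.null, logical(1))]
  keep <- keep[vapply(keep, function(x)
    is.numeric(x) || is.character(x), logical(1))]
  yaml::write_yaml(keep, path)
  invisible(path)
}

resolve_input <- function(x, reader, ...) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

#' Run the full DSB / TRC analysis pipeline
#'
#' Stages, in order: mapping-quality filter and UMI deduplication per
#' sample; down-sampling to the smallest library; 2 kb binning,
#' coverage thresholding and gap merging into break-enriched regions
#' per sample; union of replicate regions per condition; genomic
#' annotation (promoter / intragenic / extragenic, ERR and transcript
#' overlap, clusters); TRC classification against the EdU-HU track;
#' summaries. Identical configuration and inputs give byte-identical
#' outputs.
#'
#' @param config a `trcmap_config` (see [default_config()]); input
#'   slots may hold objects or file paths. When `outdir` is set,
#'   per-condition region BEDs, an annotated-region TSV, TRC-call TSV
#'   and a `summary.json` are written there.
#' @return the run summary (invisibly a list; also serialized to JSON
#'   when `outdir` is set): per-stage record counts, per-condition
#'   region counts, category fractions, ERR/transcript overlap
#'   fractions, TRC class fractions, and the output-file manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))

  breaks <- resolve_input(config$breaks, read_break_table)
  chrom_sizes <- resolve_input(config$chrom_sizes, read_chrom_sizes)
  genes <- resolve_input(config$genes, read_bed)
  errs <- resolve_input(config$errs, read_bed)
  if (is.null(breaks) || is.null(chrom_sizes))
    stop("config must provide 'breaks' and 'chrom_sizes'")
  edu_hu <- if (is.character(config$edu_hu))
    read_bedgraph(config$edu_hu, chrom_sizes, config$track_step)
  else config$edu_hu
  # BED inputs carry feature ids in the `name` column
  if (!is.null(genes) && !"gene_id" %in% names(genes))
    genes$gene_id <- if ("name" %in% names(genes)) genes$name else
      sprintf("gene_%03d", seq_len(nrow(genes)))
  if (!is.null(genes) && !"expressed" %in% names(genes))
    genes$expressed <- TRUE
  if (!is.null(errs) && !"err_id" %in% names(errs))
    errs$err_id <- if ("name" %in% names(errs)) errs$name else
      sprintf("err_%02d", seq_len(nrow(errs)))

  summary <- list(n_input_reads = nrow(breaks))

  # stage 1: MAPQ filter + dedup per sample
  if (!"sample_id" %in% names(breaks)) breaks$sample_id <- "sample"
  kept <- filter_mapq(breaks, config$min_mapq)
  summary$n_after_mapq <- nrow(kept)
  events <- deduplicate_samples(kept, config$pos_window,
                                config$umi_mismatch, min_mapq = NULL)
  summary$umis_per_sample <- lapply(events, function(e) sum(e$umi_count))

  # stage 2: down-sampling
  if (length(events))
    events <- downsample(events, seed = config$downsample_seed)
  summary$umis_after_downsampling <-
    if (length(events)) sum(events[[1]]$umi_count) else 0

  # stage 3: call regions per sample
  regions_by_sample <- lapply(events, function(e) {
    bins <- bin_coverage(e, chrom_sizes, config$bin_size)
    merge_bins(call_positive_bins(bins, config$threshold), config$max_gap)
  })

  # stage 4: union per condition
  cond_of <- config$condition_by_sample
  if (is.null(cond_of))
    cond_of <- stats::setNames(names(regions_by_sample),
                               names(regions_by_sample))
  conditions <- sort(unique(unname(cond_of[names(regions_by_sample)])))
  regions_by_condition <- stats::setNames(lapply(conditions, function(cc) {
    members <- names(regions_by_sample)[cond_of[names(regions_by_sample)] == cc]
    union_regions(regions_by_sample[members])
  }), conditions)
  summary$regions_per_condition <-
    lapply(regions_by_condition, nrow)
  if (length(conditions) >= 2)
    summary$overlap_matrix <-
      as.data.frame(overlap_matrix(regions_by_condition))

  # stage 5+6: annotation and TRC classification per condition
  annotated <- list()
  trc_calls <- list()
  for (cc in conditions) {
    regs <- regions_by_condition[[cc]]
    ann <- regs
    if (!is.null(genes) && nrow(regs)) {
      ann$category <- annotate_category(regs, genes,
                                        config$promoter_upstream,
                                        config$promoter_downstream)
      expressed <- genes[genes$expressed, , drop = FALSE]
      fo <- flag_overlaps(regs, errs, expressed, config$proximal_distance)
      ann <- cbind(ann, fo$flags)
      ann$cluster <- assign_cluster(fo$flags)
      summary$category_fractions[[cc]] <-
        as.list(prop.table(table(factor(ann$category,
          levels = c("promoter", "intragenic", "extragenic")))))
      summary$overlap_fractions[[cc]] <- as.list(fo$fractions)
      if (!is.null(edu_hu) && !is.null(errs)) {
        calls <- classify_trc(regs, errs, edu_hu, genes,
                              config$assoc_window, config$smooth_bins)
        trc_calls[[cc]] <- calls
        cls <- table(factor(calls$trc_class,
          levels = c("head_on", "co_directional", "unclassified")))
        summary$trc_fractions[[cc]] <- as.list(prop.table(cls))
      }
    }
    annotated[[cc]] <- ann
  }

  # outputs
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- character(0)
    for (cc in conditions) {
      f <- file.path(config$outdir, paste0("regions_", cc, ".bed"))
      regs <- regions_by_condition[[cc]]
      if (nrow(regs)) write_bed(regs, f) else file.create(f)
      manifest <- c(manifest, f)
      fa <- file.path(config$outdir, paste0("annotated_", cc, ".tsv"))
      write_tsv(annotated[[cc]], fa)
      manifest <- c(manifest, fa)
      if (!is.null(trc_calls[[cc]])) {
        ft <- file.path(config$outdir, paste0("trc_", cc, ".tsv"))
        write_tsv(trc_calls[[cc]], ft)
        manifest <- c(manifest, ft)
      }
    }
    summary$manifest <- basename(manifest)
    fs <- file.path(config$outdir, "summary.json")
    jsonlite::write_json(summary, fs, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  structure(summary,
            regions_by_condition = regions_by_condition,
            annotated = annotated, trc_calls = trc_calls)
}
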