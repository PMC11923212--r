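# File interchange: chrom.sizes TSV, BED via rtracklayer, bedGraph via
# rtracklayer, break tables and matrices as TSV, summaries as JSON.

#' Read a two-column chrom.sizes file
#' @param path TSV with chromosome name and length, no header.
#' @return data frame with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  stopifnot(all(df$size > 0))
  df
}

#' Read a BED file into a 0-based half-open interval data frame
#'
#' Uses \pkg{rtracklayer}; BED name/score/strand columns, when present,
#' map to `name`, `score`, `strand`.
#'
#' @param path BED file.
#' @return data frame with `chrom`, `start`, `end` and optional extras.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr_to_df(gr)
}

#' Write intervals to BED
#' @param df interval data frame (0-based half-open); an optional `name`
#'   and numeric `score` column are carried into BED columns 4-5.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  keep <- intersect(names(df), c("chrom", "start", "end", "name", "score", "strand"))
  rtracklayer::export(df_to_gr(df[keep]), path, format = "BED")
  invisible(path)
}

#' Read a bedGraph file into a fixed-step signal track
#' @param path bedGraph file.
#' @inheritParams track_from_intervals
#' @return a [signal_track].
#' @export
read_bedgraph <- function(path, chrom_sizes, step) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track_from_intervals(gr_to_df(gr), chrom_sizes, step)
}

#' Write a signal track as bedGraph
#' @param track a [signal_track].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track_to_granges(track), path, format = "bedGraph")
  invisible(path)
}

#' Read an aligned break-read table
#'
#' Expects a TSV with header and at least the columns `chrom`, `pos`,
#' `strand`, `mapq`, `umi`; `sample_id` is optional (single-sample
#' tables get `sample_id = sample`).
#'
#' @param path TSV file.
#' @return data frame of break records.
#' @export
read_break_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "mapq", "umi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("break table misses column(s): ", paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample"
  df
}

#' @keywords internal
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read unaligned read sequences from FASTA/FASTQ
#'
#' Thin wrapper around \pkg{Biostrings} used to feed
#' [demultiplex_reads()] with raw prefix-carrying sequences.
#'
#' @param path FASTA or FASTQ file.
#' @return character vector of read sequences.
#' @export
read_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA/FASTQ requires the Biostrings package")
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}
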