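#' Write a synthetic cohort to plain-text files
#'
#' Emits the pipeline's interchange files into `dir`: `fragments.tsv`
#' (sample_id, fragment_id, chrom, start, end, mapq, motif4, gc),
#' `methcalls.tsv` (sample_id, fragment_id, region_id, n_cpg, n_meth,
#' conversion_rate), `regions.bed` (0-based half-open BED4),
#' `peaks.csv` (sample_id, size_bp, intensity) and `labels.tsv`
#' (sample_id, group). All files round-trip exactly through the matching
#' `read_*` functions.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fragments = file.path(dir, "fragments.tsv"),
    methcalls = file.path(dir, "methcalls.tsv"),
    regions = file.path(dir, "regions.bed"),
    peaks = file.path(dir, "peaks.csv"),
    labels = file.path(dir, "labels.tsv"))
  write_tsv(cohort$fragments, paths["fragments"])
  write_tsv(cohort$methcalls, paths["methcalls"])
  write_bed(cohort$regions, paths["regions"])
  utils::write.csv(cohort$peaks, paths["peaks"], row.names = FALSE,
                   quote = FALSE)
  write_tsv(cohort$labels, paths["labels"])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_base <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a fragment table
#'
#' @param path Path to a `fragments.tsv` as written by [write_cohort()].
#' @return Data frame of fragment records.
#' @export
read_fragments <- function(path) read_tsv_base(path)

#' Read a per-fragment methylation-call table
#' @param path Path to `methcalls.tsv`.
#' @return Data frame of methylation-call records.
#' @export
read_methcalls <- function(path) read_tsv_base(path)

#' Read group labels
#' @param path Path to `labels.tsv` (columns sample_id, group).
#' @return Data frame with columns `sample_id`, `group`.
#' @export
read_labels <- function(path) read_tsv_base(path)

#' Read an electropherogram peak table
#' @param path Path to a CSV with at least a `size_bp` column.
#' @return Data frame of peaks.
#' @export
read_peaks <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write regions as BED (0-based half-open)
#' @param regions Data frame with columns chrom, start, end and optionally
#'   name.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  utils::write.table(regions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED3/BED4 region file (0-based half-open)
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, `name` (names
#'   autogenerated as `region_<i>` when absent).
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  else df$name <- sprintf("region_%d", seq_len(nrow(df)))
  df[, c("chrom", "start", "end", "name")]
}

#' Write a beta-value matrix with CpG annotation
#'
#' Layout: one row per CpG with columns `cpg_id`, `chrom`, `pos`, then one
#' column per sample.
#'
#' @param beta Matrix (rows = CpGs, columns = samples).
#' @param info Data frame with `cpg_id`, `chrom`, `pos` aligned to rows.
#' @param path Output path.
#' @export
write_beta <- function(beta, info, path) {
  stopifnot(nrow(beta) == nrow(info))
  write_tsv(cbind(info[, c("cpg_id", "chrom", "pos")],
                  as.data.frame(beta, check.names = FALSE)), path)
}

#' Read a beta-value matrix written by [write_beta()]
#' @param path Path to `beta.tsv`.
#' @return List with `beta` (matrix) and `info` (cpg_id, chrom, pos).
#' @export
read_beta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  info <- df[, c("cpg_id", "chrom", "pos")]
  beta <- as.matrix(df[, setdiff(names(df), c("cpg_id", "chrom", "pos")),
                       drop = FALSE])
  rownames(beta) <- info$cpg_id
  list(beta = beta, info = info)
}
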