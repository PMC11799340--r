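.CLINICAL_REQUIRED <- c("patient_id", "tumor_diameter_mm", "ca19_9_u_ml",
                        "os_months", "os_event", "rfs_months", "rfs_event")
.EVENT_TOKENS <- c("0" = 0L, "1" = 1L, "FALSE" = 0L, "TRUE" = 1L,
                   "false" = 0L, "true" = 1L)

#' Read a clinical cohort CSV
#'
#' Validates the required columns, coerces the event flags to 0/1 and
#' the time columns to numeric (reporting the offending line on
#' failure); unknown columns are preserved untouched.
#'
#' @param path CSV file with at least the columns patient_id,
#'   tumor_diameter_mm, ca19_9_u_ml, os_months, os_event, rfs_months,
#'   rfs_event.
#' @return data.frame of typed patient records.
#' @export
readClinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.CLINICAL_REQUIRED, names(df))
  if (length(missing))
    stop("clinical file lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("os_months", "rfs_months", "tumor_diameter_mm",
                "ca19_9_u_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop(sprintf("non-numeric %s at line %d: '%s'", col, bad[1] + 1L,
                   df[[col]][bad[1]]))
    df[[col]] <- v
  }
  for (col in c("os_event", "rfs_event")) {
    tok <- as.character(df[[col]])
    val <- .EVENT_TOKENS[tok]
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("invalid %s value '%s' at line %d; accepted tokens: %s",
                   col, tok[bad[1]], bad[1] + 1L,
                   paste(names(.EVENT_TOKENS), collapse = ", ")))
    df[[col]] <- unname(val)
  }
  df
}

#' Read / write the long allele-count TSV
#'
#' Columns: patient_id, modality (RNA/WES/TS), codon (G12/Q61),
#' mutant_reads, wildtype_reads, other_reads.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readAlleleCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "modality", "codon", "mutant_reads",
            "wildtype_reads", "other_reads")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("allele-count file lacks column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("mutant_reads", "wildtype_reads", "other_reads")) {
    df[[col]] <- as.integer(df[[col]])
    if (any(is.na(df[[col]])) || any(df[[col]] < 0))
      stop("read counts must be non-negative integers (", col, ")")
  }
  df
}

#' @rdname readAlleleCounts
#' @param df data.frame to write.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a copy-number TSV (patient_id, kras_total_copies, optional purity)
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readCopyNumber <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "kras_total_copies") %in% names(df)))
    stop("copy-number file needs patient_id and kras_total_copies")
  df
}

#' Write a synthetic cohort bundle to disk
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    clinical = file.path(dir, "clinical.csv"),
    counts = file.path(dir, "allele_counts.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write.csv(cohort$clinical, paths["clinical"], row.names = FALSE,
            quote = FALSE, na = "")
  writeTsv(cohort$counts, paths["counts"])
  writeTsv(cohort$truth, paths["truth"])
  invisible(paths)
}

#' @importFrom utils write.csv
NULL

#' Load pipeline options from a YAML config file
#'
#' Mirrors the arguments of [runPipeline()]: top-level keys
#' \code{out_dir}, \code{simulate}, \code{clinical}, \code{counts},
#' \code{cn}, \code{cutpoint_mode}, \code{min_group_size}, a
#' \code{thresholds} block ([scoreThresholds()] fields) and a
#' \code{simulation} block ([simulationConfig()] fields). Flags passed
#' to [runPipeline()] directly override the file.
#'
#' @param path YAML file.
#' @return named list of [runPipeline()] arguments.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$out_dir)) args$outDir <- y$out_dir
  if (!is.null(y$simulate)) args$simulate <- isTRUE(y$simulate)
  if (!is.null(y$clinical)) args$clinicalPath <- y$clinical
  if (!is.null(y$counts)) args$countsPath <- y$counts
  if (!is.null(y$cn)) args$cnPath <- y$cn
  if (!is.null(y$cutpoint_mode)) args$cutpointMode <- y$cutpoint_mode
  if (!is.null(y$min_group_size)) args$minGroupSize <- y$min_group_size
  if (!is.null(y$thresholds))
    args$thresholds <- do.call(scoreThresholds, y$thresholds)
  if (!is.null(y$simulation))
    args$config <- do.call(simulationConfig, y$simulation)
  args
}
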