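## Delimited-text dialect for all on-disk tables: tab-separated, UTF-8,
## '.' decimal point, "NA" for missing. Matrices are samples x CpGs with a
## header row of CpG ids and the sample id in the first column.

#' Write a methylation matrix to a delimited text file
#'
#' @param matrix samples-by-CpGs numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix must carry sample rownames and CpG colnames")
  }
  dt <- data.table::data.table(sample_id = rownames(matrix))
  dt <- cbind(dt, data.table::as.data.table(matrix))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a methylation matrix from a delimited text file
#'
#' Values round-trip losslessly with [write_matrix()]. Ragged rows,
#' duplicated CpG or sample identifiers and empty files are parse errors.
#'
#' @param path input file path.
#' @return samples-by-CpGs numeric matrix.
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                          na.strings = "NA")
  if (nrow(dt) == 0) stop("matrix file has no data rows: ", path)
  ids <- as.character(dt[[1]])
  cpgs <- colnames(dt)[-1]
  if (anyDuplicated(cpgs)) {
    stop("duplicate CpG identifiers in header of ", path)
  }
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in ", path)
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(m)) stop("non-numeric matrix entries in ", path)
  dimnames(m) <- list(ids, cpgs)
  m
}

#' Write a cohort table
#'
#' Column dictionary: `sample_id` (character), `age` (years), `sex`
#' (`F`/`M`), `batch` (integer code), `smoking` (smoking score, unitless),
#' `units` (reported units/week), `normal_week_flag`
#' (`normal`/`more`/`less`/`unknown`).
#'
#' @param cohort cohort data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path input file path.
#' @return cohort data.frame with `sex` and `normal_week_flag` as factors.
#' @export
read_cohort <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       na.strings = "NA"))
  if (nrow(d) == 0) stop("cohort file has no data rows: ", path)
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("F", "M"))
  if ("normal_week_flag" %in% names(d)) {
    d$normal_week_flag <- factor(d$normal_week_flag,
                                 levels = c("normal", "more", "less", "unknown"))
  }
  if ("batch" %in% names(d)) d$batch <- factor(d$batch)
  if ("sample_id" %in% names(d)) rownames(d) <- d$sample_id
  d
}

#' Write a run configuration to YAML
#'
#' @param config run configuration list (see [default_run_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path input file path.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
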