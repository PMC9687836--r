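#' Write / read a feature table as TSV
#'
#' Taxa in rows, samples in columns; the first column holds the taxon label.
#' Values are written with 15 significant digits so a write/read round trip
#' is lossless to at least 12 significant digits.
#'
#' @param x numeric matrix, taxa x samples.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(taxon = rownames(x),
                   apply(x, 2, function(col) format(col, digits = 15,
                                                    trim = TRUE,
                                                    scientific = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("taxon", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param kind value for the table's `kind` attribute.
#' @return for the reader: numeric matrix with unique row/column labels.
#' @export
read_feature_table <- function(path, kind = "counts") {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (anyDuplicated(raw[[1]]) > 0)
    stop("duplicate taxon labels in ", path, call. = FALSE)
  if (anyDuplicated(colnames(raw)[-1]) > 0)
    stop("duplicate sample labels in ", path, call. = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at row %d (taxon %s), column %s",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1], raw[[1]][bad[1, 1]],
                 colnames(raw)[bad[1, 2] + 1]), call. = FALSE)
  dimnames(num) <- list(raw[[1]], colnames(raw)[-1])
  attr(num, "kind") <- kind
  num
}

#' Write / read sample metadata as TSV
#'
#' @param metadata data.frame with `sample_id`, `group`, `age`, `bmi`, `sex`,
#'   `extraction_method` (additional columns are preserved).
#' @param path TSV path.
#' @return `path` invisibly (writer); the metadata data.frame (reader).
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample_id) > 0)
    stop("duplicate sample ids in ", path, call. = FALSE)
  md
}

#' Write / read qPCR plate results as CSV
#'
#' Columns `sample_id`, `assay`, `plate`, `ct`; missing Ct encodes no
#' amplification.
#'
#' @param plate data.frame of wells.
#' @param path CSV path.
#' @return `path` invisibly (writer); the plate data.frame (reader).
#' @export
write_qpcr <- function(plate, path) {
  write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a standard-curve dilution series and fit per-assay curves
#'
#' @param path CSV with columns `assay`, `copies`, `ct`.
#' @return named list of [fit_standard_curve()] objects.
#' @export
read_standard_curves <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  curves <- lapply(split(tab, tab$assay),
                   function(d) fit_standard_curve(d$copies, d$ct,
                                                  assay = d$assay[1]))
  curves
}

#' Serialise a match result to JSON
#'
#' @param result a `match_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_match_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
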