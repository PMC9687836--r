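#' Robust per-column scale parameters
#'
#' Median and interquartile range of each column (variables in columns,
#' samples in rows), the location/scale pair used by the robust logistic and
#' tanh transforms. Quantiles use the linear-interpolation convention
#' (`type = 7`); the IQR convention matters because it shifts transformed
#' values.
#'
#' @param x numeric matrix or data.frame, samples x variables.
#' @return an object of class `robust_scale_params` with `median` and `iqr`
#'   vectors named by column.
#' @export
robust_scale_params <- function(x) {
  x <- as.matrix(x)
  structure(list(
    median = apply(x, 2, median),
    iqr = apply(x, 2, function(col)
      diff(quantile(col, c(0.25, 0.75), names = FALSE, type = 7)))
  ), class = "robust_scale_params")
}

check_params <- function(x, params) {
  if (!inherits(params, "robust_scale_params"))
    stop("params must come from robust_scale_params()", call. = FALSE)
  if (ncol(x) != length(params$median))
    stop("params do not match the matrix columns", call. = FALSE)
}

# shared engine for the two robust column transforms; constant columns
# (IQR 0) are passed through untransformed with a warning
robust_transform <- function(x, params, fun) {
  x <- as.matrix(x)
  check_params(x, params)
  out <- x
  const <- params$iqr == 0
  if (any(const))
    warning("constant column(s) passed through untransformed: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  for (j in which(!const))
    out[, j] <- fun((x[, j] - params$median[j]) / params$iqr[j])
  out
}

#' Robust logistic transform of quantitative clinical variables
#'
#' `v = 1 / (1 + exp(-(x - Med_j) / IQR_j))` per column: a median/IQR
#' standardisation pushed through the logistic so outliers are squashed into
#' (0, 1) and the column median maps to 0.5. Binary 0/1 columns should be
#' passed through untouched, not transformed.
#'
#' @param x samples x variables matrix.
#' @param params [robust_scale_params()] fit on the population of interest
#'   (by convention the combined matched case+control set, so both groups
#'   share one map).
#' @return matrix of the same shape with transformed columns in (0, 1).
#' @export
robust_logistic_transform <- function(x, params = robust_scale_params(x)) {
  robust_transform(x, params, function(z) 1 / (1 + exp(-z)))
}

#' Robust tanh transform of qPCR relative concentrations
#'
#' `v = tanh((x - Med_j) / IQR_j)` per column: like the logistic transform but
#' mapping into (-1, 1) with the median at 0.
#'
#' @inheritParams robust_logistic_transform
#' @return matrix of the same shape with transformed columns in (-1, 1).
#' @export
tanh_robust_transform <- function(x, params = robust_scale_params(x)) {
  robust_transform(x, params, tanh)
}

#' log10 transform of nonzero culture abundances
#'
#' Zero entries are retained as zero; nonzero entries become `log10(x)`.
#' Note the map sends both 0 and 1 to 0, and values in (0, 1) to negative
#' numbers; when such values occur a message is logged, since the zero code
#' then collides with genuine abundances.
#'
#' @param x nonnegative matrix of culture/MALDI abundances.
#' @return matrix with zeros retained and nonzero entries log10-transformed.
#' @export
log10_nonzero_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative abundances are not allowed", call. = FALSE)
  nz <- x > 0
  if (any(x[nz] < 1))
    message("log10_nonzero_transform: entries in (0, 1) map to negative ",
            "values and 1 maps to the zero code")
  out <- x
  out[nz] <- log10(x[nz])
  out
}

#' Low-abundance count binning
#'
#' Sampling-noise smoothing of a count table: values below 31 are set to 0,
#' values 31-99 are replaced by 75, values 100-149 by 125, and everything
#' else is left unchanged. Idempotent.
#'
#' @param counts matrix of nonnegative integer counts.
#' @return matrix of the same shape with binned counts.
#' @export
bin_low_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  out <- counts
  out[counts < 31] <- 0
  out[counts >= 31 & counts <= 99] <- 75
  out[counts >= 100 & counts <= 149] <- 125
  out
}
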