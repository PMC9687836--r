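#' Select leading principal components
#'
#' PCA (centred, unscaled, as `prcomp` defaults) followed by selection of the
#' smallest leading set of components whose cumulative explained variance
#' reaches one third of the total, capped at 10 components. When the cap
#' binds before the one-third mark the shortfall is flagged on the result.
#'
#' @param data numeric matrix, samples x variables.
#' @param target_variance cumulative explained-variance goal (default 1/3).
#' @param max_components component cap (default 10).
#' @return list with `scores` (samples x retained components), `loadings`,
#'   `explained` (all variance fractions), `n_components`, and
#'   `shortfall` (TRUE when the cap bound first).
#' @export
select_components <- function(data, target_variance = 1/3,
                              max_components = 10L) {
  data <- as.matrix(data)
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("need at least 2 samples and 2 variables", call. = FALSE)
  pc <- prcomp(data)
  ev <- pc$sdev^2
  if (sum(ev) == 0) stop("degenerate matrix: no variance", call. = FALSE)
  frac <- ev / sum(ev)
  k_needed <- which(cumsum(frac) >= target_variance)[1]
  if (is.na(k_needed)) k_needed <- length(frac)
  k <- min(k_needed, max_components, length(frac))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = frac,
       n_components = k,
       shortfall = k_needed > max_components)
}

#' Two-class linear discriminant axis in component space
#'
#' Fisher's discriminant direction `w ~ Sw^-1 (mu_case - mu_control)` on the
#' retained principal-component scores, with ridge regularisation
#' (`1e-8 * trace`) when the pooled within-group scatter is singular. Sample
#' scores are projections onto the unit axis, and the axis sign is oriented
#' so the case-group mean score is positive (deterministic across runs).
#'
#' @param scores samples x components matrix (from [select_components()]).
#' @param groups group labels for the rows of `scores` (exactly two levels).
#' @param case label treated as the positive class; default the first level.
#' @return an object of class `discriminant_model`: `axis` (unit weight
#'   vector over components), `scores` (per-sample axis scores), `groups`,
#'   `case`, `separation` (standardised mean score difference),
#'   `regularized` flag.
#' @export
fit_discriminant <- function(scores, groups, case = NULL) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) != 2)
    stop("exactly two groups are required", call. = FALSE)
  if (is.null(case)) case <- levs[1]
  if (!case %in% levs) stop("case label not in groups", call. = FALSE)
  ctrl <- setdiff(levs, case)
  if (min(table(groups)) < 2)
    stop("both groups need at least 2 samples", call. = FALSE)
  if (ncol(scores) >= nrow(scores) - 1)
    stop("components must be fewer than samples - 1", call. = FALSE)
  xc <- scores[groups == case, , drop = FALSE]
  xk <- scores[groups == ctrl, , drop = FALSE]
  sw <- crossprod(sweep(xc, 2, colMeans(xc))) +
        crossprod(sweep(xk, 2, colMeans(xk)))
  delta <- colMeans(xc) - colMeans(xk)
  regularized <- FALSE
  w <- tryCatch(solve(sw, delta), error = function(e) NULL)
  if (is.null(w) || rcond(sw) < 1e-12) {
    eps <- 1e-8 * sum(diag(sw))
    if (eps == 0) eps <- 1e-8
    w <- solve(sw + diag(eps, ncol(sw)), delta)
    regularized <- TRUE
  }
  w <- w / sqrt(sum(w^2))
  ax_scores <- drop(scores %*% w)
  if (mean(ax_scores[groups == case]) < mean(ax_scores[groups == ctrl])) {
    w <- -w
    ax_scores <- -ax_scores
  }
  pooled_sd <- sqrt((sum((ax_scores[groups == case] -
                            mean(ax_scores[groups == case]))^2) +
                     sum((ax_scores[groups == ctrl] -
                            mean(ax_scores[groups == ctrl]))^2)) /
                    (length(ax_scores) - 2))
  sep <- if (pooled_sd > 0)
    (mean(ax_scores[groups == case]) - mean(ax_scores[groups == ctrl])) /
      pooled_sd
  else Inf
  structure(list(axis = w, scores = ax_scores, groups = groups, case = case,
                 separation = sep, regularized = regularized),
            class = "discriminant_model")
}

#' Spearman attribution of original variables to the discriminant axis
#'
#' Correlates each original variable with the per-sample discriminant axis
#' scores (Spearman); variables with `|rho|` at or above the threshold are
#' flagged as discriminant-associated. Constant variables get a missing rho.
#'
#' @param model a [fit_discriminant()] result.
#' @param original samples x variables matrix of the untransformed (or
#'   transformed, caller's choice) input variables, rows aligned with the
#'   model's samples.
#' @param threshold absolute-rho cutoff (default 0.3).
#' @return data.frame `variable`, `rho`, `flagged`.
#' @export
correlate_axis <- function(model, original, threshold = 0.3) {
  original <- as.matrix(original)
  if (nrow(original) != length(model$scores))
    stop("original rows must align with model scores", call. = FALSE)
  rho <- vapply(seq_len(ncol(original)), function(j) {
    v <- original[, j]
    if (length(unique(v)) == 1) return(NA_real_)
    suppressWarnings(cor(v, model$scores, method = "spearman"))
  }, numeric(1))
  data.frame(variable = colnames(original), rho = rho,
             flagged = !is.na(rho) & abs(rho) >= threshold,
             stringsAsFactors = FALSE)
}

#' Batch (extraction-method) effect check via PCA + LDA
#'
#' Fits the component subspace and a discriminant axis with the batch label
#' (e.g., extraction kit FS vs PF) as the class, and tests axis separation by
#' permuting batch labels and refitting the axis each time. Recommends
#' combining batches when the permutation p is at or above alpha, and
#' stratifying otherwise.
#'
#' @param data samples x variables matrix.
#' @param batch batch label per sample.
#' @param n_perm number of label permutations (default 10000).
#' @param alpha decision level (default 0.05).
#' @param seed integer RNG seed.
#' @return list with `p`, `statistic` (standardised separation),
#'   `recommendation` ("combine" or "stratify"), and the fitted `model`
#'   (NULL for a single batch).
#' @export
method_effect_check <- function(data, batch, n_perm = 10000L, alpha = 0.05,
                                seed = 1L) {
  batch <- as.character(batch)
  if (length(unique(batch)) < 2)
    return(list(p = 1, statistic = 0, recommendation = "combine",
                model = NULL))
  comp <- select_components(data)
  model <- fit_discriminant(comp$scores, batch)
  obs <- abs(model$separation)
  set.seed(seed)
  exceed <- sum(vapply(seq_len(n_perm), function(i) {
    perm <- sample(batch)
    m <- tryCatch(fit_discriminant(comp$scores, perm),
                  error = function(e) NULL)
    !is.null(m) && abs(m$separation) >= obs - 1e-12
  }, logical(1)))
  p <- (1 + exceed) / (1 + n_perm)
  list(p = p, statistic = obs,
       recommendation = if (p >= alpha) "combine" else "stratify",
       model = model)
}
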