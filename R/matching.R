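#' Matching configuration
#'
#' Thresholds for covariate-convergence matching: group mean differences in
#' the two matching variables must not exceed `t_j` (age, years) and `t_k`
#' (BMI, kg/m^2). Defaults are the study constraint of 15 years and 3 kg/m^2.
#'
#' @param var_j,var_k metadata column names of the two matching variables.
#' @param t_j,t_k convergence thresholds in the variables' units (> 0).
#' @param min_group_size guard: no group is trimmed below this size (>= 2).
#' @param corrected use the sign-corrected variant of the equal-size trimming
#'   rule (see [match_algorithm_II()]); default FALSE (rule as originally stated).
#' @return an object of class `match_config`.
#' @export
match_config <- function(var_j = "age", var_k = "bmi", t_j = 15, t_k = 3,
                         min_group_size = 5L, corrected = FALSE) {
  if (t_j <= 0 || t_k <= 0) stop("thresholds must be > 0", call. = FALSE)
  if (min_group_size < 2) stop("min_group_size must be >= 2", call. = FALSE)
  structure(list(var_j = var_j, var_k = var_k, t_j = t_j, t_k = t_k,
                 min_group_size = as.integer(min_group_size),
                 corrected = isTRUE(corrected)),
            class = "match_config")
}

#' Signed difference of group means
#'
#' @param a,b numeric vectors of the matching variable for the two groups.
#' @return `mean(a) - mean(b)` in the variable's units.
#' @export
mean_difference <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("missing values must be filtered before matching", call. = FALSE)
  mean(a) - mean(b)
}

# index of extremum with deterministic tie-break: among tied values, the
# sample with the lexicographically smallest id is removed
which_extreme <- function(x, maximum) {
  target <- if (maximum) max(x) else min(x)
  cand <- which(x == target)
  if (length(cand) > 1) cand <- cand[order(names(x)[cand])[1]]
  cand
}

new_match_result <- function(retained, removed, d_j, d_k, algorithm,
                             converged, diverged = FALSE) {
  structure(list(retained = retained, removed = removed, d_j = d_j, d_k = d_k,
                 algorithm = algorithm, converged = converged,
                 diverged = diverged),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Covariate-convergence match (algorithm ", x$algorithm, ")\n",
      "  converged: ", x$converged,
      if (x$diverged) "  [divergence logged]" else "", "\n",
      "  removed: ", nrow(x$removed), " samples\n",
      "  final d_j = ", format(x$d_j, digits = 4),
      ", d_k = ", format(x$d_k, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Convergence trimming for unequal group sizes, one variable
#'
#' Iteratively removes from the larger group A its maximum of the matching
#' variable when the mean difference `d = mean(A) - mean(B)` is positive, and
#' its minimum when negative, recomputing `d` each step, until `|d|` falls to
#' the threshold or the size guard triggers.
#'
#' @param a,b named numeric vectors (names are sample ids) of the matching
#'   variable; `a` must be the larger group.
#' @param t_j convergence threshold (> 0).
#' @param min_group_size stop trimming when `length(a)` reaches this size.
#' @return a `match_result` with retained/removed ids, final difference and a
#'   `converged` flag.
#' @export
match_algorithm_I <- function(a, b, t_j, min_group_size = 5L) {
  if (length(a) <= length(b))
    stop("algorithm I requires the first group to be larger", call. = FALSE)
  removed <- data.frame(step = integer(0), sample_id = character(0),
                        from = character(0), value = numeric(0),
                        stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    d <- mean_difference(a, b)
    if (abs(d) <= t_j)
      return(new_match_result(list(A = names(a), B = names(b)), removed,
                              d_j = d, d_k = NA_real_, "I", converged = TRUE))
    if (length(a) <= min_group_size)
      return(new_match_result(list(A = names(a), B = names(b)), removed,
                              d_j = d, d_k = NA_real_, "I", converged = FALSE))
    step <- step + 1L
    i <- which_extreme(a, maximum = d > 0)
    removed <- rbind(removed, data.frame(step = step,
                                         sample_id = names(a)[i],
                                         from = "A", value = a[[i]],
                                         stringsAsFactors = FALSE))
    a <- a[-i]
  }
}

#' Convergence trimming for equal group sizes, one variable
#'
#' The rule as originally stated: when `d = mean(A) - mean(B) > 0`, A loses
#' its minimum and B its maximum; when `d < 0`, A loses its maximum and B its
#' minimum. Note this moves the means apart; the stated rule diverges
#' whenever trimming can change the means. `corrected = TRUE`
#' applies the sign-flipped (convergent) variant: `d > 0` removes A's maximum
#' and B's minimum. Divergence (|d| increasing between steps) is logged, and
#' the size guard terminates the loop.
#'
#' @inheritParams match_algorithm_I
#' @param corrected use the sign-flipped convergent variant.
#' @return a `match_result`; `diverged` is TRUE when |d| ever increased.
#' @export
match_algorithm_II <- function(a, b, t_j, min_group_size = 5L,
                               corrected = FALSE) {
  if (length(a) != length(b))
    stop("algorithm II requires equal group sizes", call. = FALSE)
  removed <- data.frame(step = integer(0), sample_id = character(0),
                        from = character(0), value = numeric(0),
                        stringsAsFactors = FALSE)
  step <- 0L
  diverged <- FALSE
  prev_abs <- Inf
  repeat {
    d <- mean_difference(a, b)
    if (abs(d) > prev_abs) diverged <- TRUE
    prev_abs <- abs(d)
    if (abs(d) <= t_j)
      return(new_match_result(list(A = names(a), B = names(b)), removed,
                              d_j = d, d_k = NA_real_, "II",
                              converged = TRUE, diverged = diverged))
    if (length(a) <= min_group_size || length(b) <= min_group_size)
      return(new_match_result(list(A = names(a), B = names(b)), removed,
                              d_j = d, d_k = NA_real_, "II",
                              converged = FALSE, diverged = diverged))
    a_max <- if (d > 0) corrected else !corrected
    step <- step + 1L
    ia <- which_extreme(a, maximum = a_max)
    ib <- which_extreme(b, maximum = !a_max)
    removed <- rbind(removed,
                     data.frame(step = step,
                                sample_id = c(names(a)[ia], names(b)[ib]),
                                from = c("A", "B"),
                                value = c(a[[ia]], b[[ib]]),
                                stringsAsFactors = FALSE))
    a <- a[-ia]
    b <- b[-ib]
  }
}

#' Medoid of a point set
#'
#' The member minimising the sum of Euclidean distances to all members of the
#' same set. Ties broken by smallest row name.
#'
#' @param m numeric matrix, observations in rows (row names are sample ids).
#' @return row name of the medoid.
#' @export
medoid <- function(m) {
  dd <- as.matrix(stats::dist(m))
  sums <- rowSums(dd)
  cand <- which(sums == min(sums))
  if (length(cand) > 1) cand <- cand[order(rownames(m)[cand])[1]]
  rownames(m)[cand]
}

#' Convergence trimming for unequal group sizes, two variables
#'
#' Both variables are standardised by the pooled (both groups) mean and SD so
#' age and BMI live in one coordinate frame. The smaller group B contributes
#' its medoid; the observation of the larger group A farthest (Euclidean, in
#' standardised space) from that medoid is excluded, repeatedly, until both
#' mean differences fall to their thresholds, a removal fails to decrease
#' `max(d_j/t_j, d_k/t_k)`, or the size guard triggers.
#'
#' @param a,b numeric matrices with two columns (the matching variables) and
#'   sample ids as row names; `a` must be the larger group.
#' @param t_j,t_k thresholds for the first and second column respectively.
#' @param min_group_size size guard on group A.
#' @return a `match_result` with both final differences.
#' @export
match_algorithm_III <- function(a, b, t_j, t_k, min_group_size = 5L) {
  if (nrow(a) <= nrow(b))
    stop("algorithm III requires the first group to be larger", call. = FALSE)
  pooled <- rbind(a, b)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  if (any(sdv == 0))
    stop("matching variable constant across all samples", call. = FALSE)
  za <- sweep(sweep(a, 2, mu), 2, sdv, "/")
  zb <- sweep(sweep(b, 2, mu), 2, sdv, "/")
  med_id <- medoid(zb)
  med <- zb[med_id, ]
  removed <- data.frame(step = integer(0), sample_id = character(0),
                        from = character(0), value = numeric(0),
                        stringsAsFactors = FALSE)
  diffs <- function(a, b) c(abs(mean(a[, 1]) - mean(b[, 1])),
                            abs(mean(a[, 2]) - mean(b[, 2])))
  step <- 0L
  repeat {
    d <- diffs(a, b)
    if (d[1] <= t_j && d[2] <= t_k)
      return(new_match_result(list(A = rownames(a), B = rownames(b)), removed,
                              d_j = d[1], d_k = d[2], "III", converged = TRUE))
    if (nrow(a) <= min_group_size)
      return(new_match_result(list(A = rownames(a), B = rownames(b)), removed,
                              d_j = d[1], d_k = d[2], "III",
                              converged = FALSE))
    # futility guard: stop when no single exclusion can decrease the worst
    # threshold ratio max(d_j/t_j, d_k/t_k)
    n_a <- nrow(a)
    mean_j_after <- (n_a * mean(a[, 1]) - a[, 1]) / (n_a - 1)
    mean_k_after <- (n_a * mean(a[, 2]) - a[, 2]) / (n_a - 1)
    ratios_after <- pmax(abs(mean_j_after - mean(b[, 1])) / t_j,
                         abs(mean_k_after - mean(b[, 2])) / t_k)
    if (min(ratios_after) >= max(d / c(t_j, t_k)))
      return(new_match_result(list(A = rownames(a), B = rownames(b)), removed,
                              d_j = d[1], d_k = d[2], "III",
                              converged = FALSE, diverged = TRUE))
    dist_to_med <- sqrt(rowSums(sweep(za, 2, med)^2))
    cand <- which(dist_to_med == max(dist_to_med))
    if (length(cand) > 1) cand <- cand[order(rownames(a)[cand])[1]]
    step <- step + 1L
    removed <- rbind(removed, data.frame(step = step,
                                         sample_id = rownames(a)[cand],
                                         from = "A",
                                         value = dist_to_med[cand],
                                         stringsAsFactors = FALSE))
    a <- a[-cand, , drop = FALSE]
    za <- za[-cand, , drop = FALSE]
  }
}

#' Match a case group to a control group on age and BMI
#'
#' Dispatches to one of the three convergence algorithms by the applicability
#' conditions: thresholds already met (identity); unequal sizes with one
#' variable violated (algorithm I on that variable, the larger group trimmed);
#' unequal sizes with both violated (algorithm III); equal sizes with one
#' violated (algorithm II). Equal sizes with both variables violated at entry
#' has no defined algorithm and raises an error. Because trimming on one
#' variable can push the other variable past its threshold, dispatch is
#' repeated on the retained sets until both thresholds hold (converged) or an
#' algorithm stops without convergence; `converged = TRUE` therefore
#' guarantees both final differences are within their thresholds. Samples
#' with missing matching variables are excluded beforehand with a warning.
#'
#' @param disease,control data.frames of sample metadata (rows of the two
#'   groups), each with `sample_id` and the matching variable columns.
#' @param config a [match_config()].
#' @return a `match_result`; `retained` is a list with elements `disease` and
#'   `control` of sample ids, `algorithm` concatenates the rounds applied
#'   (e.g. "I" or "III+I"), and both final mean differences `d_j` (var_j) and
#'   `d_k` (var_k) are reported.
#' @export
match_pair <- function(disease, control, config = match_config()) {
  pull <- function(df, var) setNames(df[[var]], df$sample_id)
  drop_missing <- function(df, label) {
    ok <- complete.cases(df[, c(config$var_j, config$var_k)])
    if (!all(ok))
      warning(sum(!ok), " ", label,
              " sample(s) with missing matching variables excluded",
              call. = FALSE)
    df[ok, , drop = FALSE]
  }
  disease <- drop_missing(disease, "disease")
  control <- drop_missing(control, "control")
  if (nrow(disease) == 0 || nrow(control) == 0)
    stop("a group is empty after removing missing values", call. = FALSE)

  gaps <- function(dis, ctl) {
    c(mean_difference(pull(dis, config$var_j), pull(ctl, config$var_j)),
      mean_difference(pull(dis, config$var_k), pull(ctl, config$var_k)))
  }

  removed_all <- data.frame(step = integer(0), sample_id = character(0),
                            from = character(0), value = numeric(0),
                            stringsAsFactors = FALSE)
  algs <- character(0)
  diverged <- FALSE
  converged <- TRUE
  entry <- TRUE

  repeat {
    d <- gaps(disease, control)
    vj <- abs(d[1]) > config$t_j
    vk <- abs(d[2]) > config$t_k
    if (!vj && !vk) {
      converged <- TRUE
      break
    }
    n <- nrow(disease)
    m <- nrow(control)
    if (n == m && vj && vk) {
      if (entry)
        stop("no algorithm applicable: equal group sizes with both matching ",
             "variables violated", call. = FALSE)
      converged <- FALSE
      break
    }
    a_is_disease <- n >= m
    big <- if (a_is_disease) disease else control
    small <- if (a_is_disease) control else disease
    if (n != m && vj && vk) {
      mat <- function(df) {
        mm <- as.matrix(df[, c(config$var_j, config$var_k)])
        rownames(mm) <- df$sample_id
        mm
      }
      res <- match_algorithm_III(mat(big), mat(small), config$t_j,
                                 config$t_k, config$min_group_size)
    } else {
      var <- if (vj) config$var_j else config$var_k
      thr <- if (vj) config$t_j else config$t_k
      res <- if (n != m) {
        match_algorithm_I(pull(big, var), pull(small, var), thr,
                          config$min_group_size)
      } else {
        match_algorithm_II(pull(disease, var), pull(control, var), thr,
                           config$min_group_size, config$corrected)
      }
    }
    entry <- FALSE
    algs <- c(algs, res$algorithm)
    diverged <- diverged || res$diverged
    if (nrow(res$removed) > 0) {
      res$removed$step <- res$removed$step + nrow(removed_all)
      removed_all <- rbind(removed_all, res$removed)
    }
    keep_a <- res$retained$A
    keep_b <- res$retained$B
    disease <- disease[disease$sample_id %in%
                         (if (a_is_disease) keep_a else keep_b), ,
                       drop = FALSE]
    control <- control[control$sample_id %in%
                         (if (a_is_disease) keep_b else keep_a), ,
                       drop = FALSE]
    if (!res$converged) {
      converged <- FALSE
      break
    }
    if (nrow(res$removed) == 0) {
      # no progress is possible; avoid an infinite dispatch loop
      converged <- FALSE
      break
    }
  }

  d <- gaps(disease, control)
  new_match_result(
    list(disease = disease$sample_id, control = control$sample_id),
    removed_all, d_j = d[1], d_k = d[2],
    algorithm = if (length(algs) == 0) "none"
                else paste(algs, collapse = "+"),
    converged = converged, diverged = diverged)
}
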