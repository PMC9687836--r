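#' Mann-Whitney test with a Monte Carlo p-value
#'
#' Computes the Mann-Whitney U (midranks for ties) and estimates the
#' two-sided p-value by random permutation of group labels, with the add-one
#' correction `p = (1 + #extreme) / (1 + n_sim)` so p is never zero and valid
#' at any simulation count. Extremeness is `|U - nm/2| >= |U_obs - nm/2|`.
#'
#' @param x,y case and control values.
#' @param n_sim number of label permutations (the full-scale convention is
#'   1e6).
#' @param seed integer RNG seed.
#' @return list with `U` (case-side U statistic), `p`.
#' @export
mann_whitney_mc <- function(x, y, n_sim = 1e6, seed = 1L) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  obs_dev <- abs(sum(r[seq_len(n)]) - n * (n + m + 1) / 2)
  set.seed(seed)
  exceed <- mc_ranksum_exceed(r, n, as.integer(n_sim), obs_dev)
  list(U = u, p = (1 + exceed) / (1 + n_sim))
}

#' Rank eta-squared effect size
#'
#' `eta^2 = (H - k + 1) / (n - k)` with H the (tie-corrected) Kruskal-Wallis
#' statistic, k the number of groups and n the total observations. Near the
#' null the estimate can be slightly negative; it is reported unclamped, with
#' `clamp = TRUE` available for display.
#'
#' @param h Kruskal-Wallis statistic.
#' @param k number of groups (>= 2).
#' @param n total number of observations (> k).
#' @param clamp truncate negative estimates at 0.
#' @return effect size estimate.
#' @export
effect_size_eta2 <- function(h, k, n, clamp = FALSE) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n <= k) stop("n must exceed k", call. = FALSE)
  e <- (h - k + 1) / (n - k)
  if (clamp) max(0, e) else e
}

#' Fisher-type Monte Carlo test for a 2x2 table
#'
#' Samples tables with the observed margins (hypergeometric) and computes a
#' two-sided p by the point-probability criterion: the fraction of sampled
#' tables whose probability under the null is no larger than the observed
#' table's, with the add-one correction.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param n_sim number of sampled tables.
#' @param seed integer RNG seed.
#' @return list with `p` and `degenerate` (TRUE when a margin is zero, in
#'   which case p = 1).
#' @export
fisher_mc <- function(table, n_sim = 1e6, seed = 1L) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table)))
    stop("table must be a 2x2 matrix of nonnegative integers", call. = FALSE)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    return(list(p = 1, degenerate = TRUE))
  # point probability depends only on the top-left cell given the margins
  logp <- function(a) dhyper(a, cs[1], cs[2], rs[1], log = TRUE)
  obs <- logp(table[1, 1])
  set.seed(seed)
  sims <- r2dtable(as.integer(n_sim), rs, cs)
  a_sim <- vapply(sims, function(t) t[1, 1], numeric(1))
  exceed <- sum(logp(a_sim) <= obs + 1e-9)
  list(p = (1 + exceed) / (1 + n_sim), degenerate = FALSE)
}

#' Phi (mean square contingency) coefficient
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` for a 2x2 table; NA when
#' any margin is zero.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return phi in `[-1, 1]`, or NA.
#' @export
phi_coefficient <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  denom <- sqrt((a + b) * (c + d) * (a + c) * (b + d))
  if (denom == 0) return(NA_real_)
  (a * d - b * c) / denom
}

#' Benjamini-Yekutieli adjustment
#'
#' FDR control valid under arbitrary dependence: the step-up procedure with
#' the harmonic-sum inflation factor `c(m) = sum(1/i)`. By the study's
#' convention, the correction pool spans all tests of a comparison across
#' platforms; callers decide the pool.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, order-preserving, capped at 1.
#' @export
benjamini_yekutieli <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BY")
}

#' Per-feature case-control comparison
#'
#' For each feature (row of the table): Mann-Whitney with a Monte Carlo
#' p-value, rank eta-squared from the tie-corrected Kruskal-Wallis H, and a
#' direction arrow from the median difference (mean as tie-break), with
#' Benjamini-Yekutieli adjustment over the feature pool (optionally extended
#' with externally supplied p-values when the correction pool spans
#' platforms). Features constant across all samples are skipped with a
#' message.
#'
#' @param table numeric matrix, features x samples.
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param case,control group labels to compare.
#' @param n_sim Monte Carlo simulations per feature.
#' @param seed integer RNG seed (advanced per feature for independence).
#' @param extra_p optional numeric vector of additional raw p-values included
#'   in the adjustment pool (their adjusted values are not returned).
#' @return data.frame with columns `feature`, `direction` ("increased" /
#'   "decreased" relative to control), `U`, `H`, `eta_squared`, `p_raw`,
#'   `p_adjusted`, `n_case`, `n_control`.
#' @export
compare_groups <- function(table, metadata, case, control, n_sim = 1e4,
                           seed = 1L, extra_p = NULL) {
  for (lab in c(case, control))
    if (!lab %in% metadata$group)
      stop("group label not present in metadata: ", lab, call. = FALSE)
  case_ids <- intersect(metadata$sample_id[metadata$group == case],
                        colnames(table))
  ctrl_ids <- intersect(metadata$sample_id[metadata$group == control],
                        colnames(table))
  if (length(case_ids) == 0 || length(ctrl_ids) == 0)
    stop("no samples of a compared group in the table", call. = FALSE)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    x <- table[i, case_ids]
    y <- table[i, ctrl_ids]
    if (length(unique(c(x, y))) == 1) {
      message("skipping constant feature: ", rownames(table)[i])
      return(NULL)
    }
    mw <- mann_whitney_mc(x, y, n_sim = n_sim, seed = seed + i)
    kw <- suppressWarnings(
      kruskal.test(c(x, y), factor(rep(c("case", "ctrl"),
                                       c(length(x), length(y))))))
    h <- unname(kw$statistic)
    md <- median(x) - median(y)
    if (md == 0) md <- mean(x) - mean(y)
    data.frame(feature = rownames(table)[i],
               direction = if (md >= 0) "increased" else "decreased",
               U = mw$U, H = h,
               eta_squared = effect_size_eta2(h, 2, length(x) + length(y)),
               p_raw = mw$p,
               n_case = length(x), n_control = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all features constant; nothing to test",
                         call. = FALSE)
  pool <- c(out$p_raw, extra_p)
  out$p_adjusted <- benjamini_yekutieli(pool)[seq_len(nrow(out))]
  rownames(out) <- NULL
  out[, c("feature", "direction", "U", "H", "eta_squared", "p_raw",
          "p_adjusted", "n_case", "n_control")]
}

#' Significance band for reporting
#'
#' Maps adjusted p-values to the bands used in summary tables:
#' "<0.001", "<0.01", "<0.05", "ns".
#'
#' @param p adjusted p-values.
#' @return character vector of bands.
#' @export
p_band <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("<0.001", "<0.01", "<0.05", "ns"),
                   right = FALSE))
}
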