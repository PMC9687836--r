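test_that("Monte Carlo Mann-Whitney matches exact enumeration", {
  # canonical separated case: exact two-sided p = 2/20
  res <- mann_whitney_mc(1:3, 4:6, n_sim = 1e4, seed = 1)
  expect_equal(exact_mw_p(1:3, 4:6), 0.1)
  expect_lt(abs(res$p - 0.1), 3 * sqrt(0.1 * 0.9 / 1e4) + 2e-4)
  expect_equal(res$U, 0)

  # random small instances against the exhaustive oracle
  set.seed(77)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    m <- sample(3:6, 1)
    x <- sample(1:8, n, replace = TRUE)  # replace=TRUE exercises ties
    y <- sample(1:8, m, replace = TRUE)
    p_exact <- exact_mw_p(x, y)
    res <- mann_whitney_mc(x, y, n_sim = 4000, seed = i)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$p - p_exact), 4 * se + 5e-4)
  }
})

test_that("MC p-values carry the add-one correction and never reach zero", {
  res <- mann_whitney_mc(1:10, 101:110, n_sim = 500, seed = 1)
  expect_gte(res$p, 1 / 501)
  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_gte(fisher_mc(tab, n_sim = 500, seed = 1)$p, 1 / 501)
})

test_that("identically distributed groups give large p", {
  set.seed(3)
  pool <- rnorm(40)
  res <- mann_whitney_mc(pool[1:20], pool[21:40], n_sim = 5000, seed = 2)
  expect_gt(res$p, 0.05)
})

test_that("rank eta-squared follows the plug-in formula", {
  expect_equal(effect_size_eta2(1, 2, 12), 0)        # H = k - 1
  expect_equal(effect_size_eta2(3.2, 2, 12), 0.22)
  expect_error(effect_size_eta2(3, 2, 2), "exceed")
  # may be negative near the null; clamped display option
  expect_lt(effect_size_eta2(0.5, 2, 12), 0)
  expect_equal(effect_size_eta2(0.5, 2, 12, clamp = TRUE), 0)

  # complete separation: H computed from rank arithmetic by hand
  x <- 1:10
  y <- 11:20
  n <- 20
  r <- rank(c(x, y))
  h_hand <- 12 / (n * (n + 1)) *
    (sum(r[1:10])^2 / 10 + sum(r[11:20])^2 / 10) - 3 * (n + 1)
  h_pkg <- unname(kruskal.test(c(x, y),
                               rep(c("a", "b"), each = 10))$statistic)
  expect_equal(h_pkg, h_hand)  # no ties, so no tie correction
  expect_equal(effect_size_eta2(h_pkg, 2, 20), (h_hand - 1) / 18)
})

test_that("Fisher MC test matches the exact hypergeometric point-probability p", {
  balanced <- matrix(c(5, 5, 5, 5), 2)
  expect_gt(fisher_mc(balanced, n_sim = 2000, seed = 1)$p, 0.9)

  extreme <- matrix(c(10, 0, 0, 10), 2)
  p_exact <- 2 / choose(20, 10)
  res <- fisher_mc(extreme, n_sim = 1e5, seed = 2)
  expect_lt(abs(res$p - p_exact), 4 * sqrt(p_exact / 1e5) + 2 / 1e5)

  set.seed(55)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    p_exact <- exact_fisher_p(tab)
    res <- fisher_mc(tab, n_sim = 4000, seed = i)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$p - p_exact), 4 * se + 1e-3)
  }

  degen <- matrix(c(0, 0, 3, 4), 2)
  out <- fisher_mc(degen, n_sim = 100, seed = 1)
  expect_true(out$degenerate)
  expect_equal(out$p, 1)
})

test_that("phi coefficient matches hand arithmetic", {
  expect_equal(phi_coefficient(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(phi_coefficient(matrix(c(5, 5, 5, 5), 2)), 0)
  expect_equal(phi_coefficient(matrix(c(8, 3, 2, 7), 2)),
               50 / sqrt(10 * 10 * 11 * 9))
  expect_true(is.na(phi_coefficient(matrix(c(0, 0, 5, 5), 2))))
})

test_that("Benjamini-Yekutieli equals the direct step-up computation", {
  expect_equal(benjamini_yekutieli(0.02), 0.02)
  expect_equal(benjamini_yekutieli(c(0.01, 0.04)), c(0.03, 0.06))
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    adj <- benjamini_yekutieli(p)
    expect_equal(adj, by_stepup(p))
    # dominates Benjamini-Hochberg and preserves order
    expect_true(all(adj >= p.adjust(p, "BH") - 1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
  # invariant to input order
  p <- runif(15)
  perm <- sample(15)
  expect_equal(benjamini_yekutieli(p)[perm], benjamini_yekutieli(p[perm]))
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("compare_groups recovers a planted effect with the right arrow", {
  md <- toy_metadata(rnorm(30, 60, 5), rnorm(30, 58, 5))
  set.seed(10)
  tab <- matrix(rlnorm(20 * 60, 3, 0.5), nrow = 20,
                dimnames = list(sprintf("F%02d", 1:20), md$sample_id))
  tab["F03", md$group == "Disease"] <- tab["F03", md$group == "Disease"] * 4
  tab["F07", md$group == "Disease"] <- tab["F07", md$group == "Disease"] / 4
  res <- compare_groups(tab, md, "Disease", "Control", n_sim = 5000, seed = 1)
  f03 <- res[res$feature == "F03", ]
  f07 <- res[res$feature == "F07", ]
  expect_equal(f03$direction, "increased")
  expect_equal(f07$direction, "decreased")
  expect_lt(f03$p_adjusted, 0.05)
  expect_lt(f07$p_adjusted, 0.05)
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12))
  expect_gt(f03$eta_squared, 0.1)
})

test_that("compare_groups skips constant features and honours the pool", {
  md <- toy_metadata(rnorm(10, 60, 5), rnorm(10, 58, 5))
  tab <- rbind(const = rep(1, 20),
               varies = c(rnorm(10, 5), rnorm(10, 9)))
  colnames(tab) <- md$sample_id
  expect_message(res <- compare_groups(tab, md, "Disease", "Control",
                                       n_sim = 1000, seed = 1),
                 "constant")
  expect_equal(res$feature, "varies")
  # extending the correction pool can only raise the adjusted p
  res2 <- compare_groups(tab, md, "Disease", "Control", n_sim = 1000,
                         seed = 1, extra_p = runif(20))
  expect_gte(res2$p_adjusted, res$p_adjusted)
  expect_error(compare_groups(tab, md, "Disease", "NoSuchGroup"),
               "NoSuchGroup")
})

test_that("p bands split at the reporting thresholds", {
  expect_equal(p_band(c(0.0005, 0.005, 0.04, 0.2)),
               c("<0.001", "<0.01", "<0.05", "ns"))
})
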