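test_that("mean_difference is the signed difference of group means", {
  expect_equal(mean_difference(c(60, 70), 65), 0)
  expect_equal(mean_difference(c(60, 70, 80), 55), 15)
  expect_error(mean_difference(numeric(0), 55), "nonempty")
  expect_error(mean_difference(c(60, NA), 55), "missing")
})

test_that("algorithm I trims the larger group's extremes until convergence", {
  a <- c(D1 = 60, D2 = 70, D3 = 82)
  b <- c(C1 = 55)
  res <- match_algorithm_I(a, b, t_j = 15, min_group_size = 2)
  expect_true(res$converged)
  expect_identical(res$removed$sample_id, "D3")
  expect_setequal(res$retained$A, c("D1", "D2"))
  expect_equal(res$d_j, 10)

  # already within threshold: zero removals
  res0 <- match_algorithm_I(c(D1 = 60, D2 = 62), c(C1 = 61), t_j = 15,
                            min_group_size = 2)
  expect_equal(nrow(res0$removed), 0)
  expect_setequal(res0$retained$A, c("D1", "D2"))

  # constant larger group: mean never moves, guard flags non-convergence
  ac <- setNames(rep(60, 6), sprintf("D%d", 1:6))
  resc <- match_algorithm_I(ac, c(C1 = 20), t_j = 10, min_group_size = 5)
  expect_false(resc$converged)
  expect_equal(length(resc$retained$A), 5)
})

test_that("removal order replays to the retained set", {
  set.seed(9)
  a <- setNames(rnorm(20, 68, 8), sprintf("D%02d", 1:20))
  b <- setNames(rnorm(8, 52, 8), sprintf("C%02d", 1:8))
  res <- match_algorithm_I(a, b, t_j = 5, min_group_size = 5)
  replay <- setdiff(names(a), res$removed$sample_id)
  expect_setequal(res$retained$A, replay)
  # converged difference is a non-strict improvement over entry
  if (res$converged)
    expect_lte(abs(res$d_j), abs(mean_difference(a, b)))
})

test_that("the stated equal-size trimming rule diverges and logs it; corrected converges", {
  a <- c(A1 = 50, A2 = 90)
  b <- c(B1 = 40, B2 = 60)
  res <- match_algorithm_II(a, b, t_j = 5, min_group_size = 1)
  expect_false(res$converged)
  expect_true(res$diverged)
  expect_setequal(res$retained$A, "A2")
  expect_setequal(res$retained$B, "B1")
  expect_equal(res$d_j, 50)
  expect_setequal(res$removed$sample_id[res$removed$from == "A"], "A1")
  expect_setequal(res$removed$sample_id[res$removed$from == "B"], "B2")

  ac <- c(A1 = 50, A2 = 60, A3 = 70, A4 = 80, A5 = 90)
  bc <- c(B1 = 40, B2 = 50, B3 = 60, B4 = 70, B5 = 80)
  resc <- match_algorithm_II(ac, bc, t_j = 5, min_group_size = 2,
                             corrected = TRUE)
  expect_true(resc$converged)
  expect_lte(abs(resc$d_j), 5)
  expect_false(resc$diverged)
})

test_that("medoid minimises summed distance with deterministic ties", {
  m1 <- matrix(c(1, 2), nrow = 1, dimnames = list("only", c("j", "k")))
  expect_equal(medoid(m1), "only")
  m3 <- matrix(c(0, 1, 2, 0, 1, 2), ncol = 2,
               dimnames = list(c("p1", "p2", "p3"), c("j", "k")))
  expect_equal(medoid(m3), "p2")
})

test_that("algorithm III excludes the joint outlier first", {
  a <- matrix(c(60, 62, 64, 95,
                26, 27, 26, 40), ncol = 2,
              dimnames = list(c("D1", "D2", "D3", "D4"), c("age", "bmi")))
  b <- matrix(c(55, 57, 25, 26), ncol = 2,
              dimnames = list(c("C1", "C2"), c("age", "bmi")))
  # exhaustive check: D4 is farthest from B's medoid in standardised space
  pooled <- rbind(a, b)
  z <- scale(pooled, center = colMeans(pooled), scale = apply(pooled, 2, sd))
  zb <- z[rownames(b), , drop = FALSE]
  med <- zb[which.min(rowSums(as.matrix(dist(zb)))), ]
  dists <- sqrt(rowSums(sweep(z[rownames(a), ], 2, med)^2))
  expect_equal(names(which.max(dists)), "D4")
  res <- match_algorithm_III(a, b, t_j = 15, t_k = 3, min_group_size = 2)
  expect_equal(res$removed$sample_id[1], "D4")
  if (res$converged) {
    expect_lte(res$d_j, 15)
    expect_lte(res$d_k, 3)
  }
})

test_that("match_pair dispatches by the applicability conditions", {
  cfg <- match_config(t_j = 15, t_k = 3, min_group_size = 2)

  # both thresholds met: identity
  md <- toy_metadata(c(60, 62, 64), c(58, 60, 63))
  res <- match_pair(md[md$group == "Disease", ], md[md$group == "Control", ],
                    cfg)
  expect_equal(res$algorithm, "none")
  expect_equal(length(res$retained$disease), 3)

  # unequal sizes, only age violated: algorithm I
  md <- toy_metadata(c(70, 72, 74, 99), c(55, 57))
  res <- match_pair(md[md$group == "Disease", ], md[md$group == "Control", ],
                    cfg)
  expect_equal(res$algorithm, "I")
  expect_true(res$converged)
  expect_lte(abs(res$d_j), 15)

  # unequal sizes, both violated: algorithm III
  md <- toy_metadata(c(70, 72, 74, 99), c(50, 52),
                     bmi_d = c(30, 31, 32, 40), bmi_c = c(24, 25))
  res <- match_pair(md[md$group == "Disease", ], md[md$group == "Control", ],
                    cfg)
  expect_equal(res$algorithm, "III")

  # equal sizes, one violated: algorithm II
  md <- toy_metadata(c(70, 72, 90), c(50, 52, 54))
  res <- match_pair(md[md$group == "Disease", ], md[md$group == "Control", ],
                    cfg)
  expect_equal(res$algorithm, "II")

  # equal sizes, both violated: no defined algorithm
  md <- toy_metadata(c(70, 72, 90), c(50, 52, 54),
                     bmi_d = c(30, 32, 34), bmi_c = c(22, 24, 25))
  expect_error(match_pair(md[md$group == "Disease", ],
                          md[md$group == "Control", ], cfg),
               "no algorithm applicable")
})

test_that("match_pair excludes samples with missing covariates, with warning", {
  md <- toy_metadata(c(70, 72, 74, 99), c(55, 57))
  md$age[2] <- NA
  expect_warning(
    res <- match_pair(md[md$group == "Disease", ],
                      md[md$group == "Control", ],
                      match_config(min_group_size = 2)),
    "missing")
  expect_false("D02" %in% res$retained$disease)
})

test_that("matching only removes samples, never adds or duplicates", {
  set.seed(21)
  md <- toy_metadata(rnorm(25, 70, 8), rnorm(15, 52, 8),
                     bmi_d = rnorm(25, 30, 3), bmi_c = rnorm(15, 25, 3))
  res <- match_pair(md[md$group == "Disease", ], md[md$group == "Control", ],
                    match_config(min_group_size = 2))
  all_ids <- c(res$retained$disease, res$retained$control,
               res$removed$sample_id)
  expect_setequal(all_ids, md$sample_id)
  expect_false(anyDuplicated(all_ids) > 0)
})
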