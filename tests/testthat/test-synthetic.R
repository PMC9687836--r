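test_that("metadata generation is deterministic and respects group distributions", {
  spec <- cohort_spec(seed = 42L)
  md1 <- generate_metadata(spec)
  md2 <- generate_metadata(spec)
  expect_identical(md1, md2)
  expect_equal(nrow(md1), sum(spec$group_sizes))
  expect_false(anyDuplicated(md1$sample_id) > 0)
  expect_true(all(md1$age >= 18 & md1$age <= 95))
  expect_true(all(md1$bmi >= 15 & md1$bmi <= 45))

  # identical distributions: mean age gap small relative to its SE
  same <- cohort_spec(group_sizes = c(A = 20, B = 20),
                      age_dist = list(A = c(mean = 60, sd = 10),
                                      B = c(mean = 60, sd = 10)),
                      bmi_dist = list(A = c(mean = 26, sd = 3),
                                      B = c(mean = 26, sd = 3)),
                      sex_ratio = c(A = 0.5, B = 0.5), seed = 7L)
  md <- generate_metadata(same)
  gap <- diff(tapply(md$age, md$group, mean))
  expect_lt(abs(gap), 3 * sqrt(10^2 / 20 * 2))

  # planted 15-year gap recovered within 3 SE of the difference of means
  shifted <- cohort_spec(group_sizes = c(Disease = 40, Control = 40),
                         age_dist = list(Disease = c(mean = 67, sd = 10),
                                         Control = c(mean = 52, sd = 10)),
                         bmi_dist = list(Disease = c(mean = 28, sd = 3),
                                         Control = c(mean = 26, sd = 3)),
                         sex_ratio = c(Disease = 0.6, Control = 0.4),
                         seed = 11L)
  md <- generate_metadata(shifted)
  gap <- mean(md$age[md$group == "Disease"]) -
    mean(md$age[md$group == "Control"])
  expect_lt(abs(gap - 15), 3 * sqrt(100 / 40 + 100 / 40))
})

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(group_sizes = c(A = 1, B = 20)), "group sizes")
  expect_error(cohort_spec(
    group_sizes = c(A = 10, B = 10),
    age_dist = list(A = c(mean = 60, sd = 0), B = c(mean = 60, sd = 10)),
    bmi_dist = list(A = c(mean = 26, sd = 3), B = c(mean = 26, sd = 3)),
    sex_ratio = c(A = 0.5, B = 0.5)), "SDs")
})

test_that("count generation matches base proportions absent noise and effects", {
  spec <- count_spec(n_taxa = 10, dispersion = Inf,
                     depth_dist = c(mean = 2000, sd = 0), seed = 3L)
  md <- generate_metadata(cohort_spec(group_sizes = c(A = 15, B = 15),
                                      age_dist = list(A = c(mean = 60, sd = 5),
                                                      B = c(mean = 60, sd = 5)),
                                      bmi_dist = list(A = c(mean = 26, sd = 2),
                                                      B = c(mean = 26, sd = 2)),
                                      sex_ratio = c(A = 0.5, B = 0.5),
                                      seed = 3L))
  counts <- generate_counts(spec, md)
  expect_true(all(counts >= 0))
  expect_identical(storage.mode(counts), "integer")
  obs <- rowSums(counts) / sum(counts)
  # pooled multinomial proportion SE at 30 * 2000 draws
  se <- sqrt(spec$base_proportions * (1 - spec$base_proportions) /
               sum(counts))
  expect_true(all(abs(obs - spec$base_proportions) < 5 * se + 1e-4))
})

test_that("planted fold changes raise the taxon in the named group", {
  hits <- vapply(1:20, function(s) {
    spec <- count_spec(n_taxa = 20, dispersion = 100,
                       planted_effects = data.frame(group = "A",
                                                    taxon = "Family05",
                                                    log2fc = 2),
                       depth_dist = c(mean = 3000, sd = 300), seed = s)
    md <- generate_metadata(cohort_spec(
      group_sizes = c(A = 30, B = 30),
      age_dist = list(A = c(mean = 60, sd = 5), B = c(mean = 60, sd = 5)),
      bmi_dist = list(A = c(mean = 26, sd = 2), B = c(mean = 26, sd = 2)),
      sex_ratio = c(A = 0.5, B = 0.5), seed = s))
    counts <- generate_counts(spec, md)
    rel <- sweep(counts, 2, colSums(counts), "/")
    mean(rel["Family05", md$group == "A"]) >
      mean(rel["Family05", md$group == "B"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("count generation rejects bad specs", {
  md <- toy_metadata(c(60, 65), c(55, 58))
  expect_error(count_spec(depth_dist = c(mean = 0, sd = 0)), "depth mean")
  spec <- count_spec(n_taxa = 5,
                     planted_effects = data.frame(group = "Disease",
                                                  taxon = "NotATaxon",
                                                  log2fc = 2))
  expect_error(generate_counts(spec, md), "unknown taxon")
})

test_that("qPCR generation evaluates the standard-curve line exactly", {
  tc <- data.frame(sample_id = c("s1", "s2", "s3"),
                   assay = "Lacto",
                   concentration = c(1, 1e6, 0))
  cp <- data.frame(assay = "Lacto", slope = -3.3219, intercept = 40)
  plate <- generate_qpcr(qpcr_spec(tc, cp, ct_noise_sd = 0))
  expect_equal(plate$ct[1], 40)                 # log10(1) = 0
  expect_equal(plate$ct[2], 40 - 6 * 3.3219)    # 20.0686
  expect_true(is.na(plate$ct[3]))               # no amplification
  expect_error(qpcr_spec(transform(tc, concentration = -1), cp), ">= 0")
  expect_error(qpcr_spec(tc, transform(cp, slope = 3.3)), "negative")
})

test_that("noise-free qPCR round trip recovers concentrations", {
  conc <- 10^seq(0, 6, by = 0.5)
  tc <- data.frame(sample_id = sprintf("s%02d", seq_along(conc)),
                   assay = "Uni", concentration = conc)
  cp <- data.frame(assay = "Uni", slope = -3.4, intercept = 38.5)
  plate <- generate_qpcr(qpcr_spec(tc, cp, ct_noise_sd = 0))
  curve <- list(slope = -3.4, intercept = 38.5)
  back <- quantify_target(plate$ct, curve)
  expect_equal(as.numeric(back), conc, tolerance = 1e-7)
})

test_that("culture profiles honour the zero-inflation level", {
  md <- toy_metadata(rnorm(50, 60, 5), rnorm(50, 55, 5))[1:50, ]
  all_zero <- generate_culture_profiles(10, 1, md, seed = 1)
  expect_true(all(all_zero == 0))
  none_zero <- generate_culture_profiles(10, 0, md, seed = 1)
  expect_true(all(none_zero > 0))
  half <- generate_culture_profiles(100, 0.5, md, seed = 1)
  expect_gt(mean(half == 0), 0.45)
  expect_lt(mean(half == 0), 0.55)
  expect_error(generate_culture_profiles(10, 1.2, md), "zero_inflation")
})

test_that("generated trees cover the taxa and fixed seeds reproduce", {
  taxa <- sprintf("Family%02d", 1:12)
  t1 <- generate_tree(taxa, seed = 5)
  t2 <- generate_tree(taxa, seed = 5)
  expect_setequal(t1$tip.label, taxa)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})
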