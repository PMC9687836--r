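#' Synthetic cohort specification
#'
#' Describes a case-control cohort: per-group sizes, age and BMI normal
#' distributions (truncated at generation time to plausible clinical ranges),
#' and per-group sex ratios. Defaults emulate a heart-failure vs. control
#' contrast: older, higher-BMI, predominantly male disease group against a
#' younger, mixed-sex control group.
#'
#' @param group_sizes named integer vector, group label -> number of samples
#'   (each >= 2).
#' @param age_dist named list, group label -> `c(mean =, sd =)` in years.
#' @param bmi_dist named list, group label -> `c(mean =, sd =)` in kg/m^2.
#' @param sex_ratio named numeric vector, group label -> fraction male in
#'   `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(HFrEF = 40, Control = 34),
                        age_dist = list(HFrEF = c(mean = 68, sd = 8.6),
                                        Control = c(mean = 53, sd = 13)),
                        bmi_dist = list(HFrEF = c(mean = 28, sd = 3.5),
                                        Control = c(mean = 25, sd = 4)),
                        sex_ratio = c(HFrEF = 0.9, Control = 0.25),
                        seed = 1L) {
  groups <- names(group_sizes)
  if (is.null(groups) || anyDuplicated(groups) > 0)
    stop("group_sizes must be a uniquely named vector", call. = FALSE)
  if (any(group_sizes < 2))
    stop("all group sizes must be >= 2", call. = FALSE)
  for (g in groups) {
    for (d in list(age_dist[[g]], bmi_dist[[g]])) {
      if (is.null(d) || !all(c("mean", "sd") %in% names(d)))
        stop("age_dist and bmi_dist must provide c(mean, sd) for group ", g,
             call. = FALSE)
      if (d[["sd"]] <= 0) stop("SDs must be > 0", call. = FALSE)
    }
    sr <- sex_ratio[[g]]
    if (is.null(sr) || sr < 0 || sr > 1)
      stop("sex_ratio must lie in [0, 1] for group ", g, call. = FALSE)
  }
  structure(list(group_sizes = group_sizes, age_dist = age_dist,
                 bmi_dist = bmi_dist, sex_ratio = sex_ratio,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# normal draws truncated by rejection; bounds bracket plausible adult values
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Generate sample metadata for a synthetic cohort
#'
#' Draws one row per sample: age from the group's normal truncated to
#' `[18, 95]` years, BMI truncated to `[15, 45]` kg/m^2, sex from the group's
#' ratio, and a DNA extraction method label (FS or PF) assigned at random, as
#' happens when two kits are used across a study.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `sample_id`, `group`, `age`, `bmi`, `sex`
#'   ("M"/"F"), `extraction_method` ("FS"/"PF").
#' @export
generate_metadata <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec",
                                           call. = FALSE)
  set.seed(spec$seed)
  rows <- lapply(names(spec$group_sizes), function(g) {
    n <- spec$group_sizes[[g]]
    a <- spec$age_dist[[g]]
    b <- spec$bmi_dist[[g]]
    data.frame(
      sample_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g,
      age = rnorm_trunc(n, a[["mean"]], a[["sd"]], 18, 95),
      bmi = rnorm_trunc(n, b[["mean"]], b[["sd"]], 15, 45),
      sex = ifelse(rbinom(n, 1, spec$sex_ratio[[g]]) == 1, "M", "F"),
      extraction_method = sample(c("FS", "PF"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic 16S count table specification
#'
#' Family-level counts are modelled as Dirichlet-multinomial draws: each
#' sample's taxon proportions are a Dirichlet perturbation (concentration =
#' `dispersion`) of group-level base proportions, and reads are a multinomial
#' draw of the sample's library size. Planted effects multiply the named
#' group's base proportions by `2^log2fc` before renormalisation.
#'
#' @param n_taxa number of taxa (ignored when `base_proportions` is given).
#' @param base_proportions probability vector over taxa (sums to 1); default
#'   is a geometric-decay rank-abundance profile over `n_taxa` families.
#' @param dispersion Dirichlet concentration (> 0); `Inf` disables the
#'   between-sample compositional noise.
#' @param planted_effects data.frame with columns `group`, `taxon`, `log2fc`,
#'   or NULL.
#' @param depth_dist `c(mean =, sd =)` of the per-sample library size.
#' @param seed integer RNG seed.
#' @return an object of class `count_spec`.
#' @export
count_spec <- function(n_taxa = 30L,
                       base_proportions = NULL,
                       dispersion = 100,
                       planted_effects = NULL,
                       depth_dist = c(mean = 5000, sd = 1000),
                       seed = 1L) {
  if (is.null(base_proportions)) {
    base_proportions <- exp(-0.15 * seq_len(n_taxa))
    base_proportions <- base_proportions / sum(base_proportions)
    names(base_proportions) <- sprintf("Family%02d", seq_len(n_taxa))
  }
  if (abs(sum(base_proportions) - 1) > 1e-8)
    stop("base_proportions must sum to 1", call. = FALSE)
  if (is.null(names(base_proportions)))
    names(base_proportions) <- sprintf("Family%02d",
                                       seq_along(base_proportions))
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (depth_dist[["mean"]] <= 0) stop("depth mean must be > 0", call. = FALSE)
  if (!is.null(planted_effects) &&
      !all(c("group", "taxon", "log2fc") %in% names(planted_effects)))
    stop("planted_effects needs columns group, taxon, log2fc", call. = FALSE)
  structure(list(n_taxa = length(base_proportions),
                 base_proportions = base_proportions,
                 dispersion = dispersion,
                 planted_effects = planted_effects,
                 depth_dist = depth_dist,
                 seed = as.integer(seed)),
            class = "count_spec")
}

#' Generate a synthetic family-level count table
#'
#' @param spec a [count_spec()].
#' @param metadata sample metadata from [generate_metadata()]; planted effects
#'   are applied to the groups named in the spec.
#' @return integer matrix, taxa (rows) x samples (columns), with a `kind`
#'   attribute of "counts".
#' @export
generate_counts <- function(spec, metadata) {
  if (!inherits(spec, "count_spec")) stop("spec must be a count_spec",
                                          call. = FALSE)
  pe <- spec$planted_effects
  if (!is.null(pe)) {
    bad_taxa <- setdiff(pe$taxon, names(spec$base_proportions))
    if (length(bad_taxa) > 0)
      stop("planted effect on unknown taxon: ",
           paste(bad_taxa, collapse = ", "), call. = FALSE)
    bad_groups <- setdiff(pe$group, unique(metadata$group))
    if (length(bad_groups) > 0)
      stop("planted effect on unknown group: ",
           paste(bad_groups, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  n_taxa <- spec$n_taxa
  group_props <- lapply(unique(metadata$group), function(g) {
    p <- spec$base_proportions
    if (!is.null(pe)) {
      rows <- pe[pe$group == g, , drop = FALSE]
      if (nrow(rows) > 0)
        p[rows$taxon] <- p[rows$taxon] * 2^rows$log2fc
    }
    p / sum(p)
  })
  names(group_props) <- unique(metadata$group)
  counts <- vapply(seq_len(nrow(metadata)), function(i) {
    p <- group_props[[metadata$group[i]]]
    if (is.finite(spec$dispersion)) {
      g <- rgamma(n_taxa, shape = spec$dispersion * p)
      if (sum(g) == 0) g <- p else p <- g / sum(g)
    }
    depth <- max(1L, round(rnorm(1, spec$depth_dist[["mean"]],
                                 spec$depth_dist[["sd"]])))
    rmultinom(1, depth, p)[, 1]
  }, numeric(n_taxa))
  dimnames(counts) <- list(names(spec$base_proportions), metadata$sample_id)
  storage.mode(counts) <- "integer"
  attr(counts, "kind") <- "counts"
  counts
}

#' Synthetic qPCR plate specification
#'
#' Inverts the standard-curve quantification model: given true target
#' concentrations C (gene copies per uL) and per-assay curve parameters, Ct
#' values are generated as `Ct = intercept + slope * log10(C) + noise`.
#'
#' @param true_concentrations data.frame with columns `sample_id`, `assay`,
#'   `concentration` (gene copies per uL, >= 0; 0 means no template).
#' @param curve_params data.frame with columns `assay`, `slope` (cycles per
#'   log10 copies, negative), `intercept` (cycles).
#' @param ct_noise_sd Ct noise standard deviation in cycles (>= 0).
#' @param seed integer RNG seed.
#' @return an object of class `qpcr_spec`.
#' @export
qpcr_spec <- function(true_concentrations, curve_params, ct_noise_sd = 0.15,
                      seed = 1L) {
  if (any(true_concentrations$concentration < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(curve_params$slope >= 0))
    stop("standard-curve slopes must be negative", call. = FALSE)
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  structure(list(true_concentrations = true_concentrations,
                 curve_params = curve_params,
                 ct_noise_sd = ct_noise_sd, seed = as.integer(seed)),
            class = "qpcr_spec")
}

#' Generate a synthetic qPCR plate
#'
#' Zero-concentration wells are emitted with a missing Ct ("no
#' amplification"), which downstream quantification maps back to a
#' concentration of zero; this keeps true absence distinct from a late signal.
#'
#' @param spec a [qpcr_spec()].
#' @param plate_id plate label recorded on every well.
#' @return data.frame with columns `sample_id`, `assay`, `plate`, `ct`
#'   (NA for no amplification).
#' @export
generate_qpcr <- function(spec, plate_id = "P1") {
  if (!inherits(spec, "qpcr_spec")) stop("spec must be a qpcr_spec",
                                         call. = FALSE)
  set.seed(spec$seed)
  tc <- spec$true_concentrations
  cp <- spec$curve_params
  idx <- match(tc$assay, cp$assay)
  if (anyNA(idx))
    stop("curve parameters missing for assay: ",
         paste(unique(tc$assay[is.na(idx)]), collapse = ", "), call. = FALSE)
  ct <- ifelse(tc$concentration > 0,
               cp$intercept[idx] + cp$slope[idx] * log10(tc$concentration),
               NA_real_)
  if (spec$ct_noise_sd > 0)
    ct <- ct + ifelse(is.na(ct), 0, rnorm(length(ct), 0, spec$ct_noise_sd))
  data.frame(sample_id = tc$sample_id, assay = tc$assay, plate = plate_id,
             ct = ct, stringsAsFactors = FALSE)
}

#' Generate zero-inflated culture/MALDI abundance profiles
#'
#' Each species-by-sample cell is zero with probability `zero_inflation`, and
#' otherwise log-normal (CFU-like abundance), mimicking the sparsity of
#' culture-based profiling where most species are not recovered from most
#' samples.
#'
#' @param n_species number of species rows.
#' @param zero_inflation probability of a structural zero, in `[0, 1]`.
#' @param metadata sample metadata; one column is generated per sample.
#' @param seed integer RNG seed.
#' @param meanlog,sdlog log-normal parameters of the nonzero abundances.
#' @return numeric matrix species x samples with `kind` attribute
#'   "culture_abundance".
#' @export
generate_culture_profiles <- function(n_species, zero_inflation, metadata,
                                      seed = 1L, meanlog = 4, sdlog = 1) {
  if (zero_inflation < 0 || zero_inflation > 1)
    stop("zero_inflation must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  n_samp <- nrow(metadata)
  vals <- rlnorm(n_species * n_samp, meanlog, sdlog)
  zeros <- rbinom(n_species * n_samp, 1, zero_inflation) == 1
  vals[zeros] <- 0
  m <- matrix(vals, nrow = n_species, ncol = n_samp,
              dimnames = list(sprintf("Species%03d", seq_len(n_species)),
                              metadata$sample_id))
  attr(m, "kind") <- "culture_abundance"
  m
}

#' Generate a random phylogeny over synthetic taxa
#'
#' Random bifurcating topology with exponential branch lengths; useful as the
#' tree input to Faith's PD and UniFrac on synthetic count tables.
#'
#' @param taxa character vector of tip labels.
#' @param seed integer RNG seed.
#' @param rate rate of the exponential branch-length distribution.
#' @return an [ape::rtree()] phylo object with `taxa` as tip labels.
#' @export
generate_tree <- function(taxa, seed = 1L, rate = 1) {
  set.seed(seed)
  ape::rtree(length(taxa), tip.label = taxa, br = function(n) rexp(n, rate))
}
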