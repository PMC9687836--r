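#' Pipeline configuration for one case-control comparison
#'
#' One comparison per invocation (e.g., HFrEF vs Control), mirroring the
#' pairwise design of matching each disease group to the control pool.
#'
#' @param platform one of "culture", "ngs", "qpcr"; selects the per-platform
#'   transform (log10 of nonzeros / count binning / tanh robust scaling).
#' @param case,control group labels.
#' @param match a [match_config()].
#' @param rarefaction_depth reads per sample for the NGS platform; NULL skips
#'   rarefaction.
#' @param bin_counts apply the low-abundance binning rule after rarefaction
#'   (NGS only). The default order is rarefy, then bin, then test.
#' @param n_sim Monte Carlo simulations per feature test.
#' @param seed integer seed driving every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(platform = c("ngs", "culture", "qpcr"),
                            case, control, match = match_config(),
                            rarefaction_depth = NULL, bin_counts = TRUE,
                            n_sim = 1e4, seed = 1L) {
  platform <- match.arg(platform)
  structure(list(platform = platform, case = case, control = control,
                 match = match, rarefaction_depth = rarefaction_depth,
                 bin_counts = bin_counts, n_sim = n_sim,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

cohort_summary <- function(metadata, ids, config) {
  md <- metadata[metadata$sample_id %in% unlist(ids), , drop = FALSE]
  do.call(rbind, lapply(split(md, md$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               age_mean = mean(g$age), age_sd = sd(g$age),
               bmi_mean = mean(g$bmi), bmi_sd = sd(g$bmi),
               pct_male = 100 * mean(g$sex == "M"),
               stringsAsFactors = FALSE)
  }))
}

#' Run one end-to-end case-control comparison
#'
#' Stage order: covariate-convergence matching, per-platform transform
#' (rarefaction + count binning for NGS, log10 for culture, quantified
#' concentrations for qPCR), optional alpha diversity when a tree is given,
#' per-feature Mann-Whitney Monte Carlo testing with Benjamini-Yekutieli
#' correction, and a PCA + LDA discriminant-axis analysis with Spearman
#' attribution. Deterministic under a fixed config seed.
#'
#' @param metadata sample metadata (see [generate_metadata()] for the shape).
#' @param table feature table, taxa x samples. For "qpcr" this is the
#'   adjusted concentration table from [normalize_to_total()].
#' @param config a [pipeline_config()].
#' @param tree optional rooted phylogeny (NGS alpha diversity).
#' @return an object of class `comparison_report`: `cohort` (per-group
#'   summary of the matched cohort), `match` (the `match_result`), `results`
#'   (the [compare_groups()] table plus a `p_band` column), `discriminant`
#'   (axis separation and flagged variables, when estimable), `alpha`
#'   (per-sample indices, NGS with tree only), `provenance`.
#' @export
run_comparison <- function(metadata, table, config, tree = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  for (lab in c(config$case, config$control))
    if (!lab %in% metadata$group)
      stop("group label not present in metadata: ", lab, call. = FALSE)

  disease <- metadata[metadata$group == config$case, , drop = FALSE]
  control <- metadata[metadata$group == config$control, , drop = FALSE]
  match <- match_pair(disease, control, config$match)
  keep <- c(match$retained$disease, match$retained$control)
  keep <- intersect(keep, colnames(table))
  if (length(keep) < 4)
    stop("fewer than 4 matched samples present in the feature table",
         call. = FALSE)
  tab <- table[, keep, drop = FALSE]
  md <- metadata[metadata$sample_id %in% keep, , drop = FALSE]

  alpha <- NULL
  if (config$platform == "ngs") {
    if (!is.null(config$rarefaction_depth))
      tab <- rarefy(tab, config$rarefaction_depth, seed = config$seed)
    if (!is.null(tree)) alpha <- alpha_diversity(tab, tree)
    if (isTRUE(config$bin_counts)) tab <- bin_low_abundance(tab)
    ord_mat <- t(tab)
  } else if (config$platform == "culture") {
    tab <- log10_nonzero_transform(tab)
    ord_mat <- t(tab)
  } else {
    ord_mat <- tanh_robust_transform(t(tab))
  }
  md <- md[match(colnames(tab), md$sample_id), , drop = FALSE]

  results <- compare_groups(tab, md, config$case, config$control,
                            n_sim = config$n_sim, seed = config$seed)
  results$p_band <- p_band(results$p_adjusted)

  discriminant <- NULL
  ord_groups <- md$group[match(rownames(ord_mat), md$sample_id)]
  disc_try <- tryCatch({
    comp <- select_components(ord_mat)
    k_max <- max(1L, min(comp$n_components, nrow(ord_mat) - 2L))
    model <- fit_discriminant(comp$scores[, seq_len(k_max), drop = FALSE],
                              ord_groups, case = config$case)
    corr <- correlate_axis(model, ord_mat)
    list(n_components = k_max,
         explained = sum(comp$explained[seq_len(k_max)]),
         separation = model$separation,
         axis = model$axis,
         scores = data.frame(sample_id = rownames(ord_mat),
                             group = ord_groups,
                             score = model$scores,
                             stringsAsFactors = FALSE),
         correlations = corr)
  }, error = function(e) {
    message("discriminant analysis skipped: ", conditionMessage(e))
    NULL
  })
  discriminant <- disc_try

  structure(list(
    cohort = cohort_summary(metadata, match$retained, config),
    match = match,
    results = results,
    discriminant = discriminant,
    alpha = alpha,
    provenance = list(platform = config$platform, case = config$case,
                      control = config$control, n_sim = config$n_sim,
                      seed = config$seed,
                      rarefaction_depth = config$rarefaction_depth,
                      bin_counts = config$bin_counts,
                      package_version = as.character(
                        utils::packageVersion("tricohort")))
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison report:", x$provenance$case, "vs", x$provenance$control,
      "(", x$provenance$platform, ")\n")
  cat("Matched cohort:\n")
  print(x$cohort, row.names = FALSE)
  sig <- x$results[x$results$p_band != "ns", , drop = FALSE]
  cat(nrow(x$results), "features tested;", nrow(sig),
      "significant after BY correction\n")
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits three files under `dir`: `results.tsv` (per-feature table with arrow
#' directions), `report.json` (full report), and `report.md` (human-readable
#' summary in the arrow-table layout).
#'
#' @param report a [run_comparison()] result.
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$results
  res$arrow <- ifelse(res$direction == "increased", "↑", "↓")
  tsv <- file.path(dir, "results.tsv")
  write.table(format(res, digits = 15, trim = TRUE), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(cohort = report$cohort, results = res,
         match = unclass(report$match),
         discriminant = report$discriminant[c("n_components", "explained",
                                              "separation", "axis",
                                              "correlations")],
         provenance = report$provenance),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- file.path(dir, "report.md")
  lines <- c(
    sprintf("# %s vs %s (%s platform)", report$provenance$case,
            report$provenance$control, report$provenance$platform),
    "",
    "## Matched cohort",
    "",
    "| group | n | age (mean +/- SD) | BMI (mean +/- SD) | male % |",
    "|---|---|---|---|---|",
    sprintf("| %s | %d | %.1f +/- %.1f | %.1f +/- %.1f | %.1f |",
            report$cohort$group, report$cohort$n, report$cohort$age_mean,
            report$cohort$age_sd, report$cohort$bmi_mean,
            report$cohort$bmi_sd, report$cohort$pct_male),
    "",
    "## Per-feature results",
    "",
    "| feature | direction | effect size | adjusted p |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %s |", res$feature, res$arrow,
            res$eta_squared, res$p_band))
  writeLines(lines, md)
  invisible(c(tsv, js, md))
}
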