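#!/usr/bin/env Rscript
# Simulates the full three-platform study inputs: a case-control cohort with
# realistic age/BMI/sex structure, family-level 16S counts with two planted
# fold changes, a random phylogeny over the families, zero-inflated culture
# profiles, and a qPCR plate with its standard-curve dilution series.
# Everything downstream (02-06) reads the files written here.

suppressPackageStartupMessages(library(tricohort))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260901L

cspec <- cohort_spec(group_sizes = c(HFrEF = 40, Control = 34),
                     age_dist = list(HFrEF = c(mean = 68, sd = 8.6),
                                     Control = c(mean = 53, sd = 13)),
                     bmi_dist = list(HFrEF = c(mean = 28, sd = 3.5),
                                     Control = c(mean = 25, sd = 4)),
                     sex_ratio = c(HFrEF = 0.9, Control = 0.25),
                     seed = seed)
metadata <- generate_metadata(cspec)
write_metadata(metadata, file.path(out, "metadata.tsv"))

planted <- data.frame(group = "HFrEF",
                      taxon = c("Family10", "Family05"),
                      log2fc = c(2, -2))
kspec <- count_spec(n_taxa = 25, dispersion = 100, planted_effects = planted,
                    depth_dist = c(mean = 4000, sd = 500), seed = seed)
counts <- generate_counts(kspec, metadata)
write_feature_table(counts, file.path(out, "ngs_counts.tsv"))
write.table(planted, file.path(out, "planted_effects.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tree <- generate_tree(rownames(counts), seed = seed)
ape::write.tree(tree, file.path(out, "families.nwk"))

culture <- generate_culture_profiles(60, zero_inflation = 0.4, metadata,
                                     seed = seed)
write_feature_table(culture, file.path(out, "culture_abundance.tsv"))

# qPCR: nine assays plus the universal V4 total-bacteria assay; true
# organism concentrations are log-normal, converted to gene copies with the
# bundled copy numbers, then to Ct through per-assay standard curves
copy_numbers <- read_copy_numbers()
assays <- setdiff(names(copy_numbers), "Universal_V4")
set.seed(seed)
true_org <- matrix(rlnorm(length(assays) * nrow(metadata), 8, 1.2),
                   nrow = length(assays),
                   dimnames = list(assays, metadata$sample_id))
# Lactobacillaceae planted higher in the disease group (4-fold)
true_org["Lactobacillaceae", metadata$group == "HFrEF"] <-
  true_org["Lactobacillaceae", metadata$group == "HFrEF"] * 4
true_total_org <- colSums(true_org) * runif(nrow(metadata), 1.8, 2.4)
gene_copies <- rbind(true_org * copy_numbers[assays],
                     Universal_V4 = true_total_org *
                       copy_numbers[["Universal_V4"]])

curves <- data.frame(assay = rownames(gene_copies),
                     slope = round(rnorm(nrow(gene_copies), -3.32, 0.06), 4),
                     intercept = round(rnorm(nrow(gene_copies), 39.5, 0.8), 3))
tc <- do.call(rbind, lapply(rownames(gene_copies), function(a)
  data.frame(sample_id = colnames(gene_copies), assay = a,
             concentration = gene_copies[a, ])))
plate <- generate_qpcr(qpcr_spec(tc, curves, ct_noise_sd = 0.15,
                                 seed = seed), plate_id = "P1")
write_qpcr(plate, file.path(out, "qpcr_plate.csv"))

dil <- do.call(rbind, lapply(seq_len(nrow(curves)), function(i) {
  copies <- 10^(0:6)
  data.frame(assay = curves$assay[i], copies = copies,
             ct = curves$intercept[i] + curves$slope[i] * log10(copies) +
               rnorm(7, 0, 0.1))
}))
write.csv(dil, file.path(out, "standard_curves.csv"), row.names = FALSE)
write.csv(curves, file.path(out, "true_curve_params.csv"), row.names = FALSE)

cat("Simulated cohort:", nrow(metadata), "samples;",
    nrow(counts), "16S families;", nrow(culture), "culture species;",
    length(assays), "qPCR targets + universal assay\n")
cat("Planted NGS effects: Family10 +2 log2FC, Family05 -2 log2FC in HFrEF;",
    "qPCR Lactobacillaceae x4 in HFrEF\n")
cat("Inputs written under", out, "\n")
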