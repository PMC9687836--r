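# tricohort

Case–control comparison of gut microbiome profiles measured on three
platforms — bacterial culture with MALDI-TOF identification, family-level
16S rRNA amplicon counts, and targeted qPCR absolute quantification — for
cohorts (e.g., heart-failure phenotypes vs. hospital controls) whose age and
BMI structure would otherwise confound every comparison.

The package is aimed at analysts who have per-sample metadata, a
taxon-by-sample abundance table per platform, and optionally a phylogeny and
qPCR standard curves, and who need the whole chain from cohort matching to a
corrected differential-abundance table to be reproducible and testable.

## What it computes

1. **Covariate-convergence matching.** Groups are trimmed until
   |Δ mean age| ≤ 15 years and |Δ mean BMI| ≤ 3 kg/m², using three
   iterative algorithms chosen by the applicability conditions (unequal
   sizes / equal sizes / both variables violated, the last via the medoid of
   the smaller group in pooled-standardised (age, BMI) space):

   d_j = mean(A_j) − mean(B_j),  stop when |d_j| ≤ T_j (and |d_k| ≤ T_k)

2. **Per-platform transforms.** Robust logistic `1/(1+exp(−(x−Med)/IQR))`
   for clinical variables, `log10` of nonzero culture abundances, `tanh`
   robust scaling for qPCR concentrations, and the low-abundance binning
   rule for 16S counts (x < 31 → 0, 31–99 → 75, 100–149 → 125, else
   unchanged).

3. **qPCR quantification.** Standard curve Ct = slope·log10(C) + int per
   assay, absolute quantification C = 10^((Ct − int)/slope), 16S
   copy-number correction, and per-sample scaling to a fixed total of 10⁷
   organisms per µL via a universal V4 assay.

4. **Diversity.** Rarefaction, six alpha indices (Shannon base 2, Pielou,
   Simpson, Chao1, Faith's PD, Strong's dominance), midpoint rooting, and
   unweighted/weighted UniFrac.

5. **Testing.** Per-feature Mann–Whitney U with Monte Carlo permutation
   p-values (add-one corrected), rank effect size η² = (H − k + 1)/(n − k)
   from the tie-corrected Kruskal–Wallis H, Fisher-type Monte Carlo tests
   with the φ coefficient for binary indicators, and Benjamini–Yekutieli
   FDR correction with a per-platform or pooled correction pool.

6. **Ordination.** PCA (components covering ≥ 1/3 of variance, max 10) +
   two-class LDA discriminant axis, Spearman attribution of original
   variables with |ρ| ≥ 0.3, and a PCA+LDA screen for DNA-extraction batch
   effects with a permutation p-value.

A synthetic-cohort module generates all inputs (covariate-structured
metadata, Dirichlet-multinomial counts with planted log2 fold changes, Ct
values through a noisy standard curve, zero-inflated culture profiles, and
a random phylogeny) so the complete pipeline is exercised end to end
without patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate_cohort.R` through
`06_culture_comparison.R`), writing tables under `results/`. The core of it
in a session:

```r
library(tricohort)

md     <- generate_metadata(cohort_spec(seed = 20260901L))
counts <- generate_counts(count_spec(
  n_taxa = 25, dispersion = 100,
  planted_effects = data.frame(group = "HFrEF",
                               taxon = c("Family10", "Family05"),
                               log2fc = c(2, -2)),
  depth_dist = c(mean = 4000, sd = 500), seed = 20260901L), md)

cfg <- pipeline_config("ngs", case = "HFrEF", control = "Control",
                       rarefaction_depth = 3000, n_sim = 1e5,
                       seed = 20260901L)
report <- run_comparison(md, counts, cfg)
head(report$results[order(report$results$p_adjusted),
                    c("feature", "direction", "eta_squared", "p_adjusted")])
```

which prints (the two planted families first, with the right arrows):

```
  feature direction eta_squared   p_adjusted
 Family05 decreased       0.669 0.00047699
 Family10 increased       0.752 0.00047699
 Family01 decreased       0.089 0.24517286
 Family03 decreased       0.073 0.30679997
```

`eta_squared` is the rank effect size (share of rank variance explained by
the group split), and `p_adjusted` is the Benjamini–Yekutieli-corrected
Monte Carlo Mann–Whitney p over the 25-family pool. The matched cohort and
removal log live in `report$match`; `report$discriminant` carries the
PCA+LDA axis — here one component (38 % of variance), standardised group
separation 4.5, with Family05 and Family10 among the variables at
|ρ| ≥ 0.3. `write_report()` emits the result as TSV, JSON, and a
human-readable markdown table with ↑/↓ arrows.

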