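---
title: "Three-platform gut microbiome case-control comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-platform gut microbiome case-control comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tricohort` re-implements, as tested and reusable functions, a
group-comparison workflow for gut microbiome profiles measured on three
platforms: bacterial culture with MALDI-TOF species identification,
family-level 16S rRNA amplicon counts, and targeted qPCR absolute
quantification. The workflow is a fixed sequence — match the case cohort to
the control pool on age and BMI, apply a per-platform transform, test each
feature with a Monte Carlo Mann-Whitney test under a Benjamini-Yekutieli
correction, and summarise multivariate separation with a PCA+LDA
discriminant axis. This vignette explains each stage, its assumptions, and
the design decisions taken where the procedure was genuinely open.

## Covariate-convergence matching

Disease and control groups drawn from hospital recruitment differ
systematically in age and BMI, both of which shape the gut microbiome. The
matching stage trims samples until the group mean difference in age is at
most `t_j` = 15 years and in BMI at most `t_k` = 3 kg/m^2 (the defaults of
`match_config()`). Three trimming algorithms cover the applicability
conditions:

* **Algorithm I** (unequal sizes, one variable violated): the larger group
  repeatedly loses its maximum of the matching variable while the mean
  difference `d = mean(A) - mean(B)` is positive, its minimum while
  negative, until `|d|` reaches the threshold.
* **Algorithm II** (equal sizes, one variable violated): as originally
  stated, when `d > 0` group A loses its *minimum* and B its *maximum* —
  which moves the means apart. We implement the rule exactly as stated and
  log the divergence; `match_config(corrected = TRUE)` selects the
  sign-flipped convergent variant. We deliberately do not correct silently:
  the stated rule is reproducible behaviour, and the flag makes the choice
  auditable.
* **Algorithm III** (unequal sizes, both variables violated): age and BMI
  are standardised by the pooled mean and SD of both groups (so both live in
  one coordinate frame — the procedure's "standard setting" does not state
  the fitting population, and pooling is the only choice that keeps one
  frame), the smaller group contributes its *medoid* (the member minimising
  summed Euclidean distances to its own group), and the larger group
  repeatedly loses the observation farthest from that medoid.

Guards the original procedure lacks, added because pathological inputs
otherwise empty a group: no group is trimmed below `min_group_size`
(default 5), ties at an extremum remove the lexicographically smallest
sample id (deterministic, auditable), and Algorithm III stops when no single
exclusion can decrease the worst threshold ratio `max(d_j/t_j, d_k/t_k)`.
Because trimming on one variable can push the *other* variable past its
threshold, `match_pair()` re-dispatches on the retained sets until both
thresholds hold; `converged = TRUE` therefore guarantees both final
differences are within bounds, and anything else is flagged. Samples with
missing age or BMI are excluded up front with a warning. Sex ratio is not
matched; the cohort summary reports it so imbalance stays visible.

## Per-platform transforms

Each platform gets the transform suited to its scale, applied before the
multivariate (PCA+LDA) stage:

* quantitative clinical variables: `v = 1/(1 + exp(-(x - Med_j)/IQR_j))`
  per column (`robust_logistic_transform()`), a median/IQR standardisation
  squashed into (0, 1) so outliers cannot dominate; binary columns pass
  through as 0/1. Column medians map to 0.5.
* culture/MALDI abundances: zeros retained, nonzero entries `log10(x)`
  (`log10_nonzero_transform()`). Note the map sends both 0 and 1 to 0 and
  values in (0, 1) to negative numbers; the function logs a message when
  such inputs occur, since CFU-scale culture abundances normally exceed 1.
* qPCR relative concentrations: `v = tanh((x - Med_j)/IQR_j)`
  (`tanh_robust_transform()`), the (-1, 1) analogue of the logistic map.
  The identity `tanh(z) = 2*logistic(2z) - 1` ties the two transforms
  together and is used as a cross-check in the tests.
* 16S counts: low-abundance binning (`bin_low_abundance()`): counts below
  31 become 0, counts 31-99 become 75, counts 100-149 become 125, all other
  counts are unchanged. The rule smooths sampling noise in rare families;
  boundaries are inclusive integers, and the map is idempotent.

Scale parameters (median, IQR) are fit on the combined matched case+control
samples so both groups share one map; fitting per group would manufacture
group differences. IQR uses the linear-interpolation quantile convention
(R type 7); the convention matters because it shifts transformed values.
All three continuous transforms are monotone per column, so they do not
change Mann-Whitney ranks; the testing stage therefore operates on the
untransformed (or binned) values, and direction arrows are taken from
median differences on that same scale.

The default NGS order is rarefy, then bin, then test. The alternative
(bin first) is available by calling the primitives directly; binning
post-rarefaction keeps the binning thresholds meaningful at the common
depth.

## qPCR quantification

Per assay, a standard curve `Ct = slope * log10(copies) + intercept` is fit
by least squares to a serial-dilution series spanning at least two decades
(`fit_standard_curve()`); a perfect-efficiency assay has slope about -3.32.
Quantification inverts the line: `C = 10^((Ct - intercept)/slope)` gene
copies per uL (`quantify_target()`). Missing Ct is treated as true absence
(concentration 0) rather than recoded as a late cycle, so absence stays
distinct from a weak signal. Replicate wells are averaged on the Ct scale
before quantification; failed replicates are dropped from the mean unless
all replicates failed.

Because bacterial genomes carry different numbers of 16S gene copies,
gene-copy concentrations are divided by a per-taxon copy number
(`copy_number_correct()`); the bundled table is a synthetic stand-in with
representative values and is meant to be replaced by the user's reference.
The per-sample total bacterial concentration comes from a universal V4
assay — not from summing the targeted assays, which would omit everything
unassayed — and is itself divided by an average copy number (default 4.2,
configurable), so numerator and denominator are both organism equivalents.
Each sample is then scaled so its implied total is exactly 1e7 organisms
per uL (`normalize_to_total()`), making concentrations comparable across
samples; the output is invariant to any common per-sample rescaling.

## Diversity

Rarefaction subsamples each sample without replacement to a common depth
(`rarefy()`, via `vegan::rrarefy`); samples below the depth are dropped with
a warning. The full-scale convention is 19,000 reads; the synthetic tables
in this package use 3,000 at a simulated mean library size of 4,000, which
preserves the estimator behaviour at desk scale. Six alpha indices are
computed per sample (`alpha_indices()`): Shannon H' in base 2 (the common
amplicon-workflow default; the base is configurable through the underlying
call), Pielou H'/log2(S_obs), Simpson 1 - sum(p^2), Chao1 with the classic
F1^2/(2*F2) correction term replaced by F1(F1-1)/2 when no doubletons exist,
Faith's PD as the branch length of the minimal rooted subtree spanning the
observed taxa *including the path to the root* (stated explicitly because
conventions differ), and Strong's dominance index, defined as the maximum
deviation of the cumulative rank-abundance curve from the uniform line —
the index is named but not defined in many workflows, so the definition is
pinned here and tested against closed forms.

Trees are midpoint-rooted (`midpoint_root()`, via `phangorn::midpoint`) so
the two deepest leaves are equidistant from the root. UniFrac
(`unifrac()`, via `phyloseq::UniFrac`) provides the qualitative
(unweighted) and quantitative (weighted) beta-diversity views; the weighted
variant is non-length-normalised by default with normalisation as a flag.
The test suite checks both against a brute-force edge-by-edge summation on
small random trees. How a distance matrix feeds a two-sample test is not
specified by the upstream procedure; `beta_group_test()` implements the
natural interpretation — mean between-group minus mean within-group
distance, with a label-permutation p-value — and is documented as an
interpretation, not a transcription.

## Hypothesis testing

Each feature is tested with a Mann-Whitney U (midranks for ties) whose
two-sided p-value is estimated by Monte Carlo permutation of group labels —
the "Monte Carlo algorithm" is interpreted as label-permutation resampling,
the natural scheme for a two-sample rank statistic. The add-one correction
`p = (1 + #extreme)/(1 + n_sim)` keeps p-values valid (never zero) at any
simulation count. The permutation loop is compiled code driven by R's RNG,
so `set.seed()` governs it; the full-scale convention is 1e6 simulations
per test, tests in this package run at 1e4-1e5.

Effect sizes use the rank eta-squared `(H - k + 1)/(n - k)` with H the
tie-corrected Kruskal-Wallis statistic (ties are ubiquitous after binning,
so tie correction is not optional). The estimate can dip slightly below 0
under the null and is reported unclamped, with a clamped display option.
Binary clinical indicators get a Fisher-type Monte Carlo test
(`fisher_mc()`: hypergeometric sampling of tables with fixed margins,
two-sided by the point-probability criterion) and the phi coefficient.

All p-values of a comparison are corrected with Benjamini-Yekutieli, the
FDR procedure valid under arbitrary dependence — appropriate because
compositional features are anything but independent. The correction pool
defaults to the features of one platform; `compare_groups(extra_p = ...)`
extends the pool across platforms for the study-wide correction, and
`analysis/06_culture_comparison.R` shows that pooled mode.

## PCA + LDA discriminant axis

`select_components()` runs a centred, unscaled PCA (as `prcomp` defaults)
and keeps the smallest leading set of components whose cumulative explained
variance reaches one third, capped at 10. "About a third" and the cap are
both stated by the upstream procedure but not the tie between them; we
operationalise the target as ">= 1/3, cap binds first if reached" and flag
the shortfall when the cap binds. `fit_discriminant()` computes the
two-class Fisher axis `w ~ Sw^-1 (mu_case - mu_ctrl)` on the retained
component scores — written directly rather than through a classifier
wrapper so the singular case can fall back to ridge regularisation
(epsilon = 1e-8 x trace) with a flag; the tests verify the axis is
collinear with the classical LDA solution. The axis sign is oriented so the
case-group mean score is positive, making runs deterministic. Original
variables are attributed to the axis by Spearman correlation with the
per-sample scores; `|rho| >= 0.3` flags a variable as
discriminant-associated.

`method_effect_check()` reuses the same machinery with the DNA extraction
kit (FS vs PF) as the class label and a label-permutation p-value on the
standardised axis separation (10,000 permutations by default). The
upstream workflow shows separation box plots with a significance label but
does not name the test; a permutation test is the assumption-free choice
and is labelled as such. The recommendation is "combine" when p >= 0.05 and
"stratify" otherwise.

## Synthetic cohorts

The generator module exists so every downstream stage is testable without
patient data, and its defaults are fixed study conditions, not tuning
knobs: a disease group of 40 (age 68 +/- 8.6 years, BMI 28 +/- 3.5, 90%
male) against a control pool of 34 (53 +/- 13 years, 25 +/- 4, 25% male),
the shape of a heart-failure cohort against hospital controls. Ages are
truncated to [18, 95] years and BMI to [15, 45] kg/m^2 to avoid impossible
covariates. Counts are Dirichlet-multinomial: group base proportions
(geometric-decay rank-abundance over 25-30 families), a per-sample
Dirichlet draw at concentration 100 — a realistic 16S overdispersion
level — and a multinomial read draw at library size N(4000-5000, 500-1000),
a deliberate scale-down of real sequencing depth. Planted effects multiply
a group's base proportions by `2^log2fc` before renormalisation; note the
compositional closure this induces in all other taxa, which is why planted
recovery tests also track the false-flag rate among null taxa. qPCR plates
are generated by inverting the quantification line with N(0, 0.15) cycles
of Ct noise; zero concentration emits a missing Ct. Culture profiles are
zero-inflated log-normal. Negative-binomial per-taxon simulation, raw-read
simulation, chimeras and primer bias are out of scope.

What the generator does *not* emulate bounds what passing tests show:
real 16S data have taxon-correlated overdispersion, batch structure and
taxonomic misassignment that Dirichlet-multinomial noise does not produce,
and real qPCR has efficiency drift beyond a log-linear curve. The tests
demonstrate that the procedures are implemented correctly and behave as
designed under their stated model, not that the model captures every
property of real cohorts.

## Numerical choices and degenerate inputs

* MC p-values: add-one correction; permutation extremeness uses a 1e-9
  slack so ties at the observed statistic count as extreme.
* Constant features are skipped with a log message (no rank test exists);
  constant columns pass through the robust transforms with a warning.
* IQR = 0 columns are passed through untransformed rather than dividing by
  zero.
* All-zero samples return missing alpha indices.
* `effect_size_eta2` errors when n <= k; `fisher_mc` returns p = 1 with a
  degenerate flag when a margin is zero; `phi_coefficient` returns NA.
* Matching ties are broken by smallest sample id; medoid ties likewise.
* Reported problem sizes: the test suite and the acceptance script run
  matching over 20 synthetic cohorts (45 vs 35), MC-vs-exact comparisons on
  200 rank-test and 100 Fisher instances at 5,000 simulations, null
  calibration over 1,000 features at 10,000 simulations, and 20 end-to-end
  planted-recovery replicates (40 vs 34 samples, 25 taxa, 4,000
  simulations per feature) — sizes chosen as the package's desk-scale
  defaults.

## Known limitations

* Algorithm II as originally stated diverges; the corrected variant is opt-in.
* Equal group sizes with both matching variables violated at entry has no
  defined algorithm and raises an error naming the condition.
* The matching procedure is greedy trimming, not optimal matching;
  propensity scores and bipartite matching are out of scope by design.
* The log10 culture transform collides 0 and 1; downstream ranks are
  unaffected for CFU-scale data but users log-transforming small values
  should heed the logged message.
* The bundled 16S copy-number table is synthetic; real analyses must
  supply their own reference.
* Compositional differential-abundance methods (CLR-based, ANCOM-style)
  are deliberately not provided; the testing layer is the rank-based
  procedure described above.
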