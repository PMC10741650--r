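---
title: "Methods: two-sample MR with mediation decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Observational associations between haematological exposures (such as the
platelet indices: platelet count, plateletcrit, mean platelet volume,
platelet distribution width) and vascular outcomes such as ischaemic stroke
are prone to confounding and reverse causation. Two-sample Mendelian
randomization (MR) sidesteps both by using genetic variants as instrumental
variables: alleles are assorted at random at meiosis, so a variant robustly
associated with the exposure provides a quasi-randomized contrast, and
summary statistics for exposure and outcome can come from different,
non-overlapping GWAS.

`mrmediate` implements the full workflow: instrument quality control and
allele harmonization, the univariable estimator suite with its sensitivity
analyses, multivariable MR (MVMR), and a two-step mediation decomposition
that asks how much of an exposure's effect on the outcome travels through a
mediator such as systolic or diastolic blood pressure. A synthetic
summary-statistics generator with known causal structure makes every stage
testable without access to the original cohort data.

## Instrument selection and harmonization

A variant qualifies as an instrument when its exposure association passes
genome-wide significance (`p_threshold`, default 5e-10), it is not on the
user-supplied confounder exclusion list (a packaged list of seven
lipid-associated SNPs, `lipid_confounder_snps()`, covers the blood-lipid
pathway that confounds platelet-index analyses), its F-statistic
$(\beta/\mathrm{SE})^2$ is at least `f_threshold` (default 10), and it is
independent of already-retained variants. Independence is decided greedily
in order of ascending p-value against a user-supplied pairwise r² table
(`ld_r2_threshold`, default 1e-4); variants absent from the table count as
independent, which matches the generator's unlinked output. The defaults
are deliberately strict — some published analyses use 5e-8 and r² < 0.001 —
and both are plain arguments of `qc_config()`.

Harmonization expresses every trait's effect for the exposure's effect
allele. Swapped allele labels negate the effect and reflect the frequency;
A↔T / C↔G complementation resolves strand flips before matching.
Palindromic variants (A/T or C/G pairs) are the one genuinely ambiguous
case: allele labels cannot distinguish a strand flip from a label swap, so
orientation rests on allele frequency alone, and variants whose frequency
lies within `palindromic_eaf_window` (default 0.08) of 0.5 in either trait
are dropped as uninformative. The window is standard practice rather than a
published constant, and it is exposed as an argument.

## The estimator suite

With harmonized per-variant effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$ and
outcome standard errors $\sigma_{Yj}$:

* **IVW** (primary): the inverse-variance weighted mean of the Wald ratios
  $\hat\beta_{Yj}/\hat\beta_{Xj}$ with weights
  $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$, identical to weighted
  through-origin least squares. The fixed-effect SE is
  $1/\sqrt{\sum w_j}$; the multiplicative random-effects SE inflates it by
  $\sqrt{Q/(n-1)}$ when Cochran's $Q$ exceeds its degrees of freedom.
  `mode = "auto"` applies the inflation exactly when overdispersion is
  present; both SEs are always kept in the result so the two conventions
  stay comparable.
* **MR-Egger**: the same regression with a free intercept after orienting
  all exposure effects positive; the intercept estimates directional
  pleiotropy and its two-sided t-test (df $n-2$) is the pleiotropy test.
* **Weighted median**: the inverse-variance weighted median of the ratios,
  interpolated where the centred cumulative weight crosses one half;
  consistent while valid instruments hold more than half the weight. Its
  SE comes from a seeded parametric bootstrap (default 1000 draws).
* **Cochran's Q, leave-one-out**: dispersion of the ratios about a
  reference estimate, and the IVW estimate re-fit omitting each variant.
  First-order weights are used throughout so that $Q$ at the IVW estimate
  equals the weighted residual sum of squares of the fit; with very strong
  instruments the neglected exposure-side noise inflates the null
  rejection rate only slightly (about 0.057 at the default study scale,
  measured by the calibration suite).
* **Outlier screen (MR-PRESSO style)**: each instrument's
  variance-standardized squared deviation from its leave-one-out IVW
  prediction is summed into an observed RSS and compared against `n_sim`
  seeded parametric simulations under the no-pleiotropy model; per-variant
  empirical p-values are Bonferroni-adjusted over instruments, flagged
  outliers are removed, and a corrected IVW estimate is reported alongside
  — never silently substituted for — the primary one.
* **Steiger directionality**: per-variant variance explained via the
  t-statistic transform $r^2_j = t_j^2/(t_j^2 + n - 2)$, summed per trait;
  the orientation is supported when the instruments explain more variance
  in the exposure than the outcome. The transform needs no allele
  frequencies or case fractions, which makes it usable for binary outcomes
  summarized without a liability-scale correction; the p-value is a
  Fisher-z comparison across the two independent samples. The pipeline
  runs this screen first and *flags* failing pairs
  (`reverse_causation_flag`) rather than dropping them.

All p-values are two-sided. The pipeline labels p < `alpha_family /
n_tests` (default 0.05/5 = 0.01) "significant" and 0.01–0.05 "potentially
significant", a Bonferroni convention for a family of five outcomes
(stroke, ischaemic stroke, and three aetiological subtypes).

## Multivariable MR and mediation

`mvmr_ivw()` regresses outcome associations jointly on several exposures'
associations (weights $1/\sigma_{Yj}^2$, through the origin), giving each
exposure's *direct* effect conditional on the others. Rank deficiency
raises an error naming the collinear pair; a condition number above 30
triggers a warning, because strongly correlated exposures — systolic with
diastolic blood pressure being the canonical example — leave the separate
direct effects poorly identified even when the joint fit is fine.

The two-step decomposition follows the standard path diagram: the total
effect $C$ (univariable MR, exposure → outcome) splits into the direct
effect $C'$ and the indirect effect $A \times B$, where $A$ is the
exposure's total effect on the mediator (univariable MR) and $B$ the
mediator's effect on the outcome adjusted for the exposure (MVMR on the
union of both traits' instruments). The mediated proportion is
$AB/C$; the difference-method proportion $(C - C')/C$ is reported as a
cross-check and the two agree exactly on noiseless linear truth.

For the proportion's CI the package defaults to a seeded parametric
bootstrap — normal draws of $(A, B, C)$ with the proportion recomputed per
draw and percentile limits taken — because the ratio is poorly
approximated by a normal when $C$ is imprecise; a warning fires when more
than 1% of draws put $C$ across zero. The delta method
($\mathrm{var}(AB) \approx A^2\sigma_B^2 + B^2\sigma_A^2$, ratio variance
with zero covariances) is available as a fast cross-check and agrees with
the bootstrap to within 10% of interval width on well-conditioned cases.
Covariances between $A$, $B$ and $C$ are set to zero, the usual two-step
assumption for estimates built from non-overlapping samples; this is a
documented approximation, not an estimated quantity.

## The synthetic-data generator

`simulate_study()` emulates the *post-clumping* state of three large GWAS:
unlinked variants, effects per effect-allele copy, and sampling noise
$\sigma = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ per variant — with
the binary outcome's $n$ replaced by the effective size
$4/(1/\mathrm{cases} + 1/\mathrm{controls})$. Defaults mirror the study
conditions the package targets: 86 exposure instruments at an exposure
GWAS of n = 350,474, a mediator GWAS of n = 757,601, an outcome GWAS of
40,585 cases / 406,111 controls, total effect $C = 0.107$ log-odds per SD
(an odds ratio of 1.113) with 28% mediated.

Choices worth stating explicitly:

* **Per-variant instrument strength** is drawn uniformly on
  $r^2 \in [3\times10^{-4}, 2\times10^{-3}]$ of trait variance, typical of
  the strong loci of highly heritable haematological and blood-pressure
  traits at biobank scale (median F ≈ 400 at n = 350k). The draw's sign is
  random, so effects are zero-mean and symmetric, and the lower bound
  keeps essentially every exposure variant genome-wide significant — the
  generator's instrument counts are therefore configured counts.
* **Mediator-specific instruments** (`n_mediator_variants`, default 80)
  carry effects on the mediator only. They are essential, not cosmetic:
  if every variant's mediator effect were exactly $A\gamma_j$, the MVMR
  design matrix would be collinear by construction and $B$ would be
  unidentified. Real mediators have their own genetic architecture, and
  MVMR practice selects instruments for each exposure in the model; the
  generator reproduces that.
* **The exposure→mediator effect** defaults to $A = 0.3$ SD/SD. Published
  per-SD "odds ratios" for continuous blood-pressure outcomes are
  unit-ambiguous (exponentiated linear betas); 0.3 is a realistic SD-scale
  effect that, with $C = 0.107$ and 28% mediated, implies
  $B \approx 0.10$ — of the same order as published per-unit
  blood-pressure-to-stroke log-odds.
* **Pleiotropy** (`pleiotropy_sd`, `invalid_fraction`) adds direct
  mediator and outcome effects to a chosen fraction of exposure variants;
  zero by default so the clean-instrument assumptions hold exactly.
* **Binary-outcome effects are generated directly on the log-odds scale**
  rather than through a liability threshold: simpler, and sufficient for
  testing estimators that only ever see summary statistics.
* An optional **LD-block mode** (`ld_block_size` > 1) copies each causal
  signal across a block and emits the pairwise r² table, exercising the
  greedy clumping path; within-block noise is drawn independently, an
  acknowledged simplification of true LD.

What the generator does *not* emulate — sample overlap between cohorts,
population structure, winner's-curse selection into the exposure GWAS,
liability-scale attenuation, real LD — bounds what passing tests show:
they demonstrate correctness and calibration of the estimators under the
stated model, not robustness to those additional features of real data.

## Calibration and problem sizes

The package's acceptance suite, which doubles as its calibration report,
uses these problem sizes (chosen to estimate each rate with useful
precision at desk scale): IVW 95% CI coverage over 1000 simulated studies
of 86 instruments (target band 0.93–0.97; measured ≈ 0.947); Cochran's Q
null rejection at 0.05 over 2000 studies (band 0.035–0.065; measured
≈ 0.057); mediated-proportion recovery for true proportions
{0, 0.25, 0.5} over 200 studies each (mean absolute error < 0.05; measured
≤ 0.036); and recovery of a planted 10-SD pleiotropic outlier among 20
clean instruments in at least 95 of 100 studies (measured 100). The
oracle tests hold IVW, Egger and MVMR to a generic least-squares solver at
1e-10 relative error, and the weighted median to exhaustive enumeration.

## Degenerate inputs and numerical conventions

Zero exposure effects make the Wald ratio undefined and raise an error; a
zero total effect makes the mediated proportion undefined and is flagged
(`proportion_defined = FALSE`) rather than thrown, since downstream
reporting should show the null total effect. Ties in the greedy clumper
are broken by variant ID for determinism. Every stochastic routine
(weighted-median bootstrap, outlier simulations, proportion bootstrap, the
generator) takes an explicit seed and restores the caller's RNG state;
`run_pipeline()` derives all of them from one configuration seed, so a
rerun reproduces the report bundle bit for bit. Odds ratios are printed to
three decimals with Wald 95% limits, matching the convention of published
MR tables.

## A worked run

```{r example, eval = FALSE}
study <- simulate_study(simulation_config(seed = 11))
cfg <- pipeline_config(
  exposures = list(pct = study$tables$exposure),
  outcomes = list(stroke = study$tables$outcome),
  mediators = list(sbp = study$tables$mediator),
  seed = 11
)
report <- run_pipeline(cfg)
report$estimates
report$mediation_table
plot_forest(report$estimates)
```

## Known limitations

Instrument re-selection happens per exposure–outcome pair (and per MVMR
model), which is the conservative reading of multi-outcome MR practice;
analyses that reuse one instrument list across outcomes will differ
slightly. The Steiger screen uses total-sample r² without liability-scale
correction for binary outcomes. Proxy-SNP lookup, reference-panel LD
estimation and external confounder databases are out of scope: LD enters
only through a user-supplied r² table and confounders only through an
explicit exclusion list.
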