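---
title: "Methods: cross-species methylation clocks and age EWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species methylation clocks and age EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhesusclocks)
```

This vignette is the package's account of its methods: the models and
procedures implemented, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## The clock model

An epigenetic clock here is a sparse linear model predicting a transform
of chronological age from CpG beta values (methylation fractions in
[0, 1]):

$$ g(\mathrm{age}_i) = \beta_0 + \sum_j w_j x_{ij} + \varepsilon_i $$

fitted by elastic-net regression with mixing parameter $\alpha = 0.5$
(midway between ridge and lasso, the convention for methylation clocks;
it is deliberately not tuned). The penalty strength $\lambda$ is chosen by
tenfold internal cross-validation minimizing mean squared error — the
`cv.glmnet` `lambda.min` rule, not the 1-SE rule. Predictors are
standardized inside the solver and coefficients are returned on the beta
scale. The number of CpGs retained is data-dependent, typically a few
dozen at the package's desk-scale problem sizes.

Degenerate case: if the selected $\lambda$ keeps no CpG (possible when the
signal is absent, e.g. permuted ages), the fit falls back to the strongest
penalty on the path that retains at least one CpG — the most parsimonious
non-empty model — so that a `clock_model` always has at least one weight.

### Age transforms

Three invertible transforms of the dependent variable are provided:

* **identity** — age in years. Used for single-species clocks.
* **relative age** — `age / max_lifespan`, with per-species maximum
  recorded lifespans (macaque 42 y, human 122.5 y, an approximate 3:1
  ratio). This aligns species on a common [0, 1] scale: a 40-year-old
  macaque is *older* in relative age than a 40-year-old human, a
  distinction no raw-age model can express. The inverse multiplies the
  predicted fraction by each sample's own species lifespan, which is how a
  single fitted model reports calibrated years for both species.
* **log-linear** — piecewise in age with a knot at the species' age of
  sexual maturity $m$ (macaque 4 y, human 15 y) and offset $c > 0$
  (default 1 y):
  $\log\frac{a+c}{m+c}$ for $a \le m$, $\frac{a-m}{m+c}$ for $a > m$.
  Both branches are 0 at the knot and share the derivative $1/(m+c)$, so
  the transform is continuous, differentiable, strictly increasing and
  exactly invertible. The precise functional form of such transforms
  varies across the clock literature; this construction was chosen because
  it is the standard log-then-linear shape, has a closed-form inverse, and
  exposes its two constants (`maturity_age` per species in the sample
  sheet, `offset` in the transform object) rather than hard-coding them.

Species constants live in the sample sheet, not in the transform, so one
clock file applies to any species whose constants are known. Ages above
the recorded maximum lifespan are transformed with a warning rather than
rejected, because predicted ages may legitimately exceed it.

### Cross-validation

All accuracy estimates rerun the *entire* fitting procedure — CpG
selection included — inside each fold:

* `loocv_clock()` — leave one sample out, refit on the other $n-1$,
  predict the held one; the standard unbiased estimate for clocks.
* `kfold_clock()` — folds stratified by species so each fold contains
  every species; reports combined and per-species metrics, the relevant
  quantities for dual-species clocks. A species with fewer samples than
  folds is left unstratified with a warning.
* `loho_clock()` — leave-one-holdout-species-sample-out: iterates
  leave-one-out over one species' samples while all other species remain
  in every training set.

Refit seeds are derived from the held-out sample ids, which makes
`kfold_clock(k = n)` reproduce `loocv_clock()` exactly and keeps every
scheme deterministic for a fixed seed.

Metrics are the field's standard trio: Pearson correlation *R* between
predicted and chronological age, median absolute error (MAE, years), and
the median signed error — the calibration offset. The offset is reported
everywhere because transfer across species can keep *R* high while
shifting predictions by years, which MAE alone obscures.

## EWAS and meta-analysis

`screen_age_association()` computes, per CpG within one tissue, the
Pearson correlation $r$ with age, the two-sided p-value of the correlation
t-test ($t = r\sqrt{n-2}/\sqrt{1-r^2}$, $n-2$ df), and the signed normal
score $Z = \mathrm{sign}(r)\,\Phi^{-1}(1-p/2)$. $Z$ is evaluated in log
space so that p-values far below double-precision underflow still yield
finite scores, then capped at $|Z| \le 40$. Constant CpGs are reported as
missing and excluded downstream. Association is computed against raw
chronological age; tissues with fewer than 4 samples or constant age are
skipped with a warning.

Per-tissue scores are combined by Stouffer's method with sample-size
weights $w_t = \sqrt{n_t}$:
$Z_{meta} = \sum_t w_t Z_t / \sqrt{\sum_t w_t^2}$. The $\sqrt{n}$ variant
is the default because tissue sample sizes in the emulated design are
extremely unbalanced (blood $n = 199$ vs adipose $n = 5$); the unweighted
form is available via `weights = "equal"`. No multiple-testing correction
is applied to the selection step — top CpGs are taken at a fixed nominal
threshold of $p < 10^{-4}$, at most 500 per direction (hyper- and
hypomethylating, by the sign of $Z$), ordered by $|Z|$ with lexicographic
tie-breaks — but Benjamini–Hochberg q-values for the meta p-values are
emitted as an extra column.

`upset_overlap()` partitions the union of top sets into exact membership
patterns (the tabular form of an upset plot), which is how CpGs
age-associated in many tissues at once are found.
`region_distribution()` compares the genomic-context composition
(promoter, 5'UTR, exon, intron, 3'UTR, distal intergenic) of a top set
against the array background.

## Motif enrichment

`motif_enrichment()` takes a precomputed CpG-to-motif match table (motif
scanning itself is out of scope) and tests each motif's over-representation
in a foreground set — by convention the top CpGs restricted to
promoter/5'UTR — against the background of all array CpGs with the
upper-tail hypergeometric test; fold enrichment is $(k/n)/(K/N)$. The
p-value is computed with `stats::phyper`, which is log-stable and exact to
double precision over the relevant range; the test suite verifies it
against complete enumeration on all universes up to $N = 12$. The test
does not adjust for CG content or probe composition — a known limitation
of hypergeometric enrichment on methylation arrays; significant motifs
should be read as candidates, not causal hits.

## The synthetic-data generator

No public individual-level data accompany the emulated study design, so
the package ships a generator whose defaults encode that design and whose
ground truth makes every downstream stage testable.

* **Design**: the macaque arm reproduces the published sampling table —
  281 samples over 8 tissues (blood 199 at ages 1.79–42 y, skin 51 at
  7.61–42 y, six postmortem tissues with n = 4–6), maximum lifespan 42 y.
  The human arm covers ages 0–93 y (lifespan 122.5 y) and is scaled to
  n = 200 so the full pipeline runs at desk scale; a vervet-like transfer
  species (lifespan 30.8 y, n = 40) supports transfer experiments. Only
  per-tissue age ranges are published, so ages are drawn uniformly within
  each tissue's range — a stand-in, not a claim about the real cohorts.
* **Signal**: each tissue gets `n_causal_per_tissue = 100` causal CpGs;
  a shared set (`shared_set_size = 20`) is age-associated with a common
  sign and magnitude in at least 4 tissues and in every species. Effects
  are linear *in relative age* on the logit scale — this is the
  conservation structure that makes dual-species clocks possible, and it
  is the generator's core modelling assumption. Tissue-exclusive causal
  sets are drawn disjointly, so only shared CpGs can be age-associated in
  4 or more tissues.
* **Noise**: observed betas are
  `inverse-logit(baseline + effect * age/max_lifespan + N(0, noise_sd))`
  clipped to `[1e-6, 1 - 1e-6]` — a logit-normal model that keeps betas in
  range with realistic shrinking variance near 0 and 1. Defaults
  `effect_scale = 3` (logit units per unit relative age, with per-CpG
  magnitudes `U(0.5, 1.5)` times that) and `noise_sd = 0.5` put the
  strongest blood CpGs at $|r| \approx 0.85$, i.e. association scores of
  $z \approx 16$ at n = 199 — the magnitude reported for top blood hits in
  real macaque data.
* **Annotation and motifs**: region classes are multinomial with
  configurable proportions; causal CpGs can be biased toward
  promoter/5'UTR (`promoter_bias`) to emulate the concentration of
  age-related change in regulatory regions. Motif matches are Bernoulli at
  a background rate (default 0.05), with one optional planted motif at a
  configurable multiple of that rate on causal promoter CpGs, giving
  enrichment analyses a known positive control.
* **Determinism**: all randomness derives from one master seed through
  named streams (`derive_seed`), the caller's RNG state is preserved, and
  regenerating with the same config is bit-identical.

What the generator does **not** emulate: probe chemistry (type I/II
Infinium), batch and plate effects, missing values, sex-chromosome
effects, non-uniform real age distributions, correlated CpG blocks, or
nonlinear age trajectories. Passing recovery tests therefore demonstrates
the correctness and calibration of the *procedures*, not expected
performance on real arrays.

## Numerical and design choices

* **Lambda path**: the default grid is 30 values down to 5% of
  $\lambda_{max}$ with coordinate-descent tolerance `1e-5`, coarser than
  the `cv.glmnet` defaults (100, 1%, `1e-7`). On logit-normal methylation
  data the selected models are statistically indistinguishable from the
  full-resolution path while fitting about five times faster, which
  matters because leave-one-out evaluation refits the whole procedure
  hundreds of times. The full-resolution settings are one argument away
  (`nlambda = 100, lambda_min_ratio = 0.01, thresh = 1e-7`) and are used
  in the package's own noiseless-recovery tests, where the optimal penalty
  is near zero.
* **Internal folds** are assigned from a dedicated seed stream; ties at
  the top-CpG cap break lexicographically by CpG id; the $|Z|$ cap is 40.
* **Sample weighting**: none — macaque and human samples are weighted
  equally in dual-species fits.
* **Missing clock CpGs** at prediction time are a hard error naming the
  missing probes; `cross_species_eval()` can optionally zero-impute with a
  logged count, but the default refuses, since on shared-probe arrays a
  missing clock CpG usually signals a data-preparation problem.
* **Problem sizes**: the package's reference experiments use 2000 CpGs
  and the design sizes above; recovery experiments that need nominal
  per-tissue power at the $p < 10^{-4}$ selection threshold (multi-tissue
  overlap recovery) use six tissues of n = 100, at which the weakest
  planted effect is detected with probability ≈ 0.999 per tissue. At the
  published minor-tissue sizes (n = 4–6) that threshold is unreachable by
  construction — with 3 degrees of freedom even a perfect rank ordering
  cannot produce $p < 10^{-4}$ — which is why small-tissue top sets are
  expected to be empty in this regime and the overlap experiment is run
  at a design with power.

## Known limitations

* The log-linear transform's exact published form (and its constants) is
  not reproduced; the implemented construction is a documented,
  invertible substitute with the same shape.
* Enrichment ignores CG content and probe density covariates.
* The EWAS uses raw age; transformed-age screening is not implemented.
* The generator's independence of CpGs understates the multiple-testing
  burden of correlated real arrays; calibration results should be read
  accordingly.
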