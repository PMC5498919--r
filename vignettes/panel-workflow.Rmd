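---
title: "Serum biomarker panels for indeterminate pulmonary nodules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum biomarker panels for indeterminate pulmonary nodules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungpanel)
```

## The problem

An indeterminate pulmonary nodule — a lung lesion under 3 cm of uncertain
malignancy found on imaging — poses a triage problem: most are benign, yet
distinguishing the malignant minority currently drives many unnecessary
biopsies. A blood test that separates malignant from benign nodules could
act as an adjunct to imaging. `lungpanel` implements the full statistical
workflow for building and honestly evaluating such a test from serum protein
measurements: pre-analytical quality screening of candidate markers,
penalized-regression panel construction with resampling-based model
selection, internal validation, and a strictly blinded external validation
on an independent matched case–control cohort.

The package ships a synthetic cohort generator with the same statistical
structure as the study design it emulates, so every stage of the pipeline is
exercisable and testable without access to restricted clinical data.

## Stage 1: pre-analytical stability screen

Serum marker levels can change with the time blood is left to clot before
centrifugation, a pre-analytical variable that differs widely between
biobanks. The screen assays each candidate marker in serum from healthy
donors after 0.5 h (reference), 4 h, and 24 h of clotting, and computes per
donor the relative change $(L_t - L_{0.5})/L_{0.5}$.

Two summaries are implemented. The default (`method = "per_donor"`) averages
the per-donor relative changes; the alternative (`"of_means"`) takes the
relative change of donor-mean levels. The per-donor form is the default
because the screen is a within-donor design: each donor is their own
baseline, and averaging ratios weights donors equally regardless of their
absolute concentration.

A marker is deselected when its mean relative change exceeds **20%** in
magnitude at either timepoint. No canonical cutoff exists for this decision;
0.20 cleanly separates a marker losing a quarter to a half of its signal
(clearly unusable across heterogeneous collection protocols) from the
single-digit fluctuations expected from assay noise. The threshold is an
explicit parameter of `deselect_markers()` and of the pipeline
configuration. A direction-consistency flag (all donors moving the same way)
is reported for context but does not by itself drive deselection — the
magnitude criterion comes first, consistency corroborates.

## Stage 2: elasticnet panel training

Panel construction is penalized logistic regression of case status on the
preprocessed marker levels. With $p_i = \Pr(y_i = 1)$,
$\eta_i = \beta_0 + x_i^\top \beta$, the fit minimizes

$$
\frac{1}{n}\sum_i \left[\log(1 + e^{\eta_i}) - y_i\eta_i\right]
 + \lambda\left(\alpha \lVert\beta\rVert_1 +
   \frac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),
$$

with the intercept unpenalized and mixing fraction $\alpha = 0.95$ (95%
lasso, 5% ridge). The dominant lasso component performs marker selection by
driving small coefficients exactly to zero; the ridge component stabilizes
the fit when markers are correlated.

**Preprocessing.** Marker concentrations are natural-log transformed and
standardized to zero mean and unit variance by default: serum concentrations
are right-skewed, and L1/L2 penalties are scale-sensitive, so unequal scales
would silently reweight the penalty across markers. Both toggles are
exposed, and whatever preprocessing was used travels inside the frozen model
so validation subjects are always scored on the training scale.

**Solver.** The path fitter is a proximal-Newton / cyclic coordinate descent
algorithm written in C++: an IRLS quadratic approximation around the current
coefficients, solved by coordinate descent with soft-thresholding,
warm-started along a decreasing penalty grid (default 100 log-spaced values
from $\lambda_{max}$, the smallest penalty with an all-zero solution, down
to $10^{-3}\lambda_{max}$). Convergence at each grid point is declared on
the subgradient (KKT) residual of the *exact* logistic objective (default
tolerance $10^{-8}$; bootstrap refits use $10^{-6}$, since selection depends
only on score ranks), not merely on the quadratic subproblem — so returned
solutions are verifiably stationary points. Updates are cyclic and
deterministic: the same input ordering reproduces a fit bit for bit.
IRLS weights are floored at $10^{-5}$ to keep the working response bounded
when fitted probabilities saturate.

**Penalty selection.** The regularization penalty is chosen by stratified
bootstrap resampling (study value $B = 10{,}000$): each iteration resamples
cases and controls separately with replacement (preserving class counts),
fits the whole penalty path on the in-bag subjects, and scores the
out-of-bag subjects with every path model. The penalty with the greatest
mean out-of-bag AUC is selected; AUC ties resolve to the larger penalty
(the sparser model). Iterations whose out-of-bag set has fewer than two
cases or two controls have no usable AUC and are skipped and counted rather
than imputed. Per-iteration seeds are drawn once up front from the run seed,
so results do not depend on execution order. The grid is computed once from
the full training data and shared by all in-bag fits, which is what makes
"mean AUC per penalty" well defined across iterations.

**Internal validation.** The selected model's generalization is estimated
from the training data by a second bootstrap. The default scheme refits the
model at the selected penalty on each stratified resample and records the
out-of-bag AUC; the point estimate is the mean and the interval the
2.5/97.5 percentiles of the per-iteration values. A Harrell-style
optimism-correction scheme (apparent AUC minus the mean in-bag-vs-full-data
optimism) is available as an alternative. Both are standard; the out-of-bag
form is the default because it reuses the exact machinery of the selection
step. Out-of-bag estimates are mildly pessimistic (each refit sees ~63% of
subjects), so the resulting point estimate sits a little below the apparent
AUC — the qualitative pattern expected of any honest internal validation.

## Stage 3: blinded validation

The final model is frozen to a human-readable text file (coefficients,
penalty, preprocessing parameters) before the validation cohort is touched;
`validate_cohort()` records the file's MD5 checksum in its report and never
modifies the model, and the pipeline verifies the checksum of the file it
re-reads against the one written at training time.

The validation analysis set mirrors the matched design:

* **Panel and single-marker ROC per finding stratum.** Controls are matched
  to cases within radiographic finding (nodule, mass, other), so analyses
  never mix controls across strata. Single markers are scored as their raw
  concentration (higher = more suspicious) — the AUC is rank-based, so no
  refit is needed or appropriate.
* **Stage and histology subgroups.** Each tumor stage (IA–IV) and histology
  group (adenocarcinoma, squamous cell, all other histologies) among nodule
  cases is compared against the *full* benign-nodule control group, not just
  the matched partners of the subgroup's cases: the controls are exchangeable
  within the stratum and the full group gives the better-powered comparison.
  Cases with unresolved stage (`NA`, or the aggregate label `I`) appear in
  overall analyses but not in stage-specific ones. Subgroups with fewer than
  two cases are flagged rather than computed.
* **Attenuation.** `auc_delta_table()` reports per-marker
  $\mathrm{AUC}_{train} - \mathrm{AUC}_{valid}$ and their mean, the
  headline measure of how much marker performance decays from an enriched
  training population to a pre-diagnostic screening population.

All ROC inference is DeLong's nonparametric method on placement values: for
a case, its placement is the fraction of controls it outscores (ties count
half), and symmetrically for controls. The AUC variance is
$\widehat{var}(P_{cases})/m + \widehat{var}(P_{controls})/n$; paired AUC
comparisons add the placement covariances. Confidence intervals are
untransformed Wald intervals $\hat{A} \pm z_{0.975}\,\mathrm{se}$ truncated
to $[0,1]$ — the symmetric form, chosen over the logit-scale interval
because the package reports intervals the way diagnostic-accuracy tables
conventionally print them, symmetric about the AUC. The p-value tests
$A = 0.5$ by the DeLong z statistic (a Mann–Whitney test is available as an
alternative). Ties contribute $1/2$ throughout, which is what makes
$A(a,b) + A(b,a) = 1$ hold exactly.

`sensitivity_at_specificity()` scans all empirical thresholds (positive
when score $> t$) and returns the best sensitivity among thresholds meeting
the specificity floor — the operating-point summary used to judge clinical
utility (e.g. against an "80% sensitivity at 90% specificity" adjunct-test
benchmark).

## The synthetic cohort generator

The generator is a first-class, tested module that encodes the study
conditions:

* **Distributions.** Marker levels are log-normal: multivariate normal on
  the log scale with per-marker means/SDs and a common pairwise correlation
  (default 0, configurable). Serum tumor-marker concentrations are
  right-skewed and positive, which log-normality captures with the fewest
  assumptions.
* **Effects.** Cases are shifted by $\delta\sigma$ on the log scale. The
  default panel has nine candidates: five informative markers (CEA,
  CYFRA 21-1, OPN, SCC, TFPI) at $\delta = 0.8$, three stable null markers
  (MMP2, SLPI, TIMP1), and MDK, uninformative and carrying the strong
  clotting drift ($0.74\times$ at 4 h, $0.52\times$ at 24 h) the screen is
  meant to catch. With independent markers the closed-form panel AUC is
  $\Phi(\sqrt{5}\,\delta/\sqrt{2}) \approx 0.90$ and the single-marker AUC
  $\Phi(\delta/\sqrt{2}) \approx 0.71$ — the performance scale of the
  training study. These closed forms are also what the tests check
  convergence against.
* **Attenuation.** Validation shifts are $\kappa\delta$ with $\kappa$
  solving $\Phi(\kappa\delta/\sqrt{2}) = \Phi(\delta/\sqrt{2}) - 0.10$
  (`attenuation_kappa()`; $\kappa \approx 0.51$ at $\delta = 0.8$), i.e. a
  mean single-marker AUC fall of about 0.10 between studies — the magnitude
  of train-to-validation decay the workflow is designed to surface.
* **Cohort structure.** The default configurations reproduce the study
  sizes: training 95 cases / 186 controls (all stage I); validation 119
  matched nodule pairs, 50 mass pairs, 28 other-finding pairs. Stage and
  histology labels are apportioned to cases at exactly the configured
  frequencies by largest-remainder rounding and then assigned to random
  rows — subgroup sizes are thus exact (e.g. 51 stage-IA nodule cases) while
  everything else remains seed-driven. Matched controls are generated from
  their case: same finding and gender, age within ±5 years, pack-years
  within ±20 (the matching caliper, enforced on output).
* **Clotting series.** A donor's 0.5 h level is a draw from the control
  distribution; later timepoints multiply by the marker's drift factor with
  log-normal measurement noise (default SD 0.05).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: assay floor/ceiling effects and standard-curve
nonlinearity, batch and plate effects, heavy-tailed or multimodal marker
distributions, missingness, correlation between marker levels and the
matching covariates, and any real biological correlation structure beyond a
single common pairwise correlation. Tests passing on synthetic cohorts
demonstrate that the *procedure* is implemented correctly and behaves as
designed under its assumed data-generating process, not that the panel would
achieve any particular accuracy on clinical samples.

## Numerical choices and degenerate inputs

* Penalty grid: 100 log-spaced values, `lambda_min_ratio = 1e-3`; standard
  path practice, configurable because nothing forces these values.
* KKT tolerance $10^{-8}$ for reported fits, $10^{-6}$ inside bootstrap
  loops; coordinate-descent inner tolerance $10^{-9}$ on the maximum
  coefficient change.
* AUC with fewer than two cases or controls: undefined; such bootstrap
  iterations are skipped and counted, such subgroups flagged.
* Perfect separation: the DeLong variance is legitimately zero; the CI
  degenerates to a point and the p-value to 0. The elasticnet at very small
  penalties on separable data is capped by `max_outer` and reports
  non-convergence rather than silently returning a diverging fit.
* Zero-variance markers are rejected by name at preprocessing; nonpositive
  concentrations are rejected at the log step and at file ingestion (with
  the offending row).
* Mean-OOB-AUC ties across penalties resolve deterministically to the
  largest penalty.

## Problem sizes used in tests and scripts

The analysis drivers default to $B = 2{,}000$ bootstrap iterations
(`LP_B=10000` reproduces the study value; the acceptance script always uses
10,000). The test suite exercises the selection machinery at $B$ between 25
and 500 with 40–50-point grids, and the marker-recovery checks run 50
replicate cohorts at the study's class sizes (95/186). These sizes were
chosen so the full suite completes in a few minutes while leaving
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The bootstrap internal-validation scheme reported alongside the apparent
  AUC is one of several defensible conventions (mean-OOB vs optimism
  correction); both are implemented, and they can legitimately differ by a
  few hundredths of AUC.
* Penalty selection by maximum mean OOB AUC sits on a very flat objective:
  widely different penalties can be statistically indistinguishable, so the
  *selected panel* (not the selected $\lambda$) is the stable object of the
  procedure.
* The lasso-dominant penalty keeps weakly contributing markers at small
  nonzero coefficients when the AUC-optimal penalty is small; panel
  membership should be read jointly with coefficient magnitudes.
* Subgroup AUCs against the full stratum control group reuse controls
  across subgroups; the subgroup estimates are therefore correlated with
  one another.
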