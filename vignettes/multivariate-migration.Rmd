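---
title: "Modelling 3D femoral stem migration as a multivariate repeated measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 3D femoral stem migration as a multivariate repeated measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemrsa)
```

## The problem

Radiostereometric analysis (RSA) measures the micromotion of an implanted
femoral stem relative to tantalum bone markers as six degrees of freedom per
examination: translations (mm) along the transverse (x), longitudinal (y)
and sagittal (z) axes and rotations (degrees) about the same axes, each
expressed as change from the post-operative baseline. The clinically
dominant direction is subsidence - distal (negative) y-translation - but
migration is a genuinely three-dimensional event: a subsiding stem also
rotates about its long axis and tilts into varus or valgus, and the
alignment of the RSA coordinate frame with any anatomical direction is
approximate. Conventional practice nevertheless analyses each axis with its
own univariate test, or collapses the motion into scalar surrogates (total
translation, total rotation, maximum total point motion) that discard
degrees of freedom.

`stemrsa` implements the alternative: a single hierarchical linear mixed
model (LMM) in which *both* the follow-up time point and the migration axis
are repeated measures, so that all available observations of a two-arm
trial enter one model and the treatment comparison is a joint test of the
3D mean migration.

## The model

For subject $i$, let $y_i$ collect the observed change-from-baseline values
over the visit-by-axis grid (up to $n_v \times 6$ cells; any cell may be
missing). The marginal model is

$$ y_i \sim N(X_i \beta,\; \Sigma[\mathrm{obs}_i, \mathrm{obs}_i]), $$

with fixed effects for treatment group, visit, axis and their interactions
(sum-to-zero contrasts, so joint tests of a term's coefficients are
Type-III style), and a within-subject covariance $\Sigma$ over the
visit-by-axis cells shared by all subjects. Three structures are available:

* `kronecker_un` (default): $\Sigma = T \otimes A$ with an unstructured
  visit factor $T$ ($n_v \times n_v$) and an unstructured axis factor $A$
  ($6 \times 6$). The Kronecker product is scale-confounded, so $T[1,1]=1$
  is imposed for identifiability. With 3 visits and 6 axes this spends
  $5 + 21 = 26$ covariance parameters.
* `full_un`: a single unstructured $\Sigma$ (171 parameters at $18 \times
  18$) - the sensitivity model in which the Kronecker model is nested; the
  REML criterion of `full_un` is never worse, which the test suite checks.
* `diagonal`: independent cells, one variance per visit-by-axis cell - the
  bridge to classical theory (with one axis and one visit the group test
  collapses exactly to the pooled two-sample t-test).

Because each subject contributes the likelihood of its observed cells only,
sporadically missing RSA visits need no imputation; the mechanism is
assumed missing at random. Mixed units (mm next to degrees) need no
rescaling for estimation or testing: the unstructured covariance absorbs
the scale of each axis, and the joint group test is invariant under any
fixed invertible linear map of the axis block (also checked in the tests).
Only for *display* of a blended "3D migration" trajectory does the package
standardise, dividing each axis by its pooled SD
(`build_model_frame(standardize = TRUE)`); both the raw per-axis and the
standardised LS-means are emitted by `run_pipeline()`, since mm and degrees
cannot be averaged on their native scales.

### Estimation and small-sample inference

Covariance parameters are estimated by REML. The search runs on a
log-Cholesky parameterisation (diagonal entries of the Cholesky factor on
the log scale), which makes every iterate positive definite by
construction - a non-PD proposal can never surface as a crash. A BFGS
quasi-Newton phase with analytic gradients is followed by Fisher-scoring
polish steps on the expected information until the gradient norm falls
below `gtol` (default $10^{-6}$, relative to $1 + |{-2\ell_R}|$); after the
configured restarts a fit that has not converged raises a diagnostic error
naming the residual gradient norm. Starting values are deterministic moment
estimates (cell-wise residual covariance, eigenvalue-clipped to PD, with a
trace-matching split into $T$ and $A$ for the Kronecker structure); there
are no random starts, so a fit is reproducible by its inputs alone. The
accepted objective trace is stored in the fit and is non-increasing.

F-tests use the Kenward-Roger small-sample adjustment: the fixed-effect
covariance is inflated for the uncertainty of the estimated covariance
parameters, and the denominator degrees of freedom and F scale come from
moment matching. Derivatives are taken in the linear basis of distinct
covariance entries; for the Kronecker structure $V$ is bilinear in the
entries of $T$ and $A$, so the second-derivative (cross) term is included.
The adjustment is exact in the classical cases, which the test suite pins
down: a single-response two-group model gives $F = t^2$ with denominator
df $n_1 + n_2 - 2$ to $10^{-9}$, and the balanced complete single-visit
six-axis case reproduces the two-sample Hotelling $T^2$ test to $10^{-6}$.

On top of the fit, the package provides the joint 3D group test (all
group-involving terms at once, `test_3d_group_effect()`), per-axis effect
slices averaged over visits with equal weights (`slice_by_axis()`;
per-visit margins are available through `lsmeans()`), LS-means with
KR-based intervals, and deterministic backward elimination of
non-significant interactions (`simplify_model()`: largest p first, ties by
term name, marginality preserved, main effects never dropped).

## Quality control and outliers

Marker stability and scatter are summarised by the mean error of
rigid-body fitting (ME) and the condition number (CN). ME is the Kabsch
least-squares superposition residual in the $\sqrt{\sum d_i^2/(n-1)}$
convention. CN is `scale` divided by the smallest singular value of the
centred marker cloud - the spread along the weakest principal direction,
which governs the sensitivity of the fitted rotation. CN conventions
differ across RSA platforms, so the scale constant (default 1000 mm,
placing typical trochanteric configurations in the 30-150 range) and the
acceptability thresholds (ME > 0.35 mm, CN > 150) are configuration
defaults rather than hard-coded rules.

Outlying subjects are identified per axis with Tukey fences
($Q_1 - 1.5\,\mathrm{IQR}$, $Q_3 + 1.5\,\mathrm{IQR}$; type-7 quartiles;
strictly-outside values flag). The package also ships the frozen cutoffs
that defined the source trial's without-outliers cohort - subsidence
beyond 5.44 mm, internal rotation beyond 5.52 degrees, external rotation
beyond 4.32 degrees - as `trial_outlier_rules()`, because the quartile
estimator of the original software is unknown and the patient-level data
needed to re-derive them are not public. Outlier handling is always a
view: `run_pipeline()` analyses the original cohort and the
without-outliers cohort side by side, and `flag_outliers()` reports the
offending subject-axis-visit cells without touching the data.

## The offset-angle power study

The Monte Carlo study asks how much statistical power an axis-by-axis
analysis loses when the clinically meaningful signal is not aligned with
the tested axis. Each iteration draws two groups of $n = 30$ from a
six-dimensional normal; the second group's y-translation mean is shifted
by the $\delta$ that solves the noncentral-t two-sample power equation for
80% power at $\alpha = 0.05$ (`calibrate_delta()`, checked against an
independent root-finder). Both groups are then rotated by the offset angle
about a random unit vector in the x-z plane - a fresh vector per
iteration, modelling the alignment uncertainty of the RSA frame - and
three analyses are run: the Welch t-test on y-translation, Welch t-tests
on total translation and total rotation (reported separately and as
either-rejects, since a combination rule for the pair is not canonical),
and the joint multivariate test on all six axes.

Inside the sweep the multivariate test uses a closed form: for balanced
complete single-visit data the REML LMM with unstructured covariance
collapses to two-sample multivariate regression and the KR joint test
equals Hotelling's $T^2$ (`mv_joint_test()`; the equality with the
iterative fit is a test-suite assertion, and the closed form keeps
$19 \times 3000$ iterations to seconds). Iterations share their random
draws across the angle grid (common random numbers), which makes the
curves directly comparable across angles and renders the multivariate
test's affine-invariance - its power cannot depend on the offset angle -
visible as an exactly flat curve.

Two anchors are built into the design and recomputed by
`scripts/acceptance.R`: at 0 degrees the y-axis t-test must show its
designed 80% power, and at 90 degrees the calibrated difference has been
rotated entirely out of the tested axis, so the same test must fall back
to its 5% size regardless of the covariance.

When no pilot covariance is supplied, `default_migration_covariance()`
provides a documented stand-in, *not* any trial's covariance: axis SDs
built from the clinical precision profile (limit/1.96) with biological
multipliers on the two dominant axes (subsidence near 1 mm SD, y-rotation
near 1.6 degrees), correlations 0.3 among translations and 0.2 among
rotations, and the kinematic couplings real RSA data show between
subsidence and stem rotation: $r = 0.6$ with y-rotation and $r = -0.45$
with z-rotation (the magnitude clinical cohorts report between those
changes). These couplings matter: they are what lets the joint test
outperform the *average* univariate test under rotation, and with a
purely block-diagonal correlation structure the qualitative ordering
(multivariate > y-axis t-test > surrogate tests) would not hold. Absolute
power values always depend on the assumed covariance and are therefore
not comparable across covariance choices; the calibration anchors and the
ordering are. A `zero_covariance` switch reruns the study with all
off-diagonals removed - the worst case for the multivariate test.

The companion calculator `sample_size_two_proportions()` implements the
pooled-variance normal approximation for a two-sided comparison of two
outlier rates; with rates 6/32 and 2/33 at $\alpha = 0.05$ and 80% power
it returns 105 subjects per group:

```{r samplesize}
sample_size_two_proportions(6 / 32, 2 / 33)
```

## The synthetic trial generator

`generate_trial()` exists so that every pipeline stage is exercisable
without patient data. It emulates, per the configured defaults: two arms
of 33 and 32 postmenopausal subjects; RSA visits at 12, 22 and 48 weeks;
saturating mean trajectories $A(1 - e^{-t/\tau})$ with $\tau = 8$ weeks,
so most migration precedes the first visit; a BMD mixture of 50% normal /
46% osteopenia / 4% osteoporosis with a deeper subsidence asymptote for
the low-BMD classes; subject-level random asymptotes whose variance is
reduced in the treated arm (emulating an antiresorptive effect on
migration variance rather than on means); visit-level measurement noise
with per-axis SD equal to the clinical precision limit divided by 1.96
(reading the limit as the 95% bound of a single examination's error; a
`"difference"` interpretation dividing by a further $\sqrt 2$ is
configurable); 12% outlier contamination as a two-component mixture that
inflates a subject's subsidence or y-rotation asymptote beyond the
shipped cutoffs, so injected outliers are individually identifiable; and
2.1% missing observations, deleted completely at random.

What the generator does *not* emulate - and what passing tests therefore
do not demonstrate about real data: non-normal and heavy-tailed migration
errors, informative missingness, visit-time jitter, marker occlusion or
bead loss, inter-observer measurement differences, and any genuine
treatment effect on mean migration (the default mean effect is zero; the
variance effect and the BMD gradient are the only built-in signals).
Asymptote magnitudes are chosen to be clinically plausible for a
collarless tapered stem, not calibrated to any dataset, and the true
between-subject covariance of a real trial is unknown.

## Numerical choices and degenerate inputs

* Euler convention: intrinsic x-y-z (`EULER_SEQUENCE`), rotations
  restricted to (-90, 90) degrees - far beyond clinical migration, but it
  guards the decomposition's gimbal singularity. At clinical magnitudes
  the Euler-triple norm tracks the true matrix rotation angle within 1%.
* `rotate_dof6()` acts block-diagonally, rotating the translation and the
  small-angle rotation triples by the same Rodrigues matrix; the two norms
  are preserved exactly.
* Collinear marker sets: rigid fitting errors out (the rotation is not
  identifiable); `condition_number()` returns `Inf`.
* Quartiles: type 7 (linear interpolation); outlier inequalities are
  strict, matching how the shipped cutoffs are phrased.
* REML: log-Cholesky parameterisation, BFGS (max 500 iterations per
  restart, 3 restarts) plus Fisher scoring with step halving; gradient
  tolerance $10^{-6}$; deterministic moment initialisation.
* Contrast resolution: rank-deficient contrast matrices are rejected with
  the offending rows named; factors constant in a frame (e.g. a single
  visit) are dropped from the fixed-effects formula automatically.
* Fits with fewer than two subjects per group are refused.

## Problem sizes in the shipped checks

The test suite runs the trial-sized pipeline (65 subjects, three visits,
six axes) end to end, recovers a known Kronecker covariance at 200
subjects within 10% relative Frobenius error, checks the joint test's
size with 1000 null replicates via the closed-form path, and runs the
offset-angle study at its full 3000 iterations per angle for the anchor
checks (smaller grids elsewhere). These sizes were chosen to make Monte
Carlo tolerances meaningful: binomial SE at 3000 iterations is about 0.7
percentage points at 80% power and 0.4 at the 5% size, so the acceptance
tolerances (2 and 1.5 points) sit at roughly three standard errors.

## Known limitations

* The Kronecker and full unstructured fits assume one shared $\Sigma$
  across subjects and arms; the variance-reducing treatment effect the
  generator can create is deliberately *not* modelled (the paper-level
  analysis for that is Levene's test in `companion_tests()`).
* Kenward-Roger here covers the implemented marginal structures; it does
  not generalise to crossed random effects, which this design does not
  need.
* The backward elimination is the conventional fixed-sequence procedure;
  it makes no claim of post-selection inference validity.
* Influence-based outlier diagnostics (e.g. restricted-likelihood
  distance) are out of scope; the IQR rule is the implemented definition.
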