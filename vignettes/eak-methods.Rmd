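---
title: "Models and methods for early erythrocyte aggregation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for early erythrocyte aggregation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eakr)
```

## The measurement and its models

After a whole-blood sample is stirred hard enough to disperse all
erythrocyte aggregates (shear rates of order 10^3^ s^−1^), isolated red
cells begin to stick together two-by-two, then into rouleaux and
three-dimensional structures. Because an isolated biconcave cell
backscatters far more light than a compact aggregate, the backscattered
intensity recorded after stirring stops — the *syllectogram* — decays
monotonically. `eakr` works with that decay.

Two kinetic hypotheses describe the earliest phase, where isolated cells
(concentration $[A]$) combine into doublets ($[B]$):

* **Second-order kinetics** (`model1_params`): $d[B]/dt = k[A]^2$, whose
  solution makes the *inverse* intensity linear in time,
  $1/[A] = kt + 1/A_0$. If pair formation were limited by encounters
  between isolated cells, this is what we would see.
* **First-order kinetics** (`mono_exp_params`): with cells abundant, the
  rate-limiting step is the aggregation event itself, giving
  $[A] = A_0 e^{-kt}$ — a mono-exponential decay with rate constant $k$
  (s^−1^). Its half-life $\ln 2 / k$, fitted on the first 5 s, is the
  headline statistic **EAK5s**.

Intensity is treated as directly proportional to $[A]$; no calibration
layer exists because absolute backscatter levels depend on tube optics and
are deliberately never interpreted — only the kinetics carry information.
The doublet concentration $[B]$ is never modelled explicitly: only $[A]$
maps to measured light, and no stoichiometric relation for the mixed signal
is assumed.

Over a full 20 s recording the decay is conventionally decomposed as
$$I(t) = I_f e^{-t/k_f} + I_s e^{-t/k_s} + I_0,$$
a fast component (rouleaux formation), a slow component (three-dimensional
growth) and a baseline. Note the deliberate change of convention:
$k_f, k_s$ here are *time constants* in seconds, whereas the
mono-exponential $k$ is a *rate* in s^−1^. Both conventions are standard in
syllectometry; `eakr` keeps them in separate typed parameter objects so no
bare "k" ever crosses an interface.

## Fitting choices

**Mono-exponential segments.** `fit_mono_exp()` minimises intensity-scale
residuals for $A_0 e^{-kt}$ with Levenberg–Marquardt (via `minpack.lm`),
started from a log-linear regression of $\log I$ on $t$ — deterministic,
derivative-free, seed-independent. There is *no offset term* by default:
the first-order model as written has none, and adding one makes $A_0$ and
the baseline trade off on short segments (an `offset = TRUE` flag exists
for exploration). A signal whose initial log-linear slope is non-negative
is rejected with a typed `NonDecaying` error rather than fitted.
Convergence uses a relative parameter tolerance of 10^−10^ and at most 200
iterations; non-convergence is flagged in the result, never silent.

**r² convention.** $r^2 = 1 - SS_{res}/SS_{tot}$ is always computed on the
scale actually fitted: raw intensity for the exponential models, inverse
intensity for the second-order model. Alternatives (e.g. back-transforming
the inverse-linear fit) would mix scales and blur the model comparison.

**Segment selection.** `select_best_segment()` fits the first 1.5, 3, 5 and
10 s and picks the largest r²; ties within 10^−4^ go to the *shortest*
segment. Rationale: the mono-exponential describes the earliest, two-by-two
phase, so when a short and a long segment explain the data equally well the
short fit makes the weaker assumption. On data with a strong slow
component, the 10 s fit visibly degrades — which is why the 5 s segment is
the default analysis window.

**Bi-exponential decomposition.** Sums of exponentials are classically
ill-conditioned, and all five constants need starting values. `fit_bi_exp()`
initialises by curve peeling: baseline from the mean of the final 5% of
samples; slow component log-linearly from the last third of the recording;
fast component log-linearly from the first 3 s of the slow-subtracted
residual. Refinement runs bounded Levenberg–Marquardt from that start and
from a small deterministic family of perturbed starts, keeping the
lowest-SSE convergent fit — the perturbations exist because when the slow
component has not decayed by the end of the recording, $I_0$ and the slow
tail trade off and the surface has local minima. Amplitudes are
box-constrained at zero (an amplitude on the boundary is reported as
`clamped`); components are reordered so $k_f < k_s$; time constants closer
than 2× — or a component collapsing to zero amplitude — raise a
"poorly identifiable" warning. The fit requires ≥ 15 s of signal: on a 5 s
segment the slow component is simply not observable.

## The synthetic device

No public repository of syllectograms exists, so the `simulate` layer
stands in for the instrument, and every statistical property of the
package is validated against it in closed loop (generate → fit → compare).

* **Noise.** The device's photodiode noise is not characterised publicly;
  the default is additive Gaussian noise at 0.5% of the initial amplitude,
  chosen once so that the closed-loop repeatability of fitted EAK5s lands
  in the low-percent range reported for repeated measurements on one tube
  (≈ 2.3–2.6%). Proportional noise is available; noisy samples are clipped
  to stay positive and clipping is counted and warned about beyond 1% of
  samples.
* **Subjects and cohorts.** A subject's repeats draw half-lives from
  Normal(true EAK5s, intra_cv · true EAK5s) (redrawing non-positive
  values); cohorts draw subject-level EAK5s from Normal(mean, sd)
  truncated at 0.2 s — without truncation a Normal tail could produce
  unphysical non-positive half-lives. Presets carry the reference study
  populations: healthy donors (n = 51, 2.51 ± 0.38 s), cardiology
  inpatients (n = 14, 1.73 ± 0.34 s), ACS (n = 6, 1.70 ± 0.17 s) and
  non-ACS (n = 8, 1.76 ± 0.44 s).
* **Hematocrit pairs.** Hematocrit is uniform over the observed clinical
  range (23.6–55.3%); EAK5s is built as
  $z_2 = r z_1 + \sqrt{1-r^2}\,\varepsilon$ on standardised variables, so
  the *population* correlation equals the target exactly (default 0.26,
  the weak association consistent with first-order kinetics, whose rate
  constant does not depend on cell concentration).
* **Shear rate.** The bubble traverses its stroke once per half stirring
  cycle, so mean velocity is 2 × stroke × frequency, and shear rate is
  velocity over the bubble-to-wall gap. The default geometry (13 mm tube,
  12.8 mm bubble, 60 mm stroke, 1 Hz) is a declared convention read off a
  standard 4 ml EDTA tube, giving ≈ 1.2 × 10^3^ s^−1^ — an
  order-of-magnitude figure, not a calibrated one.
* **Determinism.** Every stochastic function takes an explicit seed,
  restores the caller's RNG state, and is a pure function of that seed;
  simulation to disk is byte-reproducible.

What the simulator does *not* emulate: baseline drift, photodiode
saturation, tube-to-tube optical variation, the disaggregation phase, and
any dependence of the rate constant on hematocrit or plasma composition.
Tests passing against it therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to every artefact
of real recordings.

## Cohort statistics

"Student's t test" in the clinical literature usually means the
pooled-variance form, so that is the default of `t_test_two_sample()` and
the only form of `t_test_from_summary()` (which reproduces group-table
comparisons from printed n/mean/SD). Because group SDs in practice differ —
sometimes by more than 2×, where the equal-variance assumption is
doubtful — the pooled result then carries a note recommending the Welch
variant, which is available explicitly. Zero-variance degeneracies return
p = 1 when the means agree and error otherwise.

`stability_analysis()` compares measurements taken right after blood draw
with those taken an hour later. The literature does not define the blocks,
so the package chooses: with subject ids, the baseline block is each
subject's first measurement; without, all measurements within the first 15
minutes. The late block is everything at ≥ 60 min. The comparison is an
unpaired pooled t-test by default; a paired variant (subject's first vs the
mean of their late measurements) is exposed because repeated measures on
the same subjects are naturally paired — unpaired remains the default as
the more conservative, assumption-light choice. The per-subject CV of
repeats is reported alongside.

Shapiro–Wilk (normality of cohort EAK5s) and Pearson correlation wrap the
standard `stats` implementations behind validated interfaces; no multiple
testing correction is applied anywhere, matching standard practice for
these small validation panels.

## Numerical and calibration checks

The test suite validates, among others: exact recovery on noiseless curves
(rate constants to 10^−6^ relative, r² ≥ 1 − 10^−10^; inverse-linear r² = 1
on second-order data); five-constant bi-exponential recovery within 5% on
noiseless 20 s recordings with ≥ 10× separated time constants; EAK5s bias
< 1% and replicate CV < 3% over 200 noisy 5 s syllectograms; the
mono-exponential out-explaining the inverse-linear fit in ≥ 95% of noisy
first-order replicates; type-I error of the t-test and of the stability
analysis within [0.03, 0.07] at α = 0.05 over 2000 null simulations; and a
10^4^-subject cohort reproducing its target CV (15.1%) within 0.5
percentage points. Problem sizes (200 fit replicates, 2000 null
simulations, 10^4^ subjects on the no-refit fast path) were chosen as the
smallest that pin each property down to well under its tolerance; the full
suite runs in seconds.

## Limitations

* The mono-exponential model is only valid while two-by-two aggregation
  dominates — roughly the first 5 s; EAK5s from longer windows is biased
  by rouleaux growth, which is exactly what segment selection exposes.
* The bi-exponential decomposition needs the full recording and remains
  ill-conditioned when time constants are close; treat component
  amplitudes quantitatively only when the separation warning is absent.
* Simulated cohorts inherit their parameters from published summary
  statistics of small studies; they are appropriate for validating
  estimators and power calculations, not for generating reference ranges.
* The shear-rate estimate is dimensional analysis on an idealised
  geometry, suitable for order-of-magnitude checks only.
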