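# eakr — erythrocyte aggregation kinetics from syllectograms

Erythrocyte aggregation (EA) is the reversible sticking of red blood cells
into rouleaux at low shear, a major determinant of in-vivo blood viscosity
and a marker of inflammation. Point-of-care aggregometry measures it
optically: a stirred blood-collection tube is illuminated, and after
stirring stops the backscattered light decays as isolated erythrocytes —
which backscatter far more light than aggregates — pair up two-by-two. The
recorded decay curve is called a **syllectogram**.

`eakr` is for hemorheologists and device developers who need to model, fit
and validate this early aggregation kinetics (EAK). It implements:

- **Forward models.** Second-order two-by-two aggregation
  (`1/[A] = kt + 1/A0`, intensity inverse-linear in time), first-order
  kinetics (`[A] = A0·e^(−kt)`, mono-exponential decay), and the full
  bi-exponential syllectogram
  `I(t) = I_f·e^(−t/k_f) + I_s·e^(−t/k_s) + I_0`
  (fast rouleaux formation + slow three-dimensional aggregate growth above a
  baseline).
- **Fitting.** Segment-wise nonlinear least squares (1.5 / 3 / 5 / 10 s
  initial segments) with log-linear initialization; the headline statistic
  **EAK5s = ln 2 / k**, the half-life of the mono-exponential fitted to the
  first 5 s; inverse-linear fitting for model comparison; bi-exponential
  decomposition initialised by classical curve peeling.
- **Simulation.** A seeded synthetic device: noisy syllectograms, subjects
  with repeated measurements at a given intra-individual CV, whole cohorts
  drawn from group distributions (built-in presets for healthy donors and
  cardiology inpatients with/without acute coronary syndrome), correlated
  hematocrit–EAK5s pairs, and a shear-rate estimate for the stirred-tube
  geometry (velocity / bubble-to-wall gap).
- **Validation statistics.** Coefficients of variation, Shapiro–Wilk
  normality, pooled/Welch two-tailed t-tests (including the
  summary-statistics form for published tables), Pearson correlation, and a
  measurement-stability analysis comparing first measurements against those
  taken an hour after blood draw.

## Worked example

```r
library(eakr)

# a noisy 10 s syllectogram from a healthy-scale decay (k = 0.2762 /s)
s <- simulate_syllectogram(mono_exp_params(A0 = 1000, k = 0.2762),
                           duration = 10, sampling_rate = 100,
                           noise = noise_spec("gaussian-additive", 5), seed = 42)

compute_eak5s(s)
#> <mono_exp_fit> 5 s segment (501 pts): k = 0.2764 /s, half-life = 2.508 s, r2 = 0.99948

select_best_segment(s, durations = c(1.5, 3, 5, 10))
#> <segment_selection>
#>     1.5 s: r2 = 0.99747
#>     3.0 s: r2 = 0.99908
#>     5.0 s: r2 = 0.99948
#>    10.0 s: r2 = 0.99962
#>   best: 10 s (max-r2)

fit_inverse_linear(extract_segment(s, 5))$r2
#> 0.9676
```

The fitted rate constant (0.2764 s⁻¹) recovers the simulated truth to 0.1%,
and EAK5s ≈ 2.51 s is a typical healthy half-life. The mono-exponential
explains 99.9% of the variance while the second-order (inverse-linear)
model explains only 96.8% — first-order kinetics describe the early
aggregation phase better. On a clean mono-exponential all segments tie near
r² = 1 (a strong slow component penalises the 10 s segment instead).

Group comparison from published summary statistics, and the tube shear rate:

```r
t_test_from_summary(51, 2.51, 0.38, 14, 1.73, 0.34)
#> <student-t-two-tailed> statistic = 6.948, df = 63, p = 2.467e-09

cv_from_summary(c(2.51, 1.73, 1.70, 1.76), c(0.38, 0.34, 0.17, 0.44))
#> 15.13944 19.65318 10.00000 25.00000

estimate_shear_rate(tube_geometry())
#> <shear_estimate> velocity 0.12 m/s through a 0.1 mm gap: shear rate 1.2e+03 /s
```

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","eak.R",package="eakr"))')" \
    simulate --preset healthy --n 10 --seed 7 --out out/
```

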