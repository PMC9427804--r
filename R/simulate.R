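# Synthetic-device layer: seeded generation of syllectograms, subjects with
# repeated measures, cohorts, correlated hematocrit pairs, and the shear-rate
# estimate for the stirred-tube geometry.
#
# Every stochastic function takes an explicit `seed`; given the same seed the
# output is identical, and the caller's RNG stream is left untouched.

#' Measurement-noise specification
#'
#' The photodiode noise of the emulated device. `"gaussian-additive"` adds
#' i.i.d. Gaussian noise with standard deviation `sd` in intensity units;
#' `"gaussian-proportional"` interprets `sd` as a fraction of the initial
#' signal amplitude; `"none"` returns the exact forward model.
#'
#' The package default for simulated measurements is additive noise at 0.5%
#' of the initial amplitude, a level at which repeated fitted half-lives show
#' an intra-measurement CV in the low-percent range typical of stirred-tube
#' aggregometry.
#'
#' @param kind One of `"none"`, `"gaussian-additive"`, `"gaussian-proportional"`.
#' @param sd Noise scale, >= 0 (units depend on `kind`).
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(kind = c("none", "gaussian-additive", "gaussian-proportional"),
                       sd = 0) {
  kind <- match.arg(kind)
  check_scalar_pos(sd, "sd", strict = FALSE)
  structure(list(kind = kind, sd = sd), class = "noise_spec")
}

#' Cohort distribution specification
#'
#' Group-level parameters for simulating a study population: per-subject true
#' EAK5s half-lives are Normal(`eak5s_mean`, `eak5s_sd`) truncated at 0.2 s,
#' and repeated measurements on one subject vary with coefficient of
#' variation `intra_cv` around the subject's true value.
#'
#' @param n_subjects Number of subjects, >= 1.
#' @param eak5s_mean Group mean EAK5s in seconds, > 0.
#' @param eak5s_sd Between-subject SD in seconds, >= 0.
#' @param intra_cv Within-subject repeat CV as a fraction (default 0.026,
#'   the repeatability scale of stirred-tube EAK measurements).
#' @param repeats_per_subject Measurements per subject (default 1).
#' @param label Group name.
#' @return Object of class `"cohort_spec"`.
#' @seealso [eak_presets()] for the built-in study populations.
#' @export
cohort_spec <- function(n_subjects, eak5s_mean, eak5s_sd,
                        intra_cv = 0.026, repeats_per_subject = 1L,
                        label = "cohort") {
  stopifnot(n_subjects >= 1)
  check_scalar_pos(eak5s_mean, "eak5s_mean")
  check_scalar_pos(eak5s_sd, "eak5s_sd", strict = FALSE)
  check_scalar_pos(intra_cv, "intra_cv", strict = FALSE)
  stopifnot(repeats_per_subject >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 eak5s_mean = eak5s_mean, eak5s_sd = eak5s_sd,
                 intra_cv = intra_cv,
                 repeats_per_subject = as.integer(repeats_per_subject),
                 label = label),
            class = "cohort_spec")
}

#' Built-in study-population presets
#'
#' Group sizes, mean and SD of EAK5s for the reference populations: healthy
#' blood donors, patients hospitalized in intensive-care cardiology, and the
#' latter split by acute coronary syndrome (ACS) status.
#'
#' @return A data.frame with columns `label`, `n_subjects`, `eak5s_mean`,
#'   `eak5s_sd`.
#' @export
eak_presets <- function() {
  data.frame(
    label = c("healthy", "cardiology", "acs", "non-acs"),
    n_subjects = c(51L, 14L, 6L, 8L),
    eak5s_mean = c(2.51, 1.73, 1.70, 1.76),
    eak5s_sd = c(0.38, 0.34, 0.17, 0.44),
    stringsAsFactors = FALSE
  )
}

#' Look up a preset as a cohort_spec
#' @param label One of `"healthy"`, `"cardiology"`, `"acs"`, `"non-acs"`.
#' @param ... Overrides passed to [cohort_spec()] (e.g. `n_subjects`).
#' @return A [cohort_spec()].
#' @export
preset_cohort <- function(label, ...) {
  p <- eak_presets()
  row <- p[p$label == label, ]
  if (nrow(row) != 1L) {
    stop_eak(sprintf("unknown preset '%s'; available: %s",
                     label, paste(p$label, collapse = ", ")),
             "eak_domain_error")
  }
  args <- list(n_subjects = row$n_subjects, eak5s_mean = row$eak5s_mean,
               eak5s_sd = row$eak5s_sd, label = row$label)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

#' Simulate one syllectogram
#'
#' Evaluates the requested forward model on a regular time grid and adds
#' measurement noise. The noiseless output is exactly the forward model;
#' noisy samples are clipped to stay positive (a physical intensity), and a
#' warning is raised if more than 1% of samples had to be clipped.
#'
#' @param params [mono_exp_params()], [bi_exp_params()] or [model1_params()].
#' @param duration Recording length in seconds (default 5).
#' @param sampling_rate Samples per second (default 100; the endpoint is
#'   included, so 5 s at 100 Hz gives 501 samples).
#' @param noise A [noise_spec()] (default: none).
#' @param seed Integer seed; same seed, same syllectogram.
#' @param meta Metadata list attached to the result.
#' @return A [syllectogram()]; `meta$n_clipped` counts clipped samples.
#' @export
simulate_syllectogram <- function(params, duration = 5, sampling_rate = 100,
                                  noise = noise_spec("none"), seed = NULL,
                                  meta = list()) {
  check_scalar_pos(duration, "duration")
  check_scalar_pos(sampling_rate, "sampling_rate")
  stopifnot(inherits(noise, "noise_spec"))
  times <- seq(0, duration, by = 1 / sampling_rate)
  clean <- if (inherits(params, "mono_exp_params")) {
    eval_mono_exp(params, times)
  } else if (inherits(params, "bi_exp_params")) {
    eval_bi_exp(params, times)
  } else if (inherits(params, "model1_params")) {
    eval_model1(params, times)
  } else {
    stop_eak("params must be mono_exp_params, bi_exp_params or model1_params",
             "eak_domain_error")
  }
  amp0 <- clean[1L]
  values <- with_seed(seed, {
    if (noise$kind == "none" || noise$sd == 0) {
      clean
    } else {
      sd_abs <- switch(noise$kind,
                       "gaussian-additive" = noise$sd,
                       "gaussian-proportional" = noise$sd * amp0)
      clean + stats::rnorm(length(clean), sd = sd_abs)
    }
  })
  floor_val <- 1e-6 * amp0
  n_clipped <- sum(values < floor_val)
  if (n_clipped > 0.01 * length(values)) {
    warn_eak(sprintf("noise clipped %d of %d samples (> 1%%); sd is large relative to the signal",
                     n_clipped, length(values)), "eak_noise_clipping")
  }
  values <- pmax(values, floor_val)
  meta$n_clipped <- n_clipped
  syllectogram(times, values, meta = meta)
}

#' Simulate repeated measurements on one subject
#'
#' Each repeat's true half-life is drawn from
#' Normal(`true_eak5s`, `intra_cv * true_eak5s`) (non-positive draws are
#' redrawn and counted), converted to a rate `k = ln 2 / half-life`, and a
#' noisy syllectogram is generated per repeat. Repeats are stamped with
#' `minutes_after_draw` to support stability analyses over the first hour.
#'
#' @param true_eak5s Subject's true EAK5s half-life in seconds, > 0.
#' @param n_repeats Number of repeated measurements (default 21, a typical
#'   per-patient count in repeatability protocols).
#' @param intra_cv Within-subject CV as a fraction in `[0, 0.5)`.
#' @param A0 Initial signal amplitude for the generated curves.
#' @param duration,sampling_rate Recording grid (default 5 s at 100 Hz).
#' @param noise [noise_spec()]; default additive Gaussian at 0.5% of `A0`.
#' @param minutes Times of the repeats in minutes after blood draw
#'   (default evenly spread over 0-60 min).
#' @param seed Integer seed.
#' @return List of [syllectogram()]s; each carries `meta$repeat_idx`,
#'   `meta$minutes_after_draw` and `meta$true_half_life`.
#' @export
simulate_subject <- function(true_eak5s, n_repeats = 21L, intra_cv = 0.026,
                             A0 = 1000, duration = 5, sampling_rate = 100,
                             noise = noise_spec("gaussian-additive", 0.005 * A0),
                             minutes = seq(0, 60, length.out = n_repeats),
                             seed = NULL) {
  check_scalar_pos(true_eak5s, "true_eak5s")
  stopifnot(n_repeats >= 1, intra_cv >= 0, intra_cv < 0.5,
            length(minutes) == n_repeats)
  with_seed(seed, {
    hl <- stats::rnorm(n_repeats, mean = true_eak5s, sd = intra_cv * true_eak5s)
    n_redraws <- 0L
    while (any(hl <= 0)) { # non-positive half-lives are unphysical
      bad <- hl <= 0
      n_redraws <- n_redraws + sum(bad)
      hl[bad] <- stats::rnorm(sum(bad), true_eak5s, intra_cv * true_eak5s)
    }
    lapply(seq_len(n_repeats), function(i) {
      simulate_syllectogram(
        mono_exp_params(A0 = A0, k = log(2) / hl[i]),
        duration = duration, sampling_rate = sampling_rate, noise = noise,
        meta = list(repeat_idx = i, minutes_after_draw = minutes[i],
                    true_half_life = hl[i], n_redraws = n_redraws))
    })
  })
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject true EAK5s values from the cohort distribution
#' (Normal, truncated at > 0.2 s), optionally generates noisy syllectograms
#' and re-fits them, and returns a tidy per-measurement table.
#'
#' With `fit = FALSE` no signals are generated and `eak5s_fitted` is `NA`;
#' this fast path serves large calibration runs where only the subject-level
#' distribution matters.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param fit Generate syllectograms and re-fit EAK5s per measurement
#'   (default `TRUE`).
#' @param A0,duration,sampling_rate,noise Measurement settings passed to
#'   [simulate_subject()].
#' @return data.frame with columns `subject_id`, `group`, `repeat_idx`,
#'   `minutes_after_draw`, `eak5s_true`, `eak5s_fitted`.
#' @export
simulate_cohort <- function(spec, seed = NULL, fit = TRUE,
                            A0 = 1000, duration = 5, sampling_rate = 100,
                            noise = noise_spec("gaussian-additive", 0.005 * A0)) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    truth <- stats::rnorm(spec$n_subjects, spec$eak5s_mean, spec$eak5s_sd)
    while (any(truth <= 0.2)) { # truncate the subject distribution at 0.2 s
      bad <- truth <= 0.2
      truth[bad] <- stats::rnorm(sum(bad), spec$eak5s_mean, spec$eak5s_sd)
    }
    reps <- spec$repeats_per_subject
    rows <- lapply(seq_len(spec$n_subjects), function(i) {
      minutes <- if (reps == 1L) 0 else seq(0, 60, length.out = reps)
      fitted <- rep(NA_real_, reps)
      true_rep <- rep(truth[i], reps)
      if (fit) {
        syls <- simulate_subject(truth[i], n_repeats = reps,
                                 intra_cv = spec$intra_cv, A0 = A0,
                                 duration = duration,
                                 sampling_rate = sampling_rate,
                                 noise = noise, minutes = minutes)
        fitted <- vapply(syls, function(s) compute_eak5s(s)$half_life,
                         numeric(1L))
        true_rep <- vapply(syls, function(s) s$meta$true_half_life, numeric(1L))
      }
      data.frame(subject_id = i, group = spec$label,
                 repeat_idx = seq_len(reps), minutes_after_draw = minutes,
                 eak5s_true = true_rep, eak5s_fitted = fitted)
    })
    do.call(rbind, rows)
  })
}

#' Simulate paired hematocrit / EAK5s measurements
#'
#' Generates pairs with a specified population Pearson correlation between
#' hematocrit (uniform over the observed clinical range) and EAK5s, via the
#' standard construction `z2 = r*z1 + sqrt(1 - r^2)*e` on standardised
#' variables. The population correlation equals `target_r` exactly; the
#' sample correlation fluctuates with the usual `~1/sqrt(n)` error.
#'
#' @param n Number of pairs, >= 3.
#' @param target_r Population correlation in (-1, 1) (default 0.26, the weak
#'   association observed clinically, consistent with first-order kinetics
#'   whose rate does not depend on cell concentration).
#' @param eak5s_mean,eak5s_sd Marginal distribution of EAK5s (seconds).
#' @param hct_range Hematocrit range in percent (default 23.6-55.3, the span
#'   seen in an unselected emergency-department population).
#' @param seed Integer seed.
#' @return data.frame with columns `hematocrit_pct`, `eak5s`.
#' @export
simulate_hematocrit_pairs <- function(n, target_r = 0.26,
                                      eak5s_mean = 2.51, eak5s_sd = 0.38,
                                      hct_range = c(23.6, 55.3), seed = NULL) {
  if (n < 3) stop_eak("need at least 3 pairs", "eak_domain_error")
  if (!is.finite(target_r) || abs(target_r) >= 1) {
    stop_eak("target_r must lie strictly between -1 and 1", "eak_domain_error")
  }
  with_seed(seed, {
    hct <- stats::runif(n, hct_range[1L], hct_range[2L])
    z1 <- (hct - mean(hct_range)) / (diff(hct_range) / sqrt(12))
    z2 <- target_r * z1 + sqrt(1 - target_r^2) * stats::rnorm(n)
    eak <- eak5s_mean + eak5s_sd * z2
    while (any(eak <= 0.2)) {
      bad <- eak <= 0.2
      eak[bad] <- eak5s_mean +
        eak5s_sd * (target_r * z1[bad] +
                      sqrt(1 - target_r^2) * stats::rnorm(sum(bad)))
    }
    data.frame(hematocrit_pct = hct, eak5s = eak)
  })
}

#' Estimate the stirring shear rate from tube geometry
#'
#' During upside-down stirring the air bubble travels the tube once per half
#' cycle, so its mean speed is `2 * stroke_length * frequency`; the blood is
#' forced through the annular gap `(internal_diameter - bubble_diameter)/2`
#' between bubble and wall, and the shear rate in the gap is velocity / gap.
#' For a standard 4 ml tube at 1 Hz this is of order 10^3 s^-1 — comparable
#' to the highest shear rates of rotational aggregometers, enough to disperse
#' pre-existing aggregates.
#'
#' @param g A [tube_geometry()].
#' @return Object of class `"shear_estimate"`: `velocity` (m/s), `gap` (m),
#'   `shear_rate` (s^-1), satisfying `shear_rate == velocity / gap`.
#' @export
estimate_shear_rate <- function(g) {
  stopifnot(inherits(g, "tube_geometry"))
  gap <- (g$internal_diameter - g$bubble_diameter) / 2
  if (gap <= 0) stop_eak("bubble-wall gap must be positive", "eak_domain_error")
  velocity <- 2 * g$stroke_length * g$frequency
  structure(list(velocity = velocity, gap = gap,
                 shear_rate = velocity / gap),
            class = "shear_estimate")
}

#' @export
print.shear_estimate <- function(x, ...) {
  cat(sprintf("<shear_estimate> velocity %.3g m/s through a %.3g mm gap: shear rate %.3g /s\n",
              x$velocity, 1e3 * x$gap, x$shear_rate))
  invisible(x)
}
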