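# Segment-wise fitting of syllectograms.
#
# The mono-exponential fit deliberately carries no baseline term: the
# first-order model as used on the first seconds of the decay has none, and
# absolute backscatter levels are device-dependent and not interpreted.
# r^2 is always 1 - SS_res/SS_tot on the scale actually fitted (raw intensity
# for the exponential models, inverse intensity for the inverse-linear model).

NLS_CONTROL <- function() minpack.lm::nls.lm.control(ptol = 1e-10, maxiter = 200)

r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

#' Extract the initial segment of a syllectogram
#'
#' Returns the samples with `t <= duration` (closed interval: the sample at
#' exactly `duration` is included), preserving metadata. Segment-wise fitting
#' of the first 1.5 / 3 / 5 / 10 s is the standard analysis of the early
#' aggregation phase.
#'
#' @param s A [syllectogram()].
#' @param duration Segment length in seconds; must not exceed the recording.
#' @return A [syllectogram()] covering `[0, duration]`.
#' @export
extract_segment <- function(s, duration) {
  stopifnot(inherits(s, "syllectogram"))
  check_scalar_pos(duration, "duration")
  avail <- syl_duration(s)
  if (duration > avail + 1e-9) {
    stop_eak(sprintf("requested segment of %.3g s but recording only covers %.3g s",
                     duration, avail), "eak_segment_too_long")
  }
  keep <- s$times <= duration + 1e-12
  syllectogram(s$times[keep], s$intensities[keep], meta = s$meta)
}

#' Fit a mono-exponential decay to a syllectogram segment
#'
#' Nonlinear least squares for `I(t) = A0 * exp(-k * t)` on the raw intensity
#' scale. Starting values come from an ordinary log-linear regression of
#' `log(I)` on `t`, which is deterministic and derivative-free; a
#' Levenberg-Marquardt refinement then minimises the intensity-scale residuals
#' (relative parameter tolerance 1e-10, at most 200 iterations).
#' Non-convergence is flagged, never silent.
#'
#' The fit carries no offset by default; `offset = TRUE` adds a baseline term
#' `+ I0` for exploratory use.
#'
#' @param segment A [syllectogram()] (typically from [extract_segment()]),
#'   at least 8 samples.
#' @param offset Logical; include a baseline offset term (default `FALSE`).
#' @return An object of class `"mono_exp_fit"`: a list with `params`
#'   ([mono_exp_params()]), `half_life` (seconds, `ln 2 / k`), `r2` (fraction
#'   of intensity-scale variance explained), `segment_duration`, `n_points`,
#'   `converged`, and `offset` (fitted baseline, 0 unless requested).
#' @seealso [compute_eak5s()] for the conventional 5 s fit.
#' @export
fit_mono_exp <- function(segment, offset = FALSE) {
  stopifnot(inherits(segment, "syllectogram"))
  t <- segment$times
  I <- segment$intensities
  loglin <- stats::lm.fit(cbind(1, t), log(I))
  slope <- loglin$coefficients[2L]
  if (!is.finite(slope) || slope >= 0) {
    stop_eak("signal is not decaying (initial log-linear slope >= 0); cannot fit an exponential decay",
             "eak_non_decaying")
  }
  start <- list(A0 = exp(loglin$coefficients[1L]), k = -slope)
  df <- data.frame(t = t, I = I)
  if (offset) {
    start$I0 <- 0
    fit <- minpack.lm::nlsLM(I ~ A0 * exp(-k * t) + I0, data = df,
                             start = start,
                             lower = c(A0 = 0, k = 1e-12, I0 = 0),
                             control = NLS_CONTROL())
  } else {
    fit <- minpack.lm::nlsLM(I ~ A0 * exp(-k * t), data = df,
                             start = start,
                             lower = c(A0 = 0, k = 1e-12),
                             control = NLS_CONTROL())
  }
  est <- as.list(stats::coef(fit))
  converged <- isTRUE(fit$convInfo$isConv)
  if (!converged) {
    warn_eak("mono-exponential fit did not converge within 200 iterations",
             "eak_nonconvergence")
  }
  structure(list(
    params = mono_exp_params(est$A0, est$k),
    half_life = log(2) / est$k,
    r2 = r_squared(I, stats::fitted(fit)),
    segment_duration = t[length(t)],
    n_points = length(t),
    converged = converged,
    offset = if (offset) est$I0 else 0
  ), class = "mono_exp_fit")
}

#' @export
print.mono_exp_fit <- function(x, ...) {
  cat(sprintf("<mono_exp_fit> %.3g s segment (%d pts): k = %.4g /s, half-life = %.4g s, r2 = %.5f%s\n",
              x$segment_duration, x$n_points, x$params$k, x$half_life, x$r2,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Fit the inverse-linear (second-order) model to a segment
#'
#' Under second-order two-by-two aggregation the inverse of the backscattered
#' intensity is linear in time: `1/I = k*t + 1/A0`. This is an ordinary
#' least-squares fit of `1/I` on `t`; the returned `r2` is computed on the
#' inverse-intensity scale, the scale actually fitted.
#'
#' @param segment A [syllectogram()] with positive intensities.
#' @return Object of class `"model1_fit"`: `slope` (the rate constant k),
#'   `intercept` (1/A0), `r2`, `n_points`, and `under_determined` (TRUE when
#'   only two points define the line).
#' @export
fit_inverse_linear <- function(segment) {
  stopifnot(inherits(segment, "syllectogram"))
  t <- segment$times
  y <- 1 / segment$intensities
  fit <- stats::lm.fit(cbind(1, t), y)
  fitted_y <- y - fit$residuals
  structure(list(
    slope = unname(fit$coefficients[2L]),
    intercept = unname(fit$coefficients[1L]),
    r2 = r_squared(y, fitted_y),
    n_points = length(t),
    under_determined = length(t) <= 2L
  ), class = "model1_fit")
}

#' Decompose a full syllectogram into fast and slow exponentials
#'
#' Fits all five constants of `I(t) = I_f*exp(-t/k_f) + I_s*exp(-t/k_s) + I_0`
#' by Levenberg-Marquardt least squares. Multi-exponential fits are notoriously
#' initialization-sensitive, so starting values come from classical curve
#' peeling (stripping):
#' 1. the baseline `I_0` is initialised from the mean of the final 5% of
#'    samples;
#' 2. the slow component is fitted log-linearly on the last third of the
#'    (baseline-subtracted) recording;
#' 3. the slow component is subtracted and the fast component fitted
#'    log-linearly on the first 3 s.
#'
#' Amplitudes are box-constrained at zero during refinement; an amplitude that
#' converges on that boundary is reported with `clamped = TRUE`. Components
#' are ordered so that `k_f < k_s`. If the fitted time constants are separated
#' by less than a factor of 2 the decomposition is poorly identifiable and a
#' warning is raised.
#'
#' @param s A [syllectogram()] of at least 15 s (the model describes the full
#'   20 s recording, not the early mono-exponential phase).
#' @return Object of class `"bi_exp_fit"`: `params` ([bi_exp_params()]), `r2`,
#'   `converged`, `clamped`, and `init_params` (the peeling initialization
#'   actually used).
#' @export
fit_bi_exp <- function(s) {
  stopifnot(inherits(s, "syllectogram"))
  total <- syl_duration(s)
  if (total < 15) {
    stop_eak(sprintf("bi-exponential decomposition needs a recording of >= 15 s, got %.3g s", total),
             "eak_segment_too_short")
  }
  t <- s$times
  I <- s$intensities
  n <- length(t)

  # (i) baseline from the final 5% of samples
  n_tail <- max(3L, ceiling(0.05 * n))
  I0_init <- mean(I[(n - n_tail + 1L):n])

  # (ii) slow component from the last third
  idx_slow <- which(t >= (2 / 3) * total)
  slow <- peel_loglin(t[idx_slow], I[idx_slow] - I0_init,
                      fallback_tau = total, fallback_amp = 0.05 * max(I))
  # (iii) fast component from the first 3 s of the slow-subtracted residual
  idx_fast <- which(t <= 3)
  resid_fast <- I[idx_fast] - I0_init - slow$amp * exp(-t[idx_fast] / slow$tau)
  fast <- peel_loglin(t[idx_fast], resid_fast,
                      fallback_tau = 1, fallback_amp = max(I[1L] - I0_init - slow$amp, 0.05 * max(I)))

  if (fast$tau > slow$tau) { tmp <- fast; fast <- slow; slow <- tmp }
  init <- bi_exp_params(I_f = fast$amp, k_f = fast$tau,
                        I_s = slow$amp, k_s = max(slow$tau, fast$tau * 1.0001),
                        I_0 = max(I0_init, 0))

  # Levenberg-Marquardt refinement from the peeling init. The 5-parameter
  # sum-of-exponentials surface has local minima when the slow component has
  # not decayed by the end of the recording (I_0 and the slow tail trade
  # off), so a small deterministic family of perturbed starts is tried and
  # the lowest-SSE convergent fit kept.
  amp_floor <- 1e-3 * max(I)
  starts <- list(
    list(I_f = max(init$I_f, amp_floor), k_f = init$k_f,
         I_s = max(init$I_s, amp_floor), k_s = min(init$k_s, 10 * total),
         I_0 = init$I_0),
    list(I_f = max(init$I_f, amp_floor), k_f = init$k_f,
         I_s = max(init$I_s, amp_floor), k_s = min(init$k_s, 10 * total) / 2,
         I_0 = init$I_0 / 2),
    list(I_f = max(I[1L] - min(I), amp_floor), k_f = total / 20,
         I_s = max(0.3 * (I[1L] - min(I)), amp_floor), k_s = total / 2,
         I_0 = min(I) / 2)
  )
  resid_fn <- function(par) {
    I - (par[["I_f"]] * exp(-t / par[["k_f"]]) +
           par[["I_s"]] * exp(-t / par[["k_s"]]) + par[["I_0"]])
  }
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = unlist(st),
        lower = c(I_f = 0, k_f = 1e-9, I_s = 0, k_s = 1e-9, I_0 = 0),
        fn = resid_fn, control = NLS_CONTROL()),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    stop_eak("bi-exponential refinement failed from every starting point",
             "eak_fit_failed")
  }
  est <- as.list(fit$par)
  if (est$k_f > est$k_s) { # reorder so the fast time constant is the smaller
    est[c("I_f", "k_f", "I_s", "k_s")] <- est[c("I_s", "k_s", "I_f", "k_f")]
  }
  amp_tol <- 1e-6 * max(I)
  clamped <- est$I_f < amp_tol || est$I_s < amp_tol
  if (clamped) {
    # one component vanished: report the surviving one in the fast slot
    if (est$I_f < amp_tol && est$I_s >= amp_tol) {
      est$I_f <- est$I_s; est$k_f <- est$k_s
    }
    est$I_s <- 0
    est$k_s <- 10 * est$k_f
    warn_eak("one exponential component vanished in the fit; the signal is effectively mono-exponential and the decomposition is poorly identifiable",
             "eak_poorly_identifiable")
  } else if (est$k_s / est$k_f < 2) {
    warn_eak(sprintf("time constants poorly identifiable: k_s/k_f = %.2f < 2",
                     est$k_s / est$k_f), "eak_poorly_identifiable")
  }
  if (est$k_f >= est$k_s) est$k_s <- est$k_f * (1 + 1e-9)
  params <- bi_exp_params(max(est$I_f, 0), est$k_f, max(est$I_s, 0), est$k_s,
                          max(est$I_0, 0))
  converged <- fit$info %in% 1:3 # minpack info codes for convergence
  if (!converged) {
    warn_eak("bi-exponential fit did not converge within 200 iterations",
             "eak_nonconvergence")
  }
  structure(list(params = params,
                 r2 = r_squared(I, I - fit$fvec),
                 converged = converged,
                 clamped = clamped,
                 init_params = init),
            class = "bi_exp_fit")
}

# log-linear fit of a (possibly noisy) positive decay; robust fallbacks when
# the peeled residual is non-positive or non-decaying
peel_loglin <- function(t, y, fallback_tau, fallback_amp) {
  ok <- y > 0
  if (sum(ok) >= 3L) {
    co <- stats::lm.fit(cbind(1, t[ok]), log(y[ok]))$coefficients
    if (is.finite(co[2L]) && co[2L] < 0) {
      return(list(amp = unname(exp(co[1L])), tau = unname(-1 / co[2L])))
    }
  }
  list(amp = fallback_amp, tau = fallback_tau)
}

#' @export
print.bi_exp_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<bi_exp_fit> I_f=%.4g (k_f=%.3g s), I_s=%.4g (k_s=%.3g s), I_0=%.4g, r2=%.5f%s\n",
              p$I_f, p$k_f, p$I_s, p$k_s, p$I_0, x$r2,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Fit several initial segments and pick the best-explained one
#'
#' Fits the mono-exponential model to each requested initial segment and
#' selects the segment with the highest r^2. Ties (r^2 within 1e-4 of the
#' maximum) go to the shortest segment, since the mono-exponential model is a
#' description of the earliest, two-by-two aggregation phase: when a short
#' and a long segment explain the data equally well, the short one makes the
#' weaker assumption.
#'
#' @param s A [syllectogram()] covering at least `max(durations)` seconds.
#' @param durations Segment lengths in seconds (default 1.5, 3, 5, 10).
#' @return Object of class `"segment_selection"`: `fits` (named list of
#'   [fit_mono_exp()] results keyed by duration), `best_duration`, and `rule`
#'   (`"max-r2"` or `"tie-shortest"`).
#' @export
select_best_segment <- function(s, durations = c(1.5, 3, 5, 10)) {
  stopifnot(inherits(s, "syllectogram"))
  durations <- sort(durations)
  if (max(durations) > syl_duration(s) + 1e-9) {
    stop_eak(sprintf("recording of %.3g s does not cover the longest requested segment (%.3g s)",
                     syl_duration(s), max(durations)), "eak_segment_too_long")
  }
  fits <- lapply(durations, function(d) {
    tryCatch(fit_mono_exp(extract_segment(s, d)), eak_error = function(e) NULL)
  })
  names(fits) <- format(durations)
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1L))
  if (!any(ok)) {
    stop_eak("no segment produced a convergent mono-exponential fit",
             "eak_all_fits_failed")
  }
  r2 <- vapply(fits, function(f) if (is.null(f)) -Inf else f$r2, numeric(1L))
  r2[!ok] <- -Inf
  near_best <- which(r2 > max(r2) - 1e-4)
  best_idx <- near_best[1L] # durations sorted ascending: first = shortest
  structure(list(fits = fits,
                 best_duration = durations[best_idx],
                 rule = if (length(near_best) > 1L) "tie-shortest" else "max-r2"),
            class = "segment_selection")
}

#' @export
print.segment_selection <- function(x, ...) {
  cat("<segment_selection>\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %5s s: %s\n", nm,
                if (is.null(f)) "fit failed" else sprintf("r2 = %.5f", f$r2)))
  }
  cat(sprintf("  best: %.3g s (%s)\n", x$best_duration, x$rule))
  invisible(x)
}

#' EAK5s: the half-life of the first 5 s of aggregation
#'
#' The headline statistic of the early aggregation kinetics: the first 5 s
#' segment of the syllectogram is fitted mono-exponentially and the half-life
#' `ln 2 / k` is reported. Shorthand for
#' `fit_mono_exp(extract_segment(s, 5))`.
#'
#' @param s A [syllectogram()] covering at least 5 s.
#' @param ... Passed to [fit_mono_exp()].
#' @return A `"mono_exp_fit"`; its `half_life` field is the EAK5s in seconds.
#' @examples
#' s <- simulate_syllectogram(mono_exp_params(1000, 0.2762), duration = 5)
#' compute_eak5s(s)$half_life # ~2.51 s, a typical healthy value
#' @export
compute_eak5s <- function(s, ...) {
  fit_mono_exp(extract_segment(s, 5), ...)
}
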