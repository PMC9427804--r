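# Forward kinetic models for the early erythrocyte-aggregation signal.
#
# Rate-constant conventions differ deliberately between types:
#   * mono_exp_params / model1_params carry a RATE k in s^-1
#     (the decay is exp(-k * t); half-life = ln 2 / k);
#   * bi_exp_params carries TIME CONSTANTS k_f, k_s in seconds
#     (each component decays as exp(-t / k)).
# Both conventions are standard in the syllectometry literature and are kept
# typed so no bare "k" crosses a module boundary.

#' Syllectogram: a backscattered-light decay curve
#'
#' A syllectogram is the time course of light backscattered by a stirred
#' whole-blood sample after stirring stops. Isolated erythrocytes backscatter
#' far more light than aggregates, so as two-by-two aggregates and rouleaux
#' form the recorded intensity decays. Time zero is the end of stirring.
#'
#' @param times Numeric vector of sampling times in seconds; strictly
#'   increasing, first sample at exactly 0.
#' @param intensities Numeric vector of backscattered-light intensities in
#'   arbitrary (device) units; all strictly positive.
#' @param meta Named list of free-form labels (subject id, tube id, minutes
#'   after blood draw, ...). Carried along by segment extraction and I/O.
#' @return An object of class `"syllectogram"`.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' s <- syllectogram(t, 1000 * exp(-0.28 * t))
#' s
#' @export
syllectogram <- function(times, intensities, meta = list()) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  n <- length(times)
  if (n != length(intensities)) {
    stop_eak("`times` and `intensities` must have equal length",
             "eak_invalid_syllectogram")
  }
  if (n < 8L) {
    stop_eak(sprintf("a syllectogram needs at least 8 samples, got %d", n),
             "eak_invalid_syllectogram")
  }
  if (any(!is.finite(times)) || any(!is.finite(intensities))) {
    stop_eak("times and intensities must be finite",
             "eak_invalid_syllectogram")
  }
  if (times[1L] != 0) {
    stop_eak(sprintf(
      "first sample must be at t = 0 (got %.6g); re-base times first (see read_syllectogram_csv)",
      times[1L]), "eak_invalid_syllectogram")
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop_eak(sprintf("times must be strictly increasing (violated at sample %d)", bad),
             "eak_invalid_syllectogram")
  }
  if (any(intensities <= 0)) {
    bad <- which(intensities <= 0)[1L]
    stop_eak(sprintf("all intensities must be > 0 (violated at sample %d)", bad),
             "eak_invalid_syllectogram")
  }
  structure(list(times = times, intensities = intensities,
                 meta = as.list(meta)),
            class = "syllectogram")
}

#' @export
print.syllectogram <- function(x, ...) {
  cat(sprintf("<syllectogram> %d samples over %.3g s, intensity %.4g .. %.4g\n",
              length(x$times), syl_duration(x),
              min(x$intensities), max(x$intensities)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.syllectogram <- function(x, ...) {
  data.frame(time_s = x$times, intensity = x$intensities)
}

#' Recording duration of a syllectogram, in seconds
#' @param s A [syllectogram()].
#' @return Duration in seconds (time of the last sample).
#' @export
syl_duration <- function(s) {
  stopifnot(inherits(s, "syllectogram"))
  s$times[length(s$times)]
}

#' Mono-exponential (first-order) kinetic parameters
#'
#' First-order aggregation kinetics: with isolated erythrocytes in excess,
#' the limiting factor is the aggregation step itself, and the concentration
#' of isolated cells (hence the backscattered intensity) decays as
#' `A0 * exp(-k * t)`.
#'
#' @param A0 Initial isolated-erythrocyte signal, arbitrary units, > 0.
#' @param k Rate constant in s^-1, > 0. Half-life is `ln(2) / k`.
#' @return Object of class `"mono_exp_params"`.
#' @export
mono_exp_params <- function(A0, k) {
  check_scalar_pos(A0, "A0")
  check_scalar_pos(k, "k")
  structure(list(A0 = A0, k = k), class = "mono_exp_params")
}

#' Second-order (inverse-linear) kinetic parameters
#'
#' Second-order aggregation kinetics: two-by-two aggregation at a rate
#' proportional to the squared concentration of isolated cells gives
#' `1/[A] = k*t + 1/A0`, i.e. the inverse intensity is linear in time.
#'
#' @param A0 Initial concentration proxy (arbitrary units), > 0.
#' @param k Second-order rate constant (per unit per second), > 0.
#' @return Object of class `"model1_params"`.
#' @export
model1_params <- function(A0, k) {
  check_scalar_pos(A0, "A0")
  check_scalar_pos(k, "k")
  structure(list(A0 = A0, k = k), class = "model1_params")
}

#' Bi-exponential syllectogram parameters
#'
#' Over a full 20 s recording the syllectogram is conventionally described as
#' the sum of a fast exponential (rouleaux formation) and a slow exponential
#' (three-dimensional aggregate growth) above a baseline:
#' `I(t) = I_f * exp(-t/k_f) + I_s * exp(-t/k_s) + I_0`.
#' `k_f` and `k_s` are TIME CONSTANTS in seconds (not rates); the fast
#' component has the smaller time constant.
#'
#' @param I_f Fast-component amplitude, >= 0.
#' @param k_f Fast time constant in seconds, > 0.
#' @param I_s Slow-component amplitude, >= 0.
#' @param k_s Slow time constant in seconds, > 0.
#' @param I_0 Baseline offset, >= 0.
#' @return Object of class `"bi_exp_params"`.
#' @export
bi_exp_params <- function(I_f, k_f, I_s, k_s, I_0 = 0) {
  check_scalar_pos(I_f, "I_f", strict = FALSE)
  check_scalar_pos(k_f, "k_f")
  check_scalar_pos(I_s, "I_s", strict = FALSE)
  check_scalar_pos(k_s, "k_s")
  check_scalar_pos(I_0, "I_0", strict = FALSE)
  if (I_f + I_s <= 0) {
    stop_eak("at least one amplitude (I_f, I_s) must be positive",
             "eak_domain_error")
  }
  if (I_f > 0 && I_s > 0 && k_f >= k_s) {
    stop_eak("fast time constant k_f must be smaller than slow k_s when both components are present",
             "eak_domain_error")
  }
  structure(list(I_f = I_f, k_f = k_f, I_s = I_s, k_s = k_s, I_0 = I_0),
            class = "bi_exp_params")
}

#' Stirred-tube geometry for shear-rate estimation
#'
#' Geometry of the blood-collection tube and the air bubble that stirs it.
#' During upside-down stirring the bubble travels along the tube axis and
#' forces blood through the gap between bubble and tube wall; the shear rate
#' in that gap is the bubble velocity divided by the gap width.
#'
#' Defaults describe a standard 4 ml EDTA tube stirred at 1 Hz, chosen to
#' give an order-of-magnitude 10^3 s^-1 shear rate.
#'
#' @param internal_diameter Tube internal diameter, meters.
#' @param bubble_diameter Horizontal diameter of the air bubble, meters;
#'   must be smaller than `internal_diameter`.
#' @param blood_volume Blood volume in liters.
#' @param stroke_length Bubble travel per half stirring cycle, meters.
#' @param frequency Stirring frequency, Hz.
#' @return Object of class `"tube_geometry"`.
#' @export
tube_geometry <- function(internal_diameter = 13e-3,
                          bubble_diameter = 12.8e-3,
                          blood_volume = 4e-3,
                          stroke_length = 60e-3,
                          frequency = 1) {
  check_scalar_pos(internal_diameter, "internal_diameter")
  check_scalar_pos(bubble_diameter, "bubble_diameter")
  check_scalar_pos(blood_volume, "blood_volume")
  check_scalar_pos(stroke_length, "stroke_length")
  check_scalar_pos(frequency, "frequency")
  if (bubble_diameter >= internal_diameter) {
    stop_eak("bubble_diameter must be smaller than internal_diameter (gap would be <= 0)",
             "eak_domain_error")
  }
  structure(list(internal_diameter = internal_diameter,
                 bubble_diameter = bubble_diameter,
                 blood_volume = blood_volume,
                 stroke_length = stroke_length,
                 frequency = frequency),
            class = "tube_geometry")
}

#' Evaluate the mono-exponential decay model
#'
#' @param params A [mono_exp_params()] (rate convention, s^-1).
#' @param times Non-negative times in seconds.
#' @return Intensities `A0 * exp(-k * times)`.
#' @examples
#' eval_mono_exp(mono_exp_params(1, log(2)), 1) # one half-life -> 0.5
#' @export
eval_mono_exp <- function(params, times) {
  stopifnot(inherits(params, "mono_exp_params"))
  times <- check_times(times)
  params$A0 * exp(-params$k * times)
}

#' Evaluate the second-order (inverse-linear) decay model
#'
#' @param params A [model1_params()].
#' @param times Non-negative times in seconds.
#' @return Intensities `1 / (k * times + 1 / A0)`.
#' @examples
#' eval_model1(model1_params(1, 1), 1) # 1/(1 + 1) = 0.5
#' @export
eval_model1 <- function(params, times) {
  stopifnot(inherits(params, "model1_params"))
  times <- check_times(times)
  1 / (params$k * times + 1 / params$A0)
}

#' Evaluate the bi-exponential syllectogram model
#'
#' @param params A [bi_exp_params()] (time-constant convention, seconds).
#' @param times Non-negative times in seconds.
#' @return Intensities `I_f*exp(-t/k_f) + I_s*exp(-t/k_s) + I_0`; the curve is
#'   monotone non-increasing and tends to `I_0`.
#' @export
eval_bi_exp <- function(params, times) {
  stopifnot(inherits(params, "bi_exp_params"))
  times <- check_times(times)
  params$I_f * exp(-times / params$k_f) +
    params$I_s * exp(-times / params$k_s) +
    params$I_0
}

#' Half-life of a first-order decay
#'
#' The headline aggregation statistic: for a mono-exponential decay with rate
#' constant `k`, the half-life is `ln(2) / k` seconds. Fitted on the first
#' 5 s of a syllectogram this quantity is called EAK5s.
#'
#' @param k Rate constant in s^-1, > 0.
#' @return Half-life in seconds.
#' @examples
#' half_life(log(2)) # 1 s
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop_eak("rate constant k must be a finite positive scalar", "eak_domain_error")
  }
  log(2) / k
}
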