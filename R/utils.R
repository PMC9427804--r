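# internal helpers: seeded evaluation, condition constructors, validation

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded simulations are pure functions of their seed and never
#' perturb the session stream. A `NULL` seed uses the current stream as-is.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialise a seed to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_eak <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "eak_error")))
}

warn_eak <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "eak_warning")))
}

check_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop_eak(sprintf("`%s` must be a finite %s number, got %s",
                     name, if (strict) "positive" else "non-negative",
                     deparse(substitute(x))),
             "eak_domain_error")
  }
  invisible(x)
}

check_times <- function(times) {
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0)) {
    stop_eak("`times` must be finite and non-negative (seconds)",
             "eak_domain_error")
  }
  invisible(as.numeric(times))
}
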