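# Validation statistics for EAK cohorts: coefficients of variation,
# normality, two-sample comparisons (pooled Student / Welch, including the
# summary-statistics form used against published group tables), correlation,
# and repeated-measurement stability.

test_result <- function(statistic, df, p_value, method, ...) {
  structure(c(list(statistic = unname(statistic), df = unname(df),
                   p_value = unname(p_value), method = method), list(...)),
            class = "eak_test")
}

#' @export
print.eak_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g%s, p = %.4g\n", x$method, x$statistic,
              if (is.null(x$df) || is.na(x$df)) "" else sprintf(", df = %.4g", x$df),
              x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean` with the sample SD (n-1 denominator). Used both across
#' subjects (interindividual CV) and across repeated measurements of one
#' sample (intraindividual CV).
#'
#' @param values Numeric vector, n >= 2, positive mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 3)) # 70.71%
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_eak("need at least 2 values", "eak_domain_error")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop_eak("coefficient of variation requires a positive mean", "eak_domain_error")
  }
  100 * stats::sd(values) / m
}

#' Coefficient of variation from summary statistics
#'
#' @param mean Group mean(s), > 0. Vectorised.
#' @param sd Group SD(s), >= 0.
#' @return CV in percent, `100 * sd / mean`.
#' @examples
#' cv_from_summary(c(2.51, 1.73, 1.70, 1.76), c(0.38, 0.34, 0.17, 0.44))
#' @export
cv_from_summary <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop_eak("mean must be positive", "eak_domain_error")
  }
  if (any(!is.finite(sd)) || any(sd < 0)) {
    stop_eak("sd must be non-negative", "eak_domain_error")
  }
  100 * sd / mean
}

#' Summarise a group of EAK5s values
#'
#' @param values Numeric vector of per-subject EAK5s, n >= 2.
#' @param label Group name.
#' @return Object of class `"group_summary"` with `n`, `mean`, `sd`, `cv_pct`,
#'   `label`.
#' @export
group_summary <- function(values, label = "group") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_eak("need at least 2 values", "eak_domain_error")
  structure(list(n = length(values), mean = mean(values),
                 sd = stats::sd(values),
                 cv_pct = coefficient_of_variation(values), label = label),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n = %d, EAK5s %.3g +/- %.3g s, CV %.1f%%\n",
              x$label, x$n, x$mean, x$sd, x$cv_pct))
  invisible(x)
}

#' Two-sample t-test on raw values
#'
#' Two-tailed comparison of two groups. The default is the classical pooled
#' (equal-variance) Student test; `variant = "welch"` uses the
#' unequal-variance form. When the two group SDs differ by more than a factor
#' of two the result carries a `note` recommending the Welch variant, since
#' the pooled test's equal-variance assumption is then doubtful.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return An `"eak_test"` with `statistic` (t), `df`, `p_value`, `method`.
#' @export
t_test_two_sample <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_eak("each group needs at least 2 values", "eak_domain_error")
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(test_result(0, length(a) + length(b) - 2L, 1,
                         method = paste0("student-t-two-tailed-", variant)))
    }
    stop_eak("both groups have zero variance but different means; t is undefined",
             "eak_degenerate_test")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  note <- NULL
  if (variant == "pooled") {
    sds <- sort(c(sqrt(va), sqrt(vb)))
    if (sds[1L] > 0 && sds[2L] / sds[1L] > 2) {
      note <- sprintf("group SDs differ by %.1fx; consider variant = 'welch'",
                      sds[2L] / sds[1L])
    }
  }
  test_result(ht$statistic, ht$parameter, ht$p.value,
              method = if (variant == "pooled") "student-t-two-tailed" else "welch-t",
              note = note)
}

#' Pooled Student t-test from summary statistics
#'
#' The two-tailed pooled-variance Student test computed directly from group
#' sizes, means and SDs — the form needed to check published group tables
#' where raw values are unavailable. Degrees of freedom are `n1 + n2 - 2`.
#'
#' @param n1,mean1,sd1 First group: size (>= 2), mean, SD.
#' @param n2,mean2,sd2 Second group.
#' @return An `"eak_test"`.
#' @examples
#' # healthy donors vs cardiology inpatients, published summaries:
#' t_test_from_summary(51, 2.51, 0.38, 14, 1.73, 0.34)
#' @export
t_test_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      return(test_result(0, df, 1, method = "student-t-two-tailed"))
    }
    stop_eak("zero pooled variance with different means; t is undefined",
             "eak_degenerate_test")
  }
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  if (mean1 == mean2) t <- 0
  test_result(t, df, 2 * stats::pt(-abs(t), df), method = "student-t-two-tailed")
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 <= n <= 5000, not constant.
#' @return An `"eak_test"` with the W statistic and two-sided p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop_eak("Shapiro-Wilk requires 3 <= n <= 5000", "eak_domain_error")
  }
  if (stats::sd(values) == 0) {
    stop_eak("Shapiro-Wilk is undefined for constant input", "eak_degenerate_test")
  }
  ht <- stats::shapiro.test(values)
  test_result(ht$statistic, NA_real_, ht$p.value, method = "shapiro-wilk")
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return An `"eak_test"` whose `statistic` is the sample correlation r
#'   (with the t value and df of the associated test carried as `t` and `df`).
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop_eak("need equal-length vectors with n >= 3", "eak_domain_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_eak("correlation is undefined for constant input", "eak_degenerate_test")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ht$estimate), unname(ht$parameter), ht$p.value,
              method = "pearson", t = unname(ht$statistic))
}

#' Stability of repeated EAK5s measurements over the first hour
#'
#' Assesses whether EAK5s drifts between blood draw and one hour later.
#' Returns the coefficient of variation of the repeated measurements
#' (per-subject, then averaged, when a `subject_id` column is present) and a
#' two-tailed t-test comparing a baseline block against all measurements
#' taken at or after `late_after` minutes.
#'
#' The baseline block is the first measurement of each subject when subject
#' ids are available; otherwise all measurements within the first
#' `baseline_window` minutes. The comparison is unpaired by default;
#' `paired = TRUE` (requires subject ids present in both blocks) compares
#' each subject's baseline with the mean of their late measurements.
#'
#' @param measurements data.frame with columns `minutes_after_draw`, `eak5s`,
#'   optionally `subject_id`.
#' @param late_after Minutes defining the late block (default 60).
#' @param baseline_window Minutes defining the baseline block when no subject
#'   ids are given (default 15).
#' @param paired Use a paired comparison (default `FALSE`).
#' @return List with `cv_pct` (mean per-subject repeat CV, in percent),
#'   `per_subject_cv` (named vector), and `first_vs_hour` (an `"eak_test"`).
#' @export
stability_analysis <- function(measurements, late_after = 60,
                               baseline_window = 15, paired = FALSE) {
  stopifnot(is.data.frame(measurements),
            all(c("minutes_after_draw", "eak5s") %in% names(measurements)))
  m <- measurements
  if (nrow(m) < 2L) stop_eak("need at least 2 measurements", "eak_domain_error")
  if (max(m$minutes_after_draw) < late_after) {
    stop_eak(sprintf("insufficient time span: no measurement at >= %g min (latest is %.3g min)",
                     late_after, max(m$minutes_after_draw)),
             "eak_insufficient_span")
  }
  has_subjects <- "subject_id" %in% names(m)
  if (has_subjects) {
    per_cv <- tapply(m$eak5s, m$subject_id, function(v) {
      if (length(v) >= 2L) coefficient_of_variation(v) else NA_real_
    })
    per_cv <- per_cv[!is.na(per_cv)]
    cv_pct <- mean(per_cv)
    first_idx <- unlist(lapply(split(seq_len(nrow(m)), m$subject_id),
                               function(i) i[which.min(m$minutes_after_draw[i])]))
    baseline <- m$eak5s[first_idx]
    baseline_subj <- m$subject_id[first_idx]
  } else {
    per_cv <- c(pooled = coefficient_of_variation(m$eak5s))
    cv_pct <- unname(per_cv)
    sel <- m$minutes_after_draw <= baseline_window
    baseline <- m$eak5s[sel]
    baseline_subj <- NULL
  }
  late_sel <- m$minutes_after_draw >= late_after
  late <- m$eak5s[late_sel]
  if (length(baseline) < 2L || length(late) < 2L) {
    stop_eak("need at least 2 measurements in both the baseline and the late block",
             "eak_domain_error")
  }
  if (paired) {
    if (!has_subjects) {
      stop_eak("paired comparison requires a subject_id column", "eak_domain_error")
    }
    late_by_subj <- tapply(late, m$subject_id[late_sel], mean)
    common <- intersect(names(late_by_subj), as.character(baseline_subj))
    if (length(common) < 2L) {
      stop_eak("paired comparison needs >= 2 subjects measured in both blocks",
               "eak_domain_error")
    }
    b <- baseline[match(common, as.character(baseline_subj))]
    l <- late_by_subj[common]
    d <- b - l
    if (stats::sd(d) == 0) {
      ht <- test_result(0, length(d) - 1L, 1, method = "paired-t-two-tailed")
    } else {
      tt <- stats::t.test(b, l, paired = TRUE)
      ht <- test_result(tt$statistic, tt$parameter, tt$p.value,
                        method = "paired-t-two-tailed")
    }
  } else {
    ht <- t_test_two_sample(baseline, late, variant = "pooled")
  }
  list(cv_pct = cv_pct, per_subject_cv = per_cv, first_vs_hour = ht)
}
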