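#' Construct a normalized FRAP trace
#'
#' @param times_s Times in seconds, re-zeroed so the bleach occurs at 0.
#' @param intensity_norm Fluorescence normalized to the pre-bleach mean (= 1).
#' @param bleach_time_s Original bleach time (annotation).
#' @param condition Free-text condition label (genotype, UV dose, ...).
#' @return Object of class `frap_trace`.
#' @export
frap_trace <- function(times_s, intensity_norm, bleach_time_s = 0,
                       condition = NA_character_) {
  if (length(times_s) != length(intensity_norm) || !length(times_s))
    smc_abort("times and intensities must be matched and non-empty", "invalid_config")
  if (any(intensity_norm < 0))
    smc_abort("normalized intensities must be nonnegative", "invalid_config")
  pre <- intensity_norm[times_s < 0]
  if (length(pre) && abs(mean(pre) - 1) > 0.05)
    smc_abort("pre-bleach mean must be 1 within 5%", "invalid_config")
  structure(list(times_s = as.numeric(times_s),
                 intensity_norm = as.numeric(intensity_norm),
                 bleach_time_s = bleach_time_s, condition = condition),
            class = "frap_trace")
}

#' Simulate a FRAP recovery trace
#'
#' Normalized fluorescence is 1 before the bleach (t < 0) and recovers as
#' `baseline + mobile_fraction * (1 - exp(-t / recovery_tau_s))` afterwards,
#' with optional additive Gaussian noise. `baseline` is the residual
#' fluorescence immediately after the bleach; `baseline + mobile_fraction`
#' is the recovery plateau and must not exceed 1 (the immobile fraction is
#' `1 - baseline - mobile_fraction`).
#'
#' @param mobile_fraction Mobile fraction in `[0, 1]`.
#' @param recovery_tau_s Recovery time constant, seconds (> 0).
#' @param times_s Sampling times, seconds, with the bleach at 0; the default
#'   is 10 s of pre-bleach and 60 s of recovery at 1 frame/s.
#' @param baseline Post-bleach residual intensity (default 0.3).
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param condition Condition label carried on the trace.
#' @param seed Integer seed or `NULL`.
#' @return A [frap_trace()].
#' @export
#' @examples
#' tr <- simulate_frap(0.5, 20, times_s = seq(-5, 120), baseline = 0.4)
#' frap_recovery_at(tr, 120) # ~ 0.899
simulate_frap <- function(mobile_fraction, recovery_tau_s,
                          times_s = seq(-10, 60, by = 1),
                          baseline = 0.3, noise_sd = 0,
                          condition = NA_character_, seed = NULL) {
  if (!length(times_s))
    smc_abort("empty time grid", "invalid_config")
  if (!is_scalar_number(mobile_fraction) || mobile_fraction < 0 || mobile_fraction > 1)
    smc_abort("mobile_fraction must lie in [0, 1]", "invalid_config")
  if (!is_scalar_number(recovery_tau_s) || recovery_tau_s <= 0)
    smc_abort("recovery_tau_s must be positive", "invalid_config")
  if (baseline < 0 || baseline + mobile_fraction > 1 + 1e-9)
    smc_abort("baseline must be >= 0 and baseline + mobile_fraction <= 1",
              "invalid_config")
  seed_if(seed)
  f <- ifelse(times_s < 0, 1,
              baseline + mobile_fraction * (1 - exp(-times_s / recovery_tau_s)))
  if (noise_sd > 0) f <- pmax(f + stats::rnorm(length(f), 0, noise_sd), 0)
  frap_trace(times_s, f, bleach_time_s = 0, condition = condition)
}

#' Normalize a raw FRAP trace to its pre-bleach intensity
#'
#' Divides the raw intensity by the mean of the pre-bleach frames and
#' re-zeroes time at the bleach.
#'
#' @param raw_times Acquisition times, seconds.
#' @param raw_intensity Raw fluorescence intensities.
#' @param bleach_time Time of the photobleach, seconds; at least 3 frames must
#'   precede it.
#' @param condition Condition label.
#' @return A [frap_trace()].
#' @export
normalize_frap_trace <- function(raw_times, raw_intensity, bleach_time,
                                 condition = NA_character_) {
  pre <- raw_intensity[raw_times < bleach_time]
  if (length(pre) < 3L)
    smc_abort("need >= 3 pre-bleach frames", "invalid_argument")
  frap_trace(raw_times - bleach_time, raw_intensity / mean(pre),
             bleach_time_s = bleach_time, condition = condition)
}

#' Fluorescence recovery at a fixed time after bleaching
#'
#' Linear interpolation of the normalized intensity at `t_s` (default 120 s),
#' the single-number mobility statistic used to compare conditions.
#'
#' @param trace A [frap_trace()].
#' @param t_s Time after bleach, seconds.
#' @param extrapolate If `FALSE` (default), a trace shorter than `t_s` is an
#'   error of class `smcurtain_out_of_range` rather than an extrapolation.
#' @return Interpolated normalized intensity.
#' @export
frap_recovery_at <- function(trace, t_s = 120, extrapolate = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  if (t_s > max(trace$times_s) && !extrapolate)
    smc_abort(sprintf("trace ends at %.1f s, before t = %.1f s", max(trace$times_s), t_s),
              "out_of_range")
  stats::approx(trace$times_s, trace$intensity_norm, xout = t_s, rule = 2)$y
}

#' Two-sample comparison of recovery statistics
#'
#' Two-sided two-sample t-test (equal-variance Student form by default, Welch
#' optionally) of per-cell recovery values between two conditions.
#'
#' @param values_a,values_b Numeric vectors of per-cell recovery values
#'   (>= 2 each).
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @return List with `t_statistic`, `p_value`, `df`, and the `htest` object.
#' @export
frap_compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    smc_abort("need >= 2 values per group", "invalid_argument")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0)
    smc_abort("zero variance in both groups; test is degenerate", "degenerate_test")
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), test = ht)
}
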