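#' Classify a trajectory's lesion engagement
#'
#' Scans a track for an arrest at the lesion: entering the lesion interval
#' (padded by one pixel to absorb localization error) and remaining within
#' `arrest_radius_kbp` of it for at least `arrest_window_s`. The engagement
#' mode is `"direct"` when the arrest starts within the first
#' `direct_max_frames` frames of the track (a molecule first detected already
#' arrested; sub-pixel diffusion before detection cannot be excluded at
#' ~1 kbp resolution), `"diffusion"` when the track visited positions more
#' than 1 kbp outside the interval before arresting, and `"none"` when no
#' arrest occurs. Transits of the window that do not end in arrest are counted
#' as bypasses.
#'
#' @param traj A [curtain_track()].
#' @param lesion_interval_kbp Lesion interval, kbp (default the 33.513-33.630
#'   kbp cassette).
#' @param arrest_window_s Minimum stay to call an arrest (default 20 s).
#' @param arrest_radius_kbp Maximum distance from the interval during an
#'   arrest (default 1 kbp, one pixel).
#' @param direct_max_frames Latest arrest-start frame still called direct
#'   binding (default 2).
#' @param pad_kbp Padding of the interval used for transit detection
#'   (default 1 kbp).
#' @return One-row data frame (class `dwell_event`) with `track_id`, `mode`,
#'   `bypass_count`, `dwell_s`, `censored`, `arrival_time_s`.
#' @export
classify_event <- function(traj, lesion_interval_kbp = c(33.513, 33.630),
                           arrest_window_s = 20, arrest_radius_kbp = 1,
                           direct_max_frames = 2, pad_kbp = 1) {
  stopifnot(inherits(traj, "curtain_track"))
  lo <- lesion_interval_kbp[1]; hi <- lesion_interval_kbp[2]
  if (lo >= hi || lo < 0 ||
      (!is.na(traj$dna_length_kbp) && hi > traj$dna_length_kbp))
    smc_abort("lesion interval outside the DNA", "invalid_argument")
  t <- traj$times_s
  n <- length(traj$positions_kbp)
  # running-median filter suppresses single-frame localization excursions that
  # would otherwise fragment a genuine arrest into sub-threshold runs
  x <- if (n >= 5L) stats::runmed(traj$positions_kbp, 5, endrule = "median")
       else traj$positions_kbp
  dt <- if (n > 1) t[2] - t[1] else Inf
  zone_lo <- lo - arrest_radius_kbp
  zone_hi <- hi + arrest_radius_kbp
  in_zone <- x >= zone_lo & x <= zone_hi
  # close short out-of-zone gaps (<= 3 frames) that survive the filter: a
  # genuine departure shorter than that is indistinguishable from noise
  runs <- rle(in_zone)
  if (length(runs$lengths) > 2L) {
    short_gap <- !runs$values & runs$lengths <= 3L &
      seq_along(runs$values) > 1L & seq_along(runs$values) < length(runs$values)
    runs$values[short_gap] <- TRUE
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  zone_runs <- which(runs$values)
  run_dur <- (runs$lengths - 1L) * dt
  # arrest: a stay of >= arrest_window_s, or a shorter stay (>= 5 s) that runs
  # to the very end of the track (engagement truncated by the window)
  qualifies <- run_dur[zone_runs] >= arrest_window_s |
    (ends[zone_runs] == n & run_dur[zone_runs] >= min(arrest_window_s, 5))
  arrest_idx <- zone_runs[qualifies]
  arrest_start <- if (length(arrest_idx)) starts[arrest_idx[1]] else NA_integer_

  # side-to-side crossings of the padded window before arrest (or before track
  # end for mode "none"), counted on the raw positions so fast one-frame
  # transits survive; same-side excursions are below the optical resolution
  upto <- if (is.na(arrest_start)) n else arrest_start - 1L
  bypass <- 0L
  if (upto >= 2L) {
    bypass <- nrow(window_passes(traj$positions_kbp[seq_len(upto)],
                                 lo - pad_kbp, hi + pad_kbp, touches = FALSE))
  }

  if (is.na(arrest_start)) {
    md <- "none"
    dwell <- NA_real_
    censored <- NA
    arrival <- NA_real_
  } else {
    arrest_end <- ends[arrest_idx[1]]
    md <- if (arrest_start <= direct_max_frames) "direct" else {
      visited_out <- any(x[seq_len(arrest_start - 1L)] < lo - 1 |
                         x[seq_len(arrest_start - 1L)] > hi + 1)
      if (visited_out) "diffusion" else "direct"
    }
    if (md == "direct") bypass <- 0L
    dwell <- t[arrest_end] - t[arrest_start]
    censored <- arrest_end == n && isTRUE(traj$censored_end)
    arrival <- t[arrest_start]
  }
  out <- data.frame(track_id = traj$track_id, mode = md,
                    bypass_count = bypass, dwell_s = dwell,
                    censored = censored, arrival_time_s = arrival,
                    stringsAsFactors = FALSE)
  class(out) <- c("dwell_event", "data.frame")
  out
}

#' Classify many trajectories
#'
#' @param trajs List of [curtain_track()].
#' @param ... Passed to [classify_event()].
#' @return Data frame with one row per track.
#' @export
classify_events <- function(trajs, ...) {
  out <- do.call(rbind, lapply(trajs, classify_event, ...))
  rownames(out) <- NULL
  out
}

#' Lesion recognition efficiency from bypass counts
#'
#' The probability-weighted efficiency
#' `sum_b 1/(b + 1) * n_b / n_total * 100 (%)` over the bypass histogram of
#' engaged molecules: a molecule that engaged on its `(b+1)`-th encounter had
#' per-encounter success `1/(b+1)` in expectation, so the statistic estimates
#' the chance that a single encounter with the lesion leads to stable binding.
#'
#' @param events Data frame with columns `mode` and `bypass_count` (e.g. from
#'   [classify_events()] or [simulate_search_experiment()]); only rows with
#'   `mode != "none"` enter.
#' @return Object of class `efficiency_result`: `efficiency_percent`,
#'   `n_total`, `bypass_histogram`.
#' @export
#' @examples
#' ev <- data.frame(mode = "diffusion", bypass_count = c(rep(0, 8), 1, 2))
#' recognition_efficiency(ev)$efficiency_percent # 88.33
recognition_efficiency <- function(events) {
  engaged <- events[events$mode != "none" & !is.na(events$bypass_count), , drop = FALSE]
  if (!nrow(engaged))
    smc_abort("no engaged molecules; efficiency undefined", "insufficient_data")
  b <- engaged$bypass_count
  structure(list(
    efficiency_percent = mean(1 / (b + 1)) * 100,
    n_total = length(b),
    bypass_histogram = table(b)
  ), class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("recognition efficiency: %.1f%% (n = %d)\n",
              x$efficiency_percent, x$n_total))
  invisible(x)
}

#' Proportion with binomial standard deviation
#'
#' `p_hat = k / n` with `sd = sqrt(p_hat (1 - p_hat) / n)`, the standard
#' deviation of a binomial proportion — the error model used for
#' direct-versus-diffusion population fractions.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (>= 1).
#' @return List with `p_hat`, `sd_binomial`, `n`.
#' @export
#' @examples
#' fraction_with_sd(27, 144)
fraction_with_sd <- function(k, n) {
  if (!is_scalar_number(n) || n < 1)
    smc_abort("n must be >= 1", "invalid_argument")
  if (!is_scalar_number(k) || k < 0 || k > n)
    smc_abort("k must satisfy 0 <= k <= n", "invalid_argument")
  p <- k / n
  list(p_hat = p, sd_binomial = sqrt(p * (1 - p) / n), n = n)
}

#' Fit the lesion residence time from dwell events
#'
#' Two estimators of the mean residence time tau of an exponential dwell
#' observed in a finite window:
#'
#' * `"naive"`: least-squares single-exponential fit to the normalized
#'   histogram of uncensored dwells, ignoring censoring. Because arrests occur
#'   throughout the window, long dwells are preferentially censored away and
#'   this estimator is biased low once tau is comparable to the window — it is
#'   provided to reproduce the conventional single-molecule analysis.
#' * `"mle"`: the censored-exponential maximum likelihood estimator
#'   `tau_hat = sum(all observed durations) / number of uncensored events`,
#'   which is unbiased under independent censoring.
#'
#' @param events Data frame with `mode`, `dwell_s`, `censored`; rows with
#'   `mode == "none"` are dropped.
#' @param window_s Observation window, seconds (default 600).
#' @param method `"naive"` or `"mle"`.
#' @param n_bins Histogram bins for the naive fit (default 12).
#' @return List with `tau_s`, `se`, `method`, `n_events`, `n_censored`, and
#'   `lower_bound_only` (`TRUE` when every event is censored and only a lower
#'   bound on tau can be reported).
#' @export
#' @examples
#' ev <- data.frame(mode = "diffusion", dwell_s = c(100, 200, 600),
#'                  censored = c(FALSE, FALSE, TRUE))
#' fit_residence_time(ev, method = "mle")$tau_s # 450
fit_residence_time <- function(events, window_s = 600,
                               method = c("naive", "mle"), n_bins = 12) {
  method <- match.arg(method)
  if (window_s <= 0)
    smc_abort("window_s must be positive", "invalid_argument")
  ev <- events[events$mode != "none" & !is.na(events$dwell_s), , drop = FALSE]
  if (!nrow(ev))
    smc_abort("no dwell records", "insufficient_data")
  if (method == "mle") {
    n_unc <- sum(!ev$censored)
    total <- sum(ev$dwell_s)
    if (n_unc == 0L) {
      w <- simpleWarning("all events censored; reporting a lower bound on tau")
      class(w) <- c("smcurtain_lower_bound", class(w))
      warning(w)
      return(list(tau_s = total, se = NA_real_, method = "mle",
                  n_events = nrow(ev), n_censored = nrow(ev),
                  lower_bound_only = TRUE))
    }
    tau <- total / n_unc
    return(list(tau_s = tau, se = tau / sqrt(n_unc), method = "mle",
                n_events = nrow(ev), n_censored = sum(ev$censored),
                lower_bound_only = FALSE))
  }
  dw <- ev$dwell_s[!ev$censored]
  if (length(dw) < 5L)
    smc_abort("naive fit needs >= 5 uncensored dwells", "insufficient_data")
  breaks <- seq(0, max(dw) * (1 + 1e-9), length.out = n_bins + 1L)
  h <- graphics::hist(dw, breaks = breaks, plot = FALSE)
  df <- data.frame(t = h$mids, y = h$density / max(h$density))
  fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                           start = list(A = 1, tau = stats::median(dw)),
                           lower = c(1e-9, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  list(tau_s = unname(cf["tau", "Estimate"]),
       se = unname(cf["tau", "Std. Error"]), method = "naive",
       n_events = nrow(ev), n_censored = sum(ev$censored),
       lower_bound_only = FALSE)
}
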