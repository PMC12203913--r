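#' Simulate a lesion-search experiment
#'
#' Generates the outcome of observing many labelled molecules searching a
#' stretched DNA carrying a lesion cassette, in one of two modes.
#'
#' `mode = "fast"` draws each molecule's outcome directly from the generative
#' law: direct lesion binding (3D collision) with probability
#' `cfg$direct_binding_prob`, otherwise engagement by 1D diffusion with a
#' bypass count drawn geometrically (number of failed transits before capture,
#' per-pass success `cfg$capture_prob_per_pass`). Arrival times are uniform on
#' the observation window for diffusive molecules and at time zero for direct
#' binders; dwells are exponential with mean `cfg$mean_dwell_s`, right-censored
#' at the end of the window. No trajectories are rendered.
#'
#' `mode = "explicit"` simulates each molecule's full reflected Brownian path
#' and realizes capture dynamically: every true transit of the lesion interval
#' is a Bernoulli capture attempt, so the bypass count is geometric by
#' construction but is produced by real crossings. Molecules whose path never
#' engages the lesion within the window get ground-truth mode `"none"`.
#' Rendered trajectories (with localization noise) are returned alongside the
#' ground-truth events so the event classifier can be validated end-to-end.
#'
#' @param cfg A [sim_config()].
#' @param n_molecules Number of molecules to simulate (>= 1).
#' @param mode `"fast"` (event-level, default) or `"explicit"` (trajectory
#'   level).
#' @param seed Integer seed; defaults to `cfg$rng_seed`.
#' @return List with `events` (a data frame with columns `track_id`, `mode`,
#'   `bypass_count`, `dwell_s`, `censored`, `arrival_time_s`) and
#'   `trajectories` (list of [curtain_track()] in explicit mode, else `NULL`).
#' @export
#' @examples
#' cfg <- sim_config(rng_seed = 1)
#' ev <- simulate_search_experiment(cfg, 50)$events
#' table(ev$mode)
simulate_search_experiment <- function(cfg, n_molecules,
                                       mode = c("fast", "explicit"),
                                       seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  if (!is_scalar_number(n_molecules) || n_molecules < 1)
    smc_abort("n_molecules must be >= 1", "invalid_config")
  n_molecules <- as.integer(n_molecules)
  if (mode == "fast") search_fast(cfg, n_molecules, seed)
  else search_explicit(cfg, n_molecules, seed)
}

search_fast <- function(cfg, n, seed) {
  seed_if(seed)
  W <- cfg$observation_window_s
  direct <- stats::runif(n) < cfg$direct_binding_prob
  q <- cfg$capture_prob_per_pass
  bypass <- integer(n)
  if (q > 0) {
    bypass[!direct] <- stats::rgeom(sum(!direct), q)
  } else {
    bypass[!direct] <- NA_integer_  # never captured
  }
  arrival <- ifelse(direct, 0, stats::runif(n, 0, W))
  dwell_true <- stats::rexp(n, rate = 1 / cfg$mean_dwell_s)
  avail <- W - arrival
  censored <- dwell_true > avail
  events <- data.frame(
    track_id = sprintf("mol%04d", seq_len(n)),
    mode = ifelse(direct, "direct", ifelse(is.na(bypass), "none", "diffusion")),
    bypass_count = bypass,
    dwell_s = ifelse(censored, avail, dwell_true),
    censored = censored,
    arrival_time_s = arrival,
    stringsAsFactors = FALSE
  )
  events$dwell_s[events$mode == "none"] <- NA_real_
  events$censored[events$mode == "none"] <- NA
  list(events = events, trajectories = NULL)
}

search_explicit <- function(cfg, n, seed) {
  L <- cfg$dna_length_kbp
  lo <- cfg$lesion_interval_kbp[1]
  hi <- cfg$lesion_interval_kbp[2]
  dt <- cfg$frame_interval_s
  nf <- cfg$n_frames
  step_sd <- sqrt(2 * cfg$diffusion_kbp2_s * dt)
  q <- cfg$capture_prob_per_pass
  center <- (lo + hi) / 2

  trajs <- vector("list", n)
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    seed_if(split_seed(seed, i))
    id <- sprintf("mol%04d", i)
    direct <- stats::runif(1) < cfg$direct_binding_prob
    dwell_true <- stats::rexp(1, rate = 1 / cfg$mean_dwell_s)
    if (direct) {
      arrest_frame <- 1L
      bypass <- 0L
      arrest_pos <- stats::runif(1, lo, hi)
      pos <- rep(arrest_pos, nf)
      md <- "direct"
    } else {
      start <- stats::runif(1, 0, L)
      pos <- reflect_into(start + cumsum(c(0, stats::rnorm(nf - 1L, 0, step_sd))), L)
      # one capture attempt per pass of the true lesion interval
      passes <- window_passes(pos, lo, hi)
      arrest_frame <- NA_integer_
      bypass <- nrow(passes)
      if (nrow(passes) && q > 0) {
        caught <- stats::runif(nrow(passes)) < q
        k <- which(caught)
        if (length(k)) {
          k <- k[1]
          bypass <- k - 1L
          arrest_frame <- passes$at[k]
        }
      }
      if (is.na(arrest_frame)) {
        md <- "none"
        arrest_pos <- NA_real_
      } else {
        md <- "diffusion"
        arrest_pos <- min(max(pos[arrest_frame], lo), hi)
      }
    }
    if (!is.na(arrest_frame)) {
      t_arrest <- (arrest_frame - 1L) * dt
      end_frame <- min(nf, arrest_frame + floor(dwell_true / dt))
      pos[arrest_frame:end_frame] <- arrest_pos
      pos <- pos[seq_len(end_frame)]
      censored <- (t_arrest + dwell_true) >= nf * dt
      dwell_obs <- (end_frame - arrest_frame) * dt
      ev[[i]] <- data.frame(track_id = id, mode = md, bypass_count = bypass,
                            dwell_s = if (censored) (nf - arrest_frame) * dt else dwell_obs,
                            censored = censored, arrival_time_s = t_arrest,
                            stringsAsFactors = FALSE)
    } else {
      ev[[i]] <- data.frame(track_id = id, mode = "none", bypass_count = bypass,
                            dwell_s = NA_real_, censored = NA,
                            arrival_time_s = NA_real_, stringsAsFactors = FALSE)
    }
    obs <- pos
    if (cfg$localization_sigma_kbp > 0)
      obs <- pmin(pmax(obs + stats::rnorm(length(pos), 0, cfg$localization_sigma_kbp), 0), L)
    trajs[[i]] <- curtain_track(id, times_s = (seq_along(obs) - 1) * dt,
                                positions_kbp = obs,
                                sigma_loc_kbp = cfg$localization_sigma_kbp,
                                salt_mM = cfg$salt_mM,
                                censored_end = length(obs) == nf,
                                dna_length_kbp = L)
  }
  list(events = do.call(rbind, ev), trajectories = trajs)
}

# Lesion-window pass detection shared by the explicit simulator and the event
# classifier. A "pass" is one encounter of the window: a side-to-side crossing
# (below -> above or vice versa, possibly jumping the window between frames)
# or, when `touches` is TRUE, an excursion that enters the window and exits on
# the same side. The simulator counts touches of the true (sub-pixel) window —
# they are genuine encounters — while the classifier counts only crossings of
# the padded window, because a same-side excursion at ~1 kbp resolution is
# indistinguishable from localization noise. Returns the frame index at which
# each pass completes, with the frame best representing the encounter (`at`:
# a frame inside the window if any, else the landing frame of the jump).
window_passes <- function(x, lo, hi, touches = TRUE) {
  side <- ifelse(x < lo, -1L, ifelse(x > hi, 1L, 0L))
  nz <- which(side != 0L)
  if (length(nz) < 2L) return(data.frame(frame = integer(0), at = integer(0)))
  crossed <- diff(side[nz]) != 0L
  touched <- diff(nz) > 1L              # frames inside the window in between
  pass <- if (touches) crossed | touched else crossed
  data.frame(frame = nz[-1][pass],
             at = ifelse(touched, nz[-length(nz)] + 1L, nz[-1])[pass])
}
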