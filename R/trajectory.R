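#' Construct a single-particle trajectory
#'
#' A trajectory is one particle's time-ordered positions along a single DNA
#' molecule, in kbp from the barrier-tethered end (coordinate 0), at a uniform
#' frame interval.
#'
#' @param track_id Identifier (coerced to character).
#' @param times_s Strictly increasing, uniformly spaced times in seconds.
#' @param positions_kbp Positions along the DNA in kbp; must lie in
#'   `[0, dna_length_kbp]` when a length is given.
#' @param sigma_loc_kbp Localization uncertainty (sd, kbp) of each position.
#' @param salt_mM Buffer NaCl concentration, mM (annotation only).
#' @param censored_end `TRUE` if the particle was still present at the end of
#'   the observation window (the track is right-censored).
#' @param dna_length_kbp DNA length in kbp, or `NA` if unknown.
#' @return Object of class `curtain_track`.
#' @export
curtain_track <- function(track_id, times_s, positions_kbp,
                          sigma_loc_kbp = 0, salt_mM = NA_real_,
                          censored_end = FALSE, dna_length_kbp = NA_real_) {
  times_s <- as.numeric(times_s)
  positions_kbp <- as.numeric(positions_kbp)
  if (length(times_s) != length(positions_kbp))
    smc_abort("times and positions differ in length", "validation")
  if (length(times_s) < 1L)
    smc_abort("empty trajectory", "validation")
  if (length(times_s) > 1L) {
    dt <- diff(times_s)
    if (any(dt <= 0))
      smc_abort(sprintf("track '%s': times must be strictly increasing", track_id),
                "validation")
    if (max(dt) - min(dt) > 1e-6 * max(dt))
      smc_abort(sprintf("track '%s': times must be uniformly spaced", track_id),
                "validation")
  }
  if (!is.na(dna_length_kbp) &&
      (any(positions_kbp < -1e-9) || any(positions_kbp > dna_length_kbp + 1e-9)))
    smc_abort(sprintf("track '%s': positions outside [0, L]", track_id), "validation")
  structure(list(
    track_id = as.character(track_id),
    times_s = times_s,
    positions_kbp = positions_kbp,
    sigma_loc_kbp = sigma_loc_kbp,
    salt_mM = salt_mM,
    censored_end = isTRUE(censored_end),
    dna_length_kbp = dna_length_kbp
  ), class = "curtain_track")
}

#' @export
print.curtain_track <- function(x, ...) {
  cat(sprintf("curtain_track '%s': %d frames, t = [%.3g, %.3g] s, pos = [%.2f, %.2f] kbp%s\n",
              x$track_id, length(x$times_s), x$times_s[1],
              x$times_s[length(x$times_s)], min(x$positions_kbp),
              max(x$positions_kbp), if (x$censored_end) " (censored)" else ""))
  invisible(x)
}

# Reflect free positions into [0, L] (exact method for reflecting Brownian
# motion: fold the unbounded path at 0 and L).
reflect_into <- function(x, L) {
  p <- x %% (2 * L)
  ifelse(p > L, 2 * L - p, p)
}

#' Simulate a 1D sliding trajectory on stretched DNA
#'
#' Brownian motion along the DNA with reflecting boundaries at both ends.
#' Per-frame true displacements are Gaussian with variance `2 * D * dt`
#' (converted from um^2/s to kbp^2/s through the extension factor); independent
#' Gaussian localization noise of sd `localization_sigma_kbp` is added to each
#' observed position, which is then clipped to the DNA.
#'
#' @param cfg A [sim_config()].
#' @param track_id Identifier for the generated track.
#' @param start_kbp Starting position; default uniform on the DNA.
#' @param seed Integer seed; defaults to `cfg$rng_seed`.
#' @return A [curtain_track()].
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 100, rng_seed = 7)
#' tr <- simulate_sliding_trajectory(cfg)
#' range(tr$positions_kbp)
simulate_sliding_trajectory <- function(cfg, track_id = "sim1",
                                        start_kbp = NULL,
                                        seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  seed_if(seed)
  L <- cfg$dna_length_kbp
  n <- cfg$n_frames
  dt <- cfg$frame_interval_s
  step_sd <- sqrt(2 * cfg$diffusion_kbp2_s * dt)
  if (is.null(start_kbp)) start_kbp <- stats::runif(1, 0, L)
  true_pos <- if (n > 1L) {
    reflect_into(start_kbp + cumsum(c(0, stats::rnorm(n - 1L, 0, step_sd))), L)
  } else start_kbp
  obs <- true_pos
  if (cfg$localization_sigma_kbp > 0)
    obs <- pmin(pmax(obs + stats::rnorm(n, 0, cfg$localization_sigma_kbp), 0), L)
  tr <- curtain_track(track_id, times_s = (seq_len(n) - 1) * dt,
                      positions_kbp = obs,
                      sigma_loc_kbp = cfg$localization_sigma_kbp,
                      salt_mM = cfg$salt_mM, censored_end = TRUE,
                      dna_length_kbp = L)
  tr$true_positions_kbp <- true_pos
  tr
}
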