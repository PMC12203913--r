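#' Configuration for a simulated DNA-curtain experiment
#'
#' Collects every knob of the synthetic single-molecule experiment in one
#' validated object. Defaults describe the reference experiment the package
#' emulates: a 48,502 bp lambda phage DNA stretched at ~0.272 um/kbp carrying a
#' triple-CPD lesion cassette between 33,513 and 33,630 bp, imaged at
#' ~1 kbp/pixel over a 600 s observation window, with the searching protein
#' diffusing at 0.025 um^2/s.
#'
#' @param dna_length_bp DNA substrate length in base pairs (lambda genome,
#'   48,502 bp).
#' @param lesion_interval_bp Two integers, start/end of the lesion cassette in
#'   bp from the barrier-tethered end.
#' @param extension_um_per_kbp Imaged extension of the stretched DNA in um per
#'   kbp; converts diffusion coefficients between um^2/s and kbp^2/s.
#' @param frame_interval_s Acquisition interval in seconds.
#' @param n_frames Number of frames; defaults to
#'   `observation_window_s / frame_interval_s`.
#' @param localization_sigma_kbp Gaussian localization noise sd, kbp. Default
#'   0.5 kbp, half the one-pixel (~1 kbp) optical resolution.
#' @param diffusion_um2_s 1D diffusion coefficient in um^2/s.
#' @param capture_prob_per_pass Probability that a diffusing molecule engages
#'   the lesion on a single transit of the lesion interval.
#' @param direct_binding_prob Probability that a molecule binds the lesion
#'   directly (3D collision) rather than arriving by 1D diffusion.
#' @param mean_dwell_s Mean of the exponential lesion residence time, seconds.
#' @param observation_window_s Length of the recording, seconds; dwells are
#'   right-censored here.
#' @param salt_mM NaCl concentration of the imaging buffer, mM.
#' @param rng_seed Integer seed or `NULL`; see [split_seed()].
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(rng_seed = 1)
#' cfg$dna_length_kbp
sim_config <- function(dna_length_bp = 48502,
                       lesion_interval_bp = c(33513, 33630),
                       extension_um_per_kbp = 0.272,
                       frame_interval_s = 0.1,
                       n_frames = NULL,
                       localization_sigma_kbp = 0.5,
                       diffusion_um2_s = 0.025,
                       capture_prob_per_pass = 0.89,
                       direct_binding_prob = 0.19,
                       mean_dwell_s = 900,
                       observation_window_s = 600,
                       salt_mM = 100,
                       rng_seed = NULL) {
  if (!is_scalar_number(frame_interval_s) || frame_interval_s <= 0)
    smc_abort("frame_interval_s must be a positive number", "invalid_config")
  if (is.null(n_frames))
    n_frames <- as.integer(round(observation_window_s / frame_interval_s))
  if (!is_scalar_number(n_frames) || n_frames < 1)
    smc_abort("n_frames must be a positive integer", "invalid_config")
  if (!is_scalar_number(dna_length_bp) || dna_length_bp <= 0)
    smc_abort("dna_length_bp must be positive", "invalid_config")
  if (length(lesion_interval_bp) != 2L ||
      lesion_interval_bp[1] >= lesion_interval_bp[2] ||
      lesion_interval_bp[1] < 0 || lesion_interval_bp[2] > dna_length_bp)
    smc_abort("lesion_interval_bp must be an increasing pair within [0, dna_length_bp]",
              "invalid_config")
  if (!is_scalar_number(diffusion_um2_s) || diffusion_um2_s < 0)
    smc_abort("diffusion_um2_s must be nonnegative", "invalid_config")
  if (!is_scalar_number(capture_prob_per_pass) ||
      capture_prob_per_pass < 0 || capture_prob_per_pass > 1)
    smc_abort("capture_prob_per_pass must lie in [0, 1]", "invalid_config")
  if (!is_scalar_number(direct_binding_prob) ||
      direct_binding_prob < 0 || direct_binding_prob > 1)
    smc_abort("direct_binding_prob must lie in [0, 1]", "invalid_config")
  if (!is_scalar_number(mean_dwell_s) || mean_dwell_s <= 0)
    smc_abort("mean_dwell_s must be positive", "invalid_config")
  if (!is_scalar_number(observation_window_s) || observation_window_s <= 0)
    smc_abort("observation_window_s must be positive", "invalid_config")
  if (!is_scalar_number(localization_sigma_kbp) || localization_sigma_kbp < 0)
    smc_abort("localization_sigma_kbp must be nonnegative", "invalid_config")
  if (!is_scalar_number(extension_um_per_kbp) || extension_um_per_kbp <= 0)
    smc_abort("extension_um_per_kbp must be positive", "invalid_config")

  structure(list(
    dna_length_bp = dna_length_bp,
    dna_length_kbp = dna_length_bp / 1000,
    lesion_interval_bp = as.numeric(lesion_interval_bp),
    lesion_interval_kbp = as.numeric(lesion_interval_bp) / 1000,
    extension_um_per_kbp = extension_um_per_kbp,
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    localization_sigma_kbp = localization_sigma_kbp,
    diffusion_um2_s = diffusion_um2_s,
    diffusion_kbp2_s = um2_to_kbp2(diffusion_um2_s, extension_um_per_kbp),
    capture_prob_per_pass = capture_prob_per_pass,
    direct_binding_prob = direct_binding_prob,
    mean_dwell_s = mean_dwell_s,
    observation_window_s = observation_window_s,
    salt_mM = salt_mM,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("DNA-curtain simulation config\n")
  cat(sprintf("  DNA: %d bp, lesion at %.0f-%.0f bp, extension %.3f um/kbp\n",
              x$dna_length_bp, x$lesion_interval_bp[1], x$lesion_interval_bp[2],
              x$extension_um_per_kbp))
  cat(sprintf("  imaging: %d frames x %.3g s, sigma_loc %.2f kbp, window %.0f s\n",
              x$n_frames, x$frame_interval_s, x$localization_sigma_kbp,
              x$observation_window_s))
  cat(sprintf("  motion: D = %.4g um^2/s (%.4g kbp^2/s), salt %.0f mM\n",
              x$diffusion_um2_s, x$diffusion_kbp2_s, x$salt_mM))
  cat(sprintf("  search: P(direct) = %.2f, P(capture per pass) = %.2f, mean dwell %.0f s\n",
              x$direct_binding_prob, x$capture_prob_per_pass, x$mean_dwell_s))
  invisible(x)
}
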