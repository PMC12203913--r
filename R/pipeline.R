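#' Default pipeline configuration
#'
#' Parameter blocks for [run_pipeline()], all overridable: the simulation
#' config, the number of molecules per stage, and the equilibrium parameters.
#'
#' @param seed Global integer seed; every stage derives its stream from it.
#' @return Nested list of pipeline parameters.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = seed,
    sim = list(),                 # overrides passed to sim_config()
    search = list(n_molecules = 60),
    diffusion = list(n_tracks = 40, n_frames = 300, fit_lags = 1:10),
    snapshot = list(n_events = 300, specific_fraction = 0.6,
                    localization_sigma_kbp = 1),
    titration = list(ladder_nM = c(0, 3, 5, 10, 15, 20, 30, 50),
                     dna_total_nM = 4, noise_sd = 0.05),
    equilibria = list()           # overrides passed to equilibrium_params()
  )
}

load_run_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw
}

merge_config <- function(base, user) {
  known <- names(base)
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    smc_abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
              "invalid_config")
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      utils::modifyList(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Run the full simulate-track-analyze pipeline
#'
#' Executes, from one seed: an explicit lesion-search simulation with event
#' classification (mode fractions with binomial sd, recognition efficiency,
#' naive and censored-MLE residence times), a sliding-trajectory ensemble with
#' pooled diffusion estimation and displacement-Gaussian check, a curtain
#' snapshot with histogram, peak fit and lesion enrichment, titration
#' simulation and Kd refitting for the lesion substrate, and the coupled
#' equilibrium enhancement folds. Writes a single JSON report (plus a
#' resolved-config snapshot) when `out_dir` is given.
#'
#' @param config List of overrides (see [default_run_config()]) or a path to
#'   a YAML/JSON config file.
#' @param out_dir Optional output directory for `report.json` and
#'   `config.json`.
#' @return The report, an S3 list of class `smcurtain_report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- load_run_config_file(config)
  cfg_all <- merge_config(default_run_config(), config)
  seed <- as.integer(cfg_all$seed)
  sim <- do.call(sim_config, c(cfg_all$sim, list(rng_seed = seed)))

  # --- lesion search -------------------------------------------------------
  search <- simulate_search_experiment(sim, cfg_all$search$n_molecules,
                                       mode = "explicit",
                                       seed = split_seed(seed, 1))
  events <- classify_events(search$trajectories,
                            lesion_interval_kbp = sim$lesion_interval_kbp)
  engaged <- events[events$mode != "none", , drop = FALSE]
  frac_direct <- fraction_with_sd(sum(engaged$mode == "direct"),
                                  max(nrow(engaged), 1))
  eff <- recognition_efficiency(events)
  res_naive <- tryCatch(fit_residence_time(events, sim$observation_window_s,
                                           method = "naive"),
                        smcurtain_error = function(e) NULL)
  res_mle <- fit_residence_time(events, sim$observation_window_s, method = "mle")

  # --- diffusion -----------------------------------------------------------
  dcfg <- sim_config(diffusion_um2_s = sim$diffusion_um2_s,
                     localization_sigma_kbp = sim$localization_sigma_kbp,
                     frame_interval_s = sim$frame_interval_s,
                     n_frames = cfg_all$diffusion$n_frames,
                     salt_mM = sim$salt_mM)
  tracks <- lapply(seq_len(cfg_all$diffusion$n_tracks), function(i)
    simulate_sliding_trajectory(dcfg, track_id = sprintf("slide%03d", i),
                                seed = split_seed(seed, 100 + i)))
  d_est <- estimate_D_tracks(tracks, fit_lags = cfg_all$diffusion$fit_lags,
                             extension = sim$extension_um_per_kbp,
                             seed = split_seed(seed, 2))
  disp <- displacement_gaussian(tracks, lag = 1)

  # --- positions -----------------------------------------------------------
  snap <- do.call(simulate_curtain_snapshot,
                  c(list(cfg = sim), cfg_all$snapshot,
                    list(seed = split_seed(seed, 3))))
  hist <- build_histogram(snap$position_kbp, L = sim$dna_length_kbp,
                          seed = split_seed(seed, 4))
  peak <- fit_peak(hist)
  enrich <- lesion_enrichment(snap$position_kbp, L = sim$dna_length_kbp)

  # --- equilibria ----------------------------------------------------------
  eq <- do.call(equilibrium_params, cfg_all$equilibria)
  tit <- simulate_titration(ladder_nM = cfg_all$titration$ladder_nM,
                            dna_total_nM = cfg_all$titration$dna_total_nM,
                            kd_nM = eq$kd_U_cpd_nM,
                            noise_sd = cfg_all$titration$noise_sd,
                            seed = split_seed(seed, 5))
  kd_fit <- fit_kd(tit)
  folds <- enhancement_fold(eq, "undamaged")

  report <- list(
    seed = seed,
    search = list(
      n_molecules = nrow(events),
      n_engaged = nrow(engaged),
      fraction_direct = frac_direct,
      efficiency_percent = eff$efficiency_percent,
      bypass_histogram = as.list(stats::setNames(as.integer(eff$bypass_histogram),
                                                 names(eff$bypass_histogram))),
      residence_naive_s = if (is.null(res_naive)) NULL else res_naive$tau_s,
      residence_mle_s = res_mle$tau_s,
      residence_mle_se = res_mle$se
    ),
    diffusion = list(
      D_um2_s = d_est$D_um2_s, se_um2_s = d_est$se_um2_s,
      n_tracks = d_est$n_tracks,
      displacement_center_kbp = disp$center,
      displacement_center_se = disp$center_se
    ),
    positions = list(
      peak_center_kbp = peak$center_kbp,
      peak_center_se = peak$center_se,
      peak_sigma_kbp = peak$sigma_kbp,
      lesion_enrichment_fold = enrich,
      n_events = attr(hist, "n_total")
    ),
    equilibria = list(
      kd_fit_nM = kd_fit$kd_nM, kd_fit_se = kd_fit$se,
      fold_U_undamaged = folds$fold_U, fold_X_undamaged = folds$fold_X
    )
  )
  class(report) <- "smcurtain_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(cfg_all, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.smcurtain_report <- function(x, ...) {
  cat("smcurtain pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  search: %d molecules, %d engaged; direct fraction %.2f +/- %.2f; efficiency %.1f%%\n",
              x$search$n_molecules, x$search$n_engaged,
              x$search$fraction_direct$p_hat, x$search$fraction_direct$sd_binomial,
              x$search$efficiency_percent))
  cat(sprintf("  residence: naive %.0f s, censored MLE %.0f +/- %.0f s\n",
              x$search$residence_naive_s %||% NA, x$search$residence_mle_s,
              x$search$residence_mle_se))
  cat(sprintf("  diffusion: D = %.4f +/- %.4f um^2/s (%d tracks); displacement center %.3f kbp\n",
              x$diffusion$D_um2_s, x$diffusion$se_um2_s, x$diffusion$n_tracks,
              x$diffusion$displacement_center_kbp))
  cat(sprintf("  positions: peak %.1f +/- %.1f kbp, enrichment %.2f-fold (n = %d)\n",
              x$positions$peak_center_kbp, x$positions$peak_center_se,
              x$positions$lesion_enrichment_fold, x$positions$n_events))
  cat(sprintf("  equilibria: fitted Kd %.2f +/- %.2f nM; fold U %.2f, fold X %.2f\n",
              x$equilibria$kd_fit_nM, x$equilibria$kd_fit_se,
              x$equilibria$fold_U_undamaged, x$equilibria$fold_X_undamaged))
  invisible(x)
}
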