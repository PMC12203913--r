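#' Construct a titration series
#'
#' Per-lane species fractions from a protein titration against a fixed DNA
#' concentration, as quantified from a gel shift: each lane (one protein
#' concentration) carries fractions of the DNA species present (`free`, `1x`,
#' optionally `2x` and `cobind`) that sum to 1.
#'
#' @param protein_concs_nM Protein concentration ladder, nM.
#' @param dna_total_nM Total DNA concentration, nM.
#' @param band_fractions Matrix or data frame, one row per lane, one column
#'   per species; rows must sum to 1 within `tol`.
#' @param noise_sd Multiplicative noise sd used to generate the series (0 for
#'   noise-free), recorded for provenance.
#' @param tol Tolerance on the row sums.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(protein_concs_nM, dna_total_nM, band_fractions,
                             noise_sd = 0, tol = 1e-6) {
  band_fractions <- as.matrix(band_fractions)
  if (any(protein_concs_nM < 0) || dna_total_nM < 0)
    smc_abort("concentrations must be nonnegative", "invalid_config")
  if (nrow(band_fractions) != length(protein_concs_nM))
    smc_abort("one row of band fractions per lane is required", "invalid_config")
  if (any(band_fractions < -tol) ||
      any(abs(rowSums(band_fractions) - 1) > max(tol, 1e-6)))
    smc_abort("per-lane band fractions must be nonnegative and sum to 1",
              "invalid_config")
  structure(list(protein_concs_nM = as.numeric(protein_concs_nM),
                 dna_total_nM = dna_total_nM,
                 band_fractions = band_fractions,
                 noise_sd = noise_sd),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series: %d lanes, DNA %.3g nM, species: %s\n",
              length(x$protein_concs_nM), x$dna_total_nM,
              paste(colnames(x$band_fractions), collapse = ", ")))
  invisible(x)
}

# Normalize a titration_series or data.frame to conc/fraction_bound columns
as_titration_df <- function(series) {
  if (inherits(series, "titration_series")) {
    bound <- 1 - series$band_fractions[, "free"]
    df <- data.frame(conc_nM = series$protein_concs_nM, fraction_bound = bound)
    attr(df, "dna_total_nM") <- series$dna_total_nM
    return(df)
  }
  df <- as.data.frame(series)
  if (!all(c("conc_nM", "fraction_bound") %in% names(df)))
    smc_abort("need columns conc_nM and fraction_bound", "schema")
  df
}

#' Simulate an EMSA-style titration
#'
#' Expected per-lane species fractions are computed from the equilibrium
#' model — the exact single-site depletion solution ([bound_fraction()]) when
#' `kd_nM` is given, or the full coupled solver ([solve_ux()]) when an
#' [equilibrium_params()] object is given (the ladder then varies total U) —
#' and multiplicative Gaussian noise is applied per band before renormalizing
#' each lane.
#'
#' @param ladder_nM Protein concentration ladder, nM. The default is a
#'   standard 8-point gel-shift ladder (0, 3, 5, 10, 15, 20, 30, 50 nM).
#' @param dna_total_nM Total DNA per lane, nM (default 4).
#' @param kd_nM Single-site dissociation constant (simple one-protein mode).
#' @param params Optional [equilibrium_params()] for the coupled mode.
#' @param substrate Substrate passed to [solve_ux()] in coupled mode.
#' @param noise_sd Multiplicative noise sd on each band fraction.
#' @param seed Integer seed or `NULL`.
#' @return A [titration_series()].
#' @export
#' @examples
#' ts <- simulate_titration(kd_nM = 5, noise_sd = 0)
#' ts$band_fractions
simulate_titration <- function(ladder_nM = c(0, 3, 5, 10, 15, 20, 30, 50),
                               dna_total_nM = 4, kd_nM = NULL, params = NULL,
                               substrate = "cpd", noise_sd = 0, seed = NULL) {
  if (noise_sd < 0)
    smc_abort("noise_sd must be nonnegative", "invalid_config")
  if (any(ladder_nM < 0))
    smc_abort("ladder concentrations must be nonnegative", "invalid_config")
  if (is.null(kd_nM) == is.null(params))
    smc_abort("give exactly one of kd_nM or params", "invalid_config")
  seed_if(seed)
  if (!is.null(kd_nM)) {
    fb <- bound_fraction(ladder_nM, dna_total_nM, kd_nM)
    frac <- cbind(free = 1 - fb, `1x` = fb)
  } else {
    frac <- t(vapply(ladder_nM, function(u) {
      p <- params
      p$totals["U"] <- u
      p$totals["D"] <- dna_total_nM
      st <- solve_ux(p, substrate)
      cx <- st$complexes
      tot <- dna_total_nM
      c(free = unname(st$free["D"] / tot),
        `1x` = unname(cx["UD"] / tot),
        `2x` = unname(cx["U2D"] / tot),
        cobind = unname((cx["XD"] + cx["UXD"]) / tot))
    }, numeric(4)))
  }
  if (noise_sd > 0) {
    noisy <- frac * matrix(pmax(1 + stats::rnorm(length(frac), 0, noise_sd), 0),
                           nrow = nrow(frac))
    frac <- noisy / rowSums(noisy)
  }
  titration_series(ladder_nM, dna_total_nM, frac, noise_sd = noise_sd)
}
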