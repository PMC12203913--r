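#' Simulate a curtain binding-position snapshot
#'
#' Positions of bound molecules across a field of stretched DNA molecules:
#' a fraction `specific_fraction` of events is placed uniformly within the
#' lesion interval and the remainder uniformly along the whole DNA, then all
#' positions are convolved with Gaussian localization noise and clipped to
#' the DNA.
#'
#' @param cfg A [sim_config()]; supplies DNA length, lesion interval, and the
#'   default localization noise.
#' @param n_events Number of binding events (>= 1).
#' @param specific_fraction Fraction of lesion-specific events, in `[0, 1]`.
#' @param localization_sigma_kbp Localization noise sd; defaults to the value
#'   in `cfg`.
#' @param seed Integer seed; defaults to `cfg$rng_seed`.
#' @return Object of class `curtain_snapshot`: a data frame with columns
#'   `dna_id` and `position_kbp`, with the DNA length and lesion interval as
#'   attributes.
#' @export
#' @examples
#' cfg <- sim_config(rng_seed = 3)
#' snap <- simulate_curtain_snapshot(cfg, 200, specific_fraction = 0.6)
#' head(snap)
simulate_curtain_snapshot <- function(cfg, n_events, specific_fraction,
                                      localization_sigma_kbp = cfg$localization_sigma_kbp,
                                      seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is_scalar_number(n_events) || n_events < 1)
    smc_abort("n_events must be >= 1", "invalid_config")
  if (!is_scalar_number(specific_fraction) ||
      specific_fraction < 0 || specific_fraction > 1)
    smc_abort("specific_fraction must lie in [0, 1]", "invalid_config")
  seed_if(seed)
  n_events <- as.integer(n_events)
  L <- cfg$dna_length_kbp
  lo <- cfg$lesion_interval_kbp[1]
  hi <- cfg$lesion_interval_kbp[2]
  specific <- stats::runif(n_events) < specific_fraction
  pos <- ifelse(specific, stats::runif(n_events, lo, hi),
                stats::runif(n_events, 0, L))
  if (localization_sigma_kbp > 0)
    pos <- pos + stats::rnorm(n_events, 0, localization_sigma_kbp)
  pos <- pmin(pmax(pos, 0), L)
  out <- data.frame(dna_id = sprintf("dna%04d", seq_len(n_events)),
                    position_kbp = pos, specific = specific,
                    stringsAsFactors = FALSE)
  structure(out, class = c("curtain_snapshot", "data.frame"),
            dna_length_kbp = L, lesion_interval_kbp = c(lo, hi),
            localization_sigma_kbp = localization_sigma_kbp)
}
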