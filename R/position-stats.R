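#' Binding-position histogram with percentile bootstrap intervals
#'
#' Fixed-width binning of binding positions along the DNA with per-bin
#' percentile bootstrap confidence intervals (default 70%, i.e. the 15th and
#' 85th percentiles — the interval convention used for curtain position
#' histograms). Bootstrapping resamples positions with replacement;
#' since binning is deterministic this is realized exactly (and much faster)
#' as multinomial resampling of the observed bin counts.
#'
#' @param positions_kbp Binding positions, kbp, within `[0, L]`.
#' @param bin_width_kbp Bin width (default 1 kbp, one pixel).
#' @param L DNA length in kbp (default the 48.502 kbp lambda genome).
#' @param n_boot Bootstrap resamples (>= 100; default 1000).
#' @param ci_level Confidence level (default 0.70).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `position_histogram`: data frame with `bin_lo`,
#'   `bin_hi`, `mid`, `count`, `ci_lo`, `ci_hi`; attributes `n_total`,
#'   `ci_level`.
#' @export
#' @examples
#' h <- build_histogram(runif(200, 0, 48.5), seed = 1)
#' head(h)
build_histogram <- function(positions_kbp, bin_width_kbp = 1, L = 48.502,
                            n_boot = 1000, ci_level = 0.70, seed = NULL) {
  if (!length(positions_kbp))
    smc_abort("no positions", "insufficient_data")
  if (any(positions_kbp < 0 | positions_kbp > L))
    smc_abort("positions must lie in [0, L]", "invalid_argument")
  if (n_boot < 100)
    smc_abort("n_boot must be >= 100", "invalid_argument")
  if (ci_level <= 0 || ci_level >= 1)
    smc_abort("ci_level must lie in (0, 1)", "invalid_argument")
  breaks <- seq(0, L, by = bin_width_kbp)
  if (breaks[length(breaks)] < L) breaks <- c(breaks, L)
  idx <- findInterval(positions_kbp, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(breaks) - 1L
  counts <- tabulate(idx, nbins = nb)
  n <- length(positions_kbp)
  seed_if(seed)
  boot <- stats::rmultinom(n_boot, n, counts / n)  # == resample + re-bin
  alpha <- (1 - ci_level) / 2
  qs <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    count = counts, ci_lo = qs[1, ], ci_hi = qs[2, ])
  structure(out, class = c("position_histogram", "data.frame"),
            n_total = n, ci_level = ci_level)
}

#' Gaussian peak fit to a position histogram
#'
#' Least-squares fit of a single Gaussian plus a flat baseline to the bin
#' counts. The baseline term absorbs the uniform nonspecific background of a
#' curtain snapshot; set `baseline = FALSE` for a pure single-Gaussian fit.
#'
#' @param hist A [build_histogram()] result.
#' @param baseline Include a flat baseline term (default `TRUE`).
#' @return Object of class `peak_fit`: `center_kbp`, `sigma_kbp`, `amplitude`,
#'   `baseline`, `center_se`, and the fit object.
#' @export
fit_peak <- function(hist, baseline = TRUE) {
  stopifnot(inherits(hist, "position_histogram"))
  if (sum(hist$count > 0) < 5L)
    smc_abort("need >= 5 bins with nonzero counts", "insufficient_data")
  df <- data.frame(x = hist$mid, y = hist$count)
  med <- stats::median(df$y)
  # sub-bin peak widths are not resolvable; bounding sigma at half a bin also
  # keeps near-delta histograms from degenerating the fit
  s_min <- (hist$bin_hi[1] - hist$bin_lo[1]) / 2
  start <- list(A = max(df$y) - med, mu = df$x[which.max(df$y)],
                s = max(2, s_min))
  fit <- try(
    if (baseline) {
      minpack.lm::nlsLM(y ~ b + A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                        start = c(start, b = med),
                        lower = c(0, min(df$x), s_min, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                        start = start, lower = c(0, min(df$x), s_min),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }, silent = TRUE)
  if (inherits(fit, "try-error"))
    smc_abort(paste("peak fit did not converge:", attr(fit, "condition")$message),
              "fit_error")
  cf <- summary(fit)$coefficients
  structure(list(center_kbp = unname(cf["mu", "Estimate"]),
                 sigma_kbp = abs(unname(cf["s", "Estimate"])),
                 amplitude = unname(cf["A", "Estimate"]),
                 baseline = if (baseline) unname(cf["b", "Estimate"]) else 0,
                 center_se = unname(cf["mu", "Std. Error"]),
                 fit = fit),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Gaussian peak at %.2f +/- %.2f kbp (sigma %.2f, amplitude %.3g, baseline %.3g)\n",
              x$center_kbp, x$center_se, x$sigma_kbp, x$amplitude, x$baseline))
  invisible(x)
}

#' Per-length enrichment of binding in a window
#'
#' Molecule counts inside the window and outside it, each divided by the
#' corresponding DNA length: `(n_in / w) / (n_out / (L - w))`. A fold of 1
#' means no preference; an empty outside gives `Inf` with a warning.
#'
#' @param positions_kbp Binding positions, kbp.
#' @param window_kbp Window of interest (default `c(32, 36)` kbp, the
#'   four-pixel window around the lesion cassette).
#' @param L DNA length, kbp.
#' @return Fold enrichment (numeric scalar).
#' @export
#' @examples
#' lesion_enrichment(c(runif(40, 32, 36), runif(60, 0, 48.5)), L = 48.5)
lesion_enrichment <- function(positions_kbp, window_kbp = c(32, 36), L = 48.502) {
  if (!length(positions_kbp))
    smc_abort("no positions", "insufficient_data")
  if (window_kbp[1] < 0 || window_kbp[2] > L || window_kbp[1] >= window_kbp[2])
    smc_abort("window must be an increasing pair within [0, L]", "invalid_argument")
  w <- diff(window_kbp)
  n_in <- sum(positions_kbp >= window_kbp[1] & positions_kbp <= window_kbp[2])
  n_out <- length(positions_kbp) - n_in
  if (n_out == 0L) {
    warning("no molecules outside the window; enrichment is infinite")
    return(Inf)
  }
  (n_in / w) / (n_out / (L - w))
}

#' Binding-enhancement fold between two conditions
#'
#' Ratio of bound-molecule counts with and without a co-factor. When
#' per-field-of-view replicate counts are supplied, a bootstrap standard
#' error of the ratio of means is attached.
#'
#' @param n_with,n_without Total bound molecules in each condition
#'   (`n_without > 0`), or vectors of per-field replicates.
#' @param n_boot Bootstrap resamples for the replicate case.
#' @param seed Integer seed for the bootstrap.
#' @return List with `fold` and `se` (`NA` without replicates).
#' @export
#' @examples
#' binding_enhancement(55, 10)$fold
binding_enhancement <- function(n_with, n_without, n_boot = 1000, seed = NULL) {
  if (sum(n_without) == 0)
    smc_abort("fold undefined: no molecules in the reference condition",
              "undefined_fold")
  fold <- sum(n_with) / sum(n_without)
  se <- NA_real_
  if (length(n_with) > 1L && length(n_without) > 1L) {
    seed_if(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      a <- sample(n_with, length(n_with), replace = TRUE)
      b <- sample(n_without, length(n_without), replace = TRUE)
      if (sum(b) == 0) NA_real_ else sum(a) / sum(b)
    }, numeric(1))
    se <- stats::sd(boot, na.rm = TRUE)
  }
  list(fold = fold, se = se)
}

#' Expected photolesion burden of a genome
#'
#' Expected number of photolesions given a lesion density per kbp and a
#' genome size in bp: `density * genome_bp / 1000`. At the commonly cited
#' density of ~0.027 lesions/kbp per 1 J/m^2 of UV-C, a 3e9 bp genome carries
#' ~8.1e4 lesions.
#'
#' @param density_per_kbp Photolesion density, lesions per kbp (>= 0).
#' @param genome_bp Genome size in bp (>= 0).
#' @return Expected lesion count.
#' @export
#' @examples
#' lesion_burden(0.027, 3e9)
lesion_burden <- function(density_per_kbp, genome_bp) {
  if (density_per_kbp < 0 || genome_bp < 0)
    smc_abort("inputs must be nonnegative", "invalid_argument")
  density_per_kbp * genome_bp / 1000
}
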