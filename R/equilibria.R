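#' Dissociation constants and totals for the two-protein/DNA equilibrium
#'
#' Parameter set for the coupled mass-action system of a damage sensor "U"
#' (binds the lesion tightly, undamaged DNA weakly), a second sensor "X"
#' (binds undamaged DNA tightly but barely discriminates the lesion), their
#' solution complex "UX", and a DNA substrate "D". Default affinities are the
#' package's reference hierarchy: Kd(U, lesion) = 5 nM, Kd(U, undamaged) =
#' 26 nM, Kd(X, lesion) = 7 nM, Kd(X, undamaged) = 9 nM.
#'
#' @param kd_U_cpd_nM,kd_U_und_nM Kd of protein U for lesion-containing and
#'   undamaged DNA, nM.
#' @param kd_X_cpd_nM,kd_X_und_nM Kd of protein X for the two substrates, nM.
#' @param kd_UX_protein_nM Kd of the U:X protein-protein complex, nM. The
#'   complex shows minimal dissociation experimentally, so the default is
#'   tight (1 nM).
#' @param kd_UXdna_policy How the UX complex binds DNA: `"tighter"` (default;
#'   the complex adopts the Kd of whichever subunit binds that substrate more
#'   tightly) or a positive number giving the complex-DNA Kd in nM directly.
#' @param kd_U2_nM Optional Kd for a second U loading onto a U-bound DNA
#'   (species U2D); `NULL` (default) disables the species.
#' @param totals Named vector of total concentrations in nM for `U`, `X`, `D`.
#' @return Object of class `equilibrium_params`.
#' @export
equilibrium_params <- function(kd_U_cpd_nM = 5, kd_U_und_nM = 26,
                               kd_X_cpd_nM = 7, kd_X_und_nM = 9,
                               kd_UX_protein_nM = 1,
                               kd_UXdna_policy = "tighter",
                               kd_U2_nM = NULL,
                               totals = c(U = 2, X = 2, D = 10)) {
  kds <- c(kd_U_cpd_nM, kd_U_und_nM, kd_X_cpd_nM, kd_X_und_nM, kd_UX_protein_nM)
  if (any(!is.finite(kds) & !is.infinite(kds)) || any(kds <= 0))
    smc_abort("all Kd values must be positive", "invalid_config")
  if (is.numeric(kd_UXdna_policy) && kd_UXdna_policy <= 0)
    smc_abort("numeric kd_UXdna_policy must be positive", "invalid_config")
  if (!is.null(kd_U2_nM) && kd_U2_nM <= 0)
    smc_abort("kd_U2_nM must be positive", "invalid_config")
  if (!all(c("U", "X", "D") %in% names(totals)) || any(totals < 0))
    smc_abort("totals must name nonnegative U, X, D", "invalid_config")
  structure(list(
    kd_U_cpd_nM = kd_U_cpd_nM, kd_U_und_nM = kd_U_und_nM,
    kd_X_cpd_nM = kd_X_cpd_nM, kd_X_und_nM = kd_X_und_nM,
    kd_UX_protein_nM = kd_UX_protein_nM,
    kd_UXdna_policy = kd_UXdna_policy,
    kd_U2_nM = kd_U2_nM,
    totals = totals[c("U", "X", "D")]
  ), class = "equilibrium_params")
}

# Resolve substrate-specific Kds (U-DNA, X-DNA, UX-DNA) for "cpd"/"undamaged"
resolve_kds <- function(params, substrate = c("cpd", "undamaged")) {
  substrate <- match.arg(substrate)
  kU <- if (substrate == "cpd") params$kd_U_cpd_nM else params$kd_U_und_nM
  kX <- if (substrate == "cpd") params$kd_X_cpd_nM else params$kd_X_und_nM
  kUX <- if (identical(params$kd_UXdna_policy, "tighter")) min(kU, kX)
         else as.numeric(params$kd_UXdna_policy)
  list(kU = kU, kX = kX, kUXd = kUX, kP = params$kd_UX_protein_nM,
       kU2 = params$kd_U2_nM)
}

#' Bound fraction of DNA for single-site binding with ligand depletion
#'
#' Exact solution of `P + D <-> PD` at total concentrations comparable to the
#' Kd, where the free-ligand approximation fails: with `S = P + D + Kd`, the
#' complex is `C = (S - sqrt(S^2 - 4 P D)) / 2` and the bound fraction `C / D`.
#'
#' @param p_tot_nM Total protein concentration(s), nM (vectorized).
#' @param d_tot_nM Total DNA concentration, nM.
#' @param kd_nM Dissociation constant, nM.
#' @return Fraction of DNA bound, in `[0, 1]`.
#' @export
#' @examples
#' bound_fraction(10, 4, 5) # 0.603
bound_fraction <- function(p_tot_nM, d_tot_nM, kd_nM) {
  if (any(p_tot_nM < 0) || d_tot_nM < 0 || kd_nM <= 0)
    smc_abort("concentrations must be nonnegative and kd positive", "invalid_argument")
  if (d_tot_nM == 0)
    smc_abort("bound fraction undefined at zero DNA", "undefined_fraction")
  s <- p_tot_nM + d_tot_nM + kd_nM
  cplx <- (s - sqrt(pmax(s^2 - 4 * p_tot_nM * d_tot_nM, 0))) / 2
  pmin(pmax(cplx / d_tot_nM, 0), 1)
}

#' Fit a dissociation constant to a titration
#'
#' Least-squares fit of the depletion-corrected single-site isotherm
#' ([bound_fraction()]) to bound-fraction measurements over a protein ladder.
#' A Hill/Langmuir approximation is deliberately not used because the DNA
#' concentration (4-10 nM in gel-shift assays) is comparable to the Kd.
#'
#' @param series A [titration_series()] or a data frame with columns `conc_nM`
#'   and `fraction_bound`.
#' @param dna_total_nM Total DNA concentration; taken from `series` when absent.
#' @return List with `kd_nM`, `se`, and the `fit` object.
#' @export
fit_kd <- function(series, dna_total_nM = NULL) {
  df <- as_titration_df(series)
  if (is.null(dna_total_nM)) dna_total_nM <- attr(df, "dna_total_nM")
  if (is.null(dna_total_nM))
    smc_abort("dna_total_nM is required", "invalid_argument")
  if (nrow(df) < 4L)
    smc_abort("need at least 4 concentrations", "invalid_argument")
  fb <- df$fraction_bound
  if (max(fb) - min(fb) < 0.15 || max(fb) < 0.2 || min(fb[df$conc_nM > 0]) > 0.85)
    smc_abort("titration is flat or saturated only; Kd not identifiable",
              "non_identifiable")
  start_kd <- stats::approx(fb, df$conc_nM, xout = 0.5, ties = mean, rule = 2)$y
  if (!is.finite(start_kd) || start_kd <= 0) start_kd <- stats::median(df$conc_nM[df$conc_nM > 0])
  fit <- minpack.lm::nlsLM(
    fraction_bound ~ bound_fraction(conc_nM, dna_total_nM, kd),
    data = df, start = list(kd = start_kd),
    lower = 1e-6, control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- summary(fit)$coefficients
  list(kd_nM = unname(est["kd", "Estimate"]), se = unname(est["kd", "Std. Error"]),
       fit = fit)
}

# ---- coupled UX equilibrium -------------------------------------------------

# Species totals implied by free concentrations (u, x, d) and Kds.
ux_totals <- function(u, x, d, k) {
  inv_kp <- if (is.infinite(k$kP)) 0 else 1 / k$kP
  UX <- u * x * inv_kp
  UD <- u * d / k$kU
  XD <- x * d / k$kX
  UXD <- UX * d / k$kUXd
  U2D <- if (is.null(k$kU2)) 0 else UD * u / k$kU2
  list(
    complexes = c(UX = UX, UD = UD, XD = XD, UXD = UXD, U2D = U2D),
    U = u + UX + UD + UXD + 2 * U2D,
    X = x + UX + XD + UXD,
    D = d + UD + XD + UXD + U2D
  )
}

#' Solve the coupled two-protein/DNA binding equilibrium
#'
#' Mass-action equilibrium of `U + X <-> UX`, `U + D <-> UD`, `X + D <-> XD`,
#' `UX + D <-> UXD` (and optionally `UD + U <-> U2D`) at fixed totals: the
#' quantitative form of the model in which the solution complex of the two
#' damage sensors loads U onto DNA through the tighter DNA affinity of its X
#' subunit. Solved by a damped Newton iteration on log free concentrations
#' with an analytic Jacobian.
#'
#' @param params An [equilibrium_params()].
#' @param substrate `"cpd"` or `"undamaged"`.
#' @param tol Relative mass-balance tolerance (default 1e-12; must reach 1e-9
#'   or the solver errors).
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `species_state`: free concentrations, complex
#'   concentrations, and the relative mass-balance residual.
#' @export
#' @examples
#' p <- equilibrium_params(totals = c(U = 2, X = 2, D = 10))
#' solve_ux(p, "undamaged")
solve_ux <- function(params, substrate = c("cpd", "undamaged"),
                     tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(params, "equilibrium_params"))
  substrate <- match.arg(substrate)
  k <- resolve_kds(params, substrate)
  tot <- params$totals
  scale <- pmax(tot, 1e-12)

  active <- tot > 0
  if (!any(active)) {
    st <- ux_totals(0, 0, 0, k)
    return(new_species_state(c(U = 0, X = 0, D = 0), st$complexes, 0, substrate))
  }

  # Newton on l = log(free) for active species; inactive species fixed at 0.
  lfree <- log(pmax(tot, 1e-9) / 2)
  lfree[!active] <- -Inf
  resid_of <- function(lf) {
    cc <- unname(exp(lf))
    st <- ux_totals(cc[1], cc[2], cc[3], k)
    (c(st$U, st$X, st$D) - tot) / scale
  }
  r <- resid_of(lfree)
  for (it in seq_len(max_iter)) {
    if (max(abs(r[active])) < tol) break
    cc <- unname(exp(lfree))
    u <- cc[1]; x <- cc[2]; d <- cc[3]
    st <- ux_totals(u, x, d, k)
    cx <- st$complexes
    # d(total_i)/d(log free_j): free term + sum over complexes of nu_i*nu_j*C
    nuU <- c(UX = 1, UD = 1, XD = 0, UXD = 1, U2D = 2)
    nuX <- c(UX = 1, UD = 0, XD = 1, UXD = 1, U2D = 0)
    nuD <- c(UX = 0, UD = 1, XD = 1, UXD = 1, U2D = 1)
    J <- rbind(
      c(u + sum(nuU * nuU * cx), sum(nuU * nuX * cx), sum(nuU * nuD * cx)),
      c(sum(nuX * nuU * cx), x + sum(nuX * nuX * cx), sum(nuX * nuD * cx)),
      c(sum(nuD * nuU * cx), sum(nuD * nuX * cx), d + sum(nuD * nuD * cx))
    ) / scale
    ia <- which(active)
    step <- rep(0, 3)
    sol <- try(solve(J[ia, ia, drop = FALSE], -r[ia]), silent = TRUE)
    if (inherits(sol, "try-error"))
      smc_abort("singular Jacobian in equilibrium solve", "solver_error")
    step[ia] <- pmin(pmax(sol, -4), 4)  # cap step in log units
    lam <- 1
    repeat {
      r_new <- resid_of(lfree + lam * step)
      if (max(abs(r_new[active])) < max(abs(r[active])) || lam < 1e-6) break
      lam <- lam / 2
    }
    lfree <- lfree + lam * step
    r <- r_new
  }
  if (max(abs(r[active])) > 1e-9)
    smc_abort(sprintf("equilibrium solver did not converge (residual %.3g)",
                      max(abs(r[active]))), "solver_error")
  cc <- unname(exp(lfree))
  st <- ux_totals(cc[1], cc[2], cc[3], k)
  new_species_state(c(U = cc[1], X = cc[2], D = cc[3]), st$complexes,
                    max(abs(r[active])), substrate)
}

new_species_state <- function(free, complexes, residual, substrate) {
  structure(list(free = free, complexes = complexes,
                 residual = residual, substrate = substrate),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat(sprintf("species_state (%s DNA), relative residual %.2g\n",
              x$substrate, x$residual))
  cat("  free (nM):     ", paste(sprintf("%s=%.4g", names(x$free), x$free),
                                 collapse = "  "), "\n")
  cat("  complexes (nM):", paste(sprintf("%s=%.4g", names(x$complexes), x$complexes),
                                 collapse = "  "), "\n")
  invisible(x)
}

# DNA-associated amount of each protein in a solved state
dna_bound_protein <- function(state) {
  cx <- state$complexes
  c(U = unname(cx["UD"] + cx["UXD"] + 2 * cx["U2D"]),
    X = unname(cx["XD"] + cx["UXD"]))
}

#' Binding-enhancement fold from the coupled equilibrium
#'
#' Ratio of DNA-associated U with protein X present to that with X absent,
#' all other totals equal; the companion ratio for X (with/without U) is
#' returned to expose the asymmetry of the model (X loads U onto DNA, but U
#' does not load X).
#'
#' @inheritParams solve_ux
#' @return List with `fold_U`, `fold_X`, and the two solved states.
#' @export
enhancement_fold <- function(params, substrate = c("cpd", "undamaged")) {
  substrate <- match.arg(substrate)
  both <- solve_ux(params, substrate)
  p_noX <- params; p_noX$totals["X"] <- 0
  p_noU <- params; p_noU$totals["U"] <- 0
  alone_U <- solve_ux(p_noX, substrate)
  alone_X <- solve_ux(p_noU, substrate)
  bU <- dna_bound_protein(both); b0U <- dna_bound_protein(alone_U)
  b0X <- dna_bound_protein(alone_X)
  list(fold_U = unname(bU["U"] / b0U["U"]),
       fold_X = unname(bU["X"] / b0X["X"]),
       state_both = both, state_U_alone = alone_U, state_X_alone = alone_X)
}

#' Steady-state affinity fit for surface plasmon resonance
#'
#' Fits the steady-state binding response `RU(C) = RU_max * C / (Kd + C)` to
#' equilibrium response units versus analyte concentration. Because the
#' analyte is in vast excess over the immobilized ligand, no depletion
#' correction is applied here (unlike [fit_kd()]).
#'
#' @param conc_nM Analyte concentrations, nM (>= 4 values).
#' @param ru Steady-state response units at each concentration.
#' @return List with `kd_nM`, `ru_max`, standard errors and the fit; a warning
#'   of class `smcurtain_wide_ci` is signalled when the data do not approach
#'   saturation (fitted Kd beyond the ladder).
#' @export
spr_steady_state <- function(conc_nM, ru) {
  if (length(conc_nM) < 4L || length(ru) != length(conc_nM))
    smc_abort("need >= 4 matched concentrations and responses", "invalid_argument")
  df <- data.frame(conc = conc_nM, ru = ru)
  # fit in (initial slope, 1/Kd): numerically stable when the ladder does not
  # approach saturation (1/Kd then converges to the 0 boundary instead of the
  # rmax/Kd ridge diverging)
  c1 <- df$conc[df$conc > 0][1]
  fit <- ls_fit(
    start = list(s0 = df$ru[df$conc == c1][1] / c1,
                 inv_kd = 1 / stats::median(conc_nM[conc_nM > 0])),
    resid_fn = function(p) df$ru - p$s0 * df$conc / (1 + p$inv_kd * df$conc),
    lower = c(0, 0), upper = c(Inf, Inf))
  s0 <- unname(fit$par["s0"]); s0_se <- unname(fit$se["s0"])
  ik <- unname(fit$par["inv_kd"]); ik_se <- unname(fit$se["inv_kd"])
  out <- list(kd_nM = 1 / ik, ru_max = s0 / ik,
              kd_se = ik_se / ik^2,                      # delta method
              ru_max_se = sqrt((s0_se / ik)^2 + (s0 * ik_se / ik^2)^2),
              fit = fit)
  if (!is.finite(out$kd_nM) || out$kd_nM > max(conc_nM)) {
    w <- simpleWarning("SPR ladder does not reach saturation; Kd confidence interval is wide")
    class(w) <- c("smcurtain_wide_ci", class(w))
    warning(w)
  }
  out
}
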