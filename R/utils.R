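# Internal utilities: classed error conditions, seed splitting, unit helpers.

smc_abort <- function(message, class) {
  cond <- structure(
    class = c(paste0("smcurtain_", class), "smcurtain_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

#' Derive a child seed from a base seed
#'
#' All randomness in smcurtain flows from a single integer seed. Operations
#' that need several independent streams (one per molecule, one per bootstrap,
#' ...) derive child seeds deterministically with this multiplicative-hash
#' scheme, so a whole simulated experiment is reproducible from one number.
#'
#' @param seed Base integer seed, or `NULL` for "do not seed".
#' @param k Nonnegative integer stream index.
#' @return An integer seed below 2^31 - 1, or `NULL` if `seed` is `NULL`.
#' @export
#' @examples
#' split_seed(1L, 0:3)
split_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483647 * 48271 + 104729 * (as.double(k) + 1)) %% 2147483647)
}

# set.seed only when a seed was supplied
seed_if <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# um^2/s -> kbp^2/s given the extension (um of imaged DNA per kbp)
um2_to_kbp2 <- function(d_um2_s, extension_um_per_kbp) {
  d_um2_s / extension_um_per_kbp^2
}

kbp2_to_um2 <- function(d_kbp2_s, extension_um_per_kbp) {
  d_kbp2_s * extension_um_per_kbp^2
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bounded Levenberg-Marquardt least squares via nls.lm, with standard errors
# from the (pseudo-inverted) Gauss-Newton Hessian. Used where the histogram
# being fitted can be degenerate enough that stats::nlsModel's rank check
# rejects an otherwise converged solution.
ls_fit <- function(start, resid_fn, lower, upper, maxiter = 500) {
  out <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = maxiter))
  par <- unlist(out$par)
  r <- resid_fn(out$par)
  dof <- max(length(r) - length(par), 1L)
  s2 <- sum(r^2) / dof
  sv <- svd(out$hessian)
  dinv <- ifelse(sv$d > 1e-12 * max(sv$d, 1e-300), 1 / sv$d, 0)
  covm <- sv$v %*% (dinv * t(sv$u)) * s2
  list(par = par, se = stats::setNames(sqrt(pmax(diag(covm), 0)), names(par)),
       residuals = r, deviance = sum(r^2), info = out$info)
}
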