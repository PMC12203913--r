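#' Construct a kymograph image
#'
#' A kymograph is a position-versus-time intensity array for one DNA molecule:
#' rows are frames, columns are pixels along the DNA.
#'
#' @param intensity Nonnegative numeric matrix, `(frames x pixels)`.
#' @param pixel_size_kbp Pixel size along the DNA (default 1 kbp/pixel).
#' @param frame_interval_s Frame interval, seconds.
#' @param psf_sigma_px Point-spread-function sigma in pixels.
#' @param background_level Expected background counts per pixel.
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(intensity, pixel_size_kbp = 1, frame_interval_s = 0.1,
                      psf_sigma_px = 1, background_level = 0) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0) || nrow(intensity) < 1L || ncol(intensity) < 1L)
    smc_abort("intensity must be a nonnegative matrix of size >= 1x1",
              "invalid_config")
  structure(list(intensity = intensity, pixel_size_kbp = pixel_size_kbp,
                 frame_interval_s = frame_interval_s,
                 psf_sigma_px = psf_sigma_px,
                 background_level = background_level),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d pixels, %.3g kbp/px, %.3g s/frame\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_kbp,
              x$frame_interval_s))
  invisible(x)
}

#' Render a kymograph from a trajectory
#'
#' Each frame places a Gaussian spot (pixel-integrated point-spread function)
#' at the particle's sub-pixel position, adds a uniform background, and draws
#' Poisson photon noise.
#'
#' @param traj A [curtain_track()].
#' @param psf_sigma_px PSF sigma in pixels (> 0).
#' @param photons_per_frame Expected photons in the spot per frame (> 0).
#' @param background Expected background counts per pixel per frame.
#' @param pixel_size_kbp Pixel size (default 1 kbp).
#' @param noise Draw Poisson noise (`TRUE`, default) or return expected counts.
#' @param seed Integer seed or `NULL`.
#' @return A [kymograph()].
#' @export
render_kymograph <- function(traj, psf_sigma_px = 1, photons_per_frame = 500,
                             background = 2, pixel_size_kbp = 1,
                             noise = TRUE, seed = NULL) {
  stopifnot(inherits(traj, "curtain_track"))
  if (psf_sigma_px <= 0 || photons_per_frame <= 0)
    smc_abort("psf_sigma_px and photons_per_frame must be positive",
              "invalid_argument")
  L <- traj$dna_length_kbp
  if (is.na(L)) L <- max(traj$positions_kbp) + 3 * pixel_size_kbp
  if (any(traj$positions_kbp < 0 | traj$positions_kbp > L))
    smc_abort("trajectory leaves [0, L]; cannot render", "invalid_argument")
  n_px <- as.integer(ceiling(L / pixel_size_kbp))
  seed_if(seed)
  edges <- 0:n_px
  centers_u <- traj$positions_kbp / pixel_size_kbp  # continuous pixel coords
  expected <- t(vapply(centers_u, function(u) {
    frac <- diff(stats::pnorm(edges, mean = u, sd = psf_sigma_px))
    photons_per_frame * frac + background
  }, numeric(n_px)))
  img <- if (noise) {
    matrix(stats::rpois(length(expected), lambda = expected),
           nrow = nrow(expected))
  } else expected
  dt <- if (length(traj$times_s) > 1) traj$times_s[2] - traj$times_s[1] else 0.1
  kymograph(img, pixel_size_kbp = pixel_size_kbp, frame_interval_s = dt,
            psf_sigma_px = psf_sigma_px, background_level = background)
}

# Sub-pixel localization: least-squares Gaussian fit on a 7-px window around
# the peak; falls back to the intensity-weighted centroid if the fit fails.
fit_spot <- function(counts, peak_px, psf_sigma_px, background) {
  n_px <- length(counts)
  win <- max(1L, peak_px - 3L):min(n_px, peak_px + 3L)
  x <- win - 0.5  # pixel-center coordinates
  y <- counts[win]
  fit <- try(minpack.lm::nlsLM(
    y ~ b + A * exp(-(x - c0)^2 / (2 * s^2)),
    data = data.frame(x = x, y = y),
    start = list(A = max(y) - background, c0 = peak_px - 0.5,
                 s = psf_sigma_px, b = background),
    lower = c(0, min(x) - 1, 0.2, 0),
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    c0 <- stats::coef(fit)[["c0"]]
    # a genuine spot fit stays near its peak pixel; runaway fits fall back
    if (abs(c0 - (peak_px - 0.5)) <= 1.5) return(c0)
  }
  w <- pmax(y - background, 0)
  if (sum(w) == 0) return(peak_px - 0.5)
  sum(w * x) / sum(w)
}

#' Track particles in a kymograph
#'
#' Per-frame spot detection (local maxima above a Poisson threshold,
#' `background + 4 sqrt(background)`, ties broken toward the lower pixel
#' index) with sub-pixel localization by a least-squares 1D Gaussian fit on a
#' 7-pixel window, followed by greedy nearest-neighbour frame-to-frame linking
#' with a hard jump limit and gap closing over at most one missing frame —
#' appropriate for the single-particle, low-density curtain regime.
#'
#' @param img A [kymograph()].
#' @param max_jump_px Maximum per-frame displacement for linking (>= 1,
#'   default 3).
#' @param min_track_len Minimum detections per reported track (default 5).
#' @param threshold Detection threshold in counts; default
#'   `background + 4 * sqrt(background)`.
#' @return List of [curtain_track()] with positions in kbp; empty list when
#'   nothing is detected.
#' @export
track_kymograph <- function(img, max_jump_px = 3, min_track_len = 5,
                            threshold = NULL) {
  stopifnot(inherits(img, "kymograph"))
  if (max_jump_px < 1)
    smc_abort("max_jump_px must be >= 1", "invalid_argument")
  bg <- img$background_level
  if (is.null(threshold)) threshold <- bg + 4 * sqrt(max(bg, 1))
  mat <- img$intensity
  nf <- nrow(mat); n_px <- ncol(mat)

  detections <- lapply(seq_len(nf), function(f) {
    row <- mat[f, ]
    left <- c(-Inf, row[-n_px])
    right <- c(row[-1], -Inf)
    # strict vs left, >= vs right: ties resolve to the lower pixel index
    peaks <- which(row >= threshold & row > left & row >= right)
    if (!length(peaks)) return(numeric(0))
    # suppress shoulder peaks within 3 px of a brighter one, fit brightest
    # first, and drop fits landing within 2.5 px of an accepted spot
    keep <- peaks[order(-row[peaks])]
    sel <- c()
    for (p in keep) if (!length(sel) || min(abs(sel - p)) > 3) sel <- c(sel, p)
    pos <- c()
    for (p in sel) {
      cand <- fit_spot(row, p, img$psf_sigma_px, bg)
      if (!length(pos) || min(abs(pos - cand)) > 2.5) pos <- c(pos, cand)
    }
    sort(pos)
  })

  # greedy nearest-neighbour linking with <= 1-frame gap closing
  tracks <- list()   # each: list(frames, pos, last_frame)
  active <- integer(0)
  for (f in seq_len(nf)) {
    det <- detections[[f]]
    if (length(active)) {
      lastpos <- vapply(tracks[active], function(t) t$pos[length(t$pos)], numeric(1))
      used_det <- rep(FALSE, length(det))
      used_tr <- rep(FALSE, length(active))
      if (length(det)) {
        dist <- abs(outer(lastpos, det, "-"))
        repeat {
          dmin <- suppressWarnings(min(dist[!used_tr, !used_det, drop = FALSE]))
          if (!is.finite(dmin) || dmin > max_jump_px) break
          idx <- which(dist == dmin & outer(!used_tr, !used_det, "&"),
                       arr.ind = TRUE)[1, , drop = TRUE]
          ti <- idx[1]; di <- idx[2]
          tr <- tracks[[active[ti]]]
          tr$frames <- c(tr$frames, f)
          tr$pos <- c(tr$pos, det[di])
          tr$last_frame <- f
          tracks[[active[ti]]] <- tr
          used_tr[ti] <- TRUE
          used_det[di] <- TRUE
          dist[ti, ] <- Inf
          dist[, di] <- Inf
          if (all(used_tr) || all(used_det)) break
        }
      }
      det <- det[!used_det]
      # drop tracks that missed more than one consecutive frame
      active <- active[vapply(tracks[active], function(t) f - t$last_frame <= 1,
                              logical(1))]
    }
    for (d in det) {
      tracks[[length(tracks) + 1L]] <- list(frames = f, pos = d, last_frame = f)
      active <- c(active, length(tracks))
    }
  }

  dt <- img$frame_interval_s
  out <- list()
  for (i in seq_along(tracks)) {
    t <- tracks[[i]]
    if (length(t$frames) < min_track_len) next
    # fill 1-frame gaps by linear interpolation onto a uniform grid
    grid <- seq(min(t$frames), max(t$frames))
    pos <- stats::approx(t$frames, t$pos, xout = grid)$y
    out[[length(out) + 1L]] <- curtain_track(
      sprintf("kymo%03d", length(out) + 1L),
      times_s = (grid - 1L) * dt,
      positions_kbp = pos * img$pixel_size_kbp,
      sigma_loc_kbp = NA_real_,
      censored_end = max(t$frames) == nf
    )
  }
  out
}
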