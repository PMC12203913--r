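# Shared fixture builders for the test suite; everything is generated in code.

# Hand-built MSD curve (bypasses compute_msd) for fitting tests
make_msd <- function(lag_s, msd_kbp2, n_pairs = rep(100L, length(lag_s))) {
  structure(data.frame(lag_frames = seq_along(lag_s), lag_s = lag_s,
                       msd_kbp2 = msd_kbp2, n_pairs = n_pairs),
            class = c("msd_curve", "data.frame"))
}

# A track that sits at `at` for all frames
stationary_track <- function(at, n = 100, dt = 0.1, L = 48.502, id = "stat") {
  curtain_track(id, times_s = (seq_len(n) - 1) * dt,
                positions_kbp = rep(at, n), dna_length_kbp = L,
                censored_end = TRUE)
}

# A crafted path from position waypoints (one frame per waypoint)
path_track <- function(positions, dt = 1, L = 48.502, id = "path",
                       censored_end = FALSE) {
  curtain_track(id, times_s = (seq_along(positions) - 1) * dt,
                positions_kbp = positions, dna_length_kbp = L,
                censored_end = censored_end)
}

# Closed-form expected recognition efficiency for geometric bypasses
geom_efficiency <- function(q) -q * log(q) / (1 - q) * 100

# Brute-force single-site bound fraction by root search on the mass balance
bound_fraction_oracle <- function(p_tot, d_tot, kd) {
  f <- function(c) (p_tot - c) * (d_tot - c) / kd - c
  stats::uniroot(f, c(0, min(p_tot, d_tot)), tol = 1e-12)$root / d_tot
}
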