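# Shared fixtures and independent brute-force oracles.

# O(N^2) biased autocovariance, the oracle for the FFT estimator.
acf_brute <- function(x, k_max) {
  n <- length(x)
  vapply(0:k_max, function(k) sum(x[seq_len(n - k)] * x[(1 + k):n]) / n,
         numeric(1))
}

# Exhaustive pair check, the oracle for hbond_count().
hbond_brute <- function(donors, hydrogens, acceptors, d_cut = 0.35,
                        angle_cut = 30) {
  cnt <- 0L
  for (i in seq_len(nrow(donors))) {
    hd <- hydrogens[i, ] - donors[i, ]
    for (j in seq_len(nrow(acceptors))) {
      da <- acceptors[j, ] - donors[i, ]
      dn <- sqrt(sum(da^2))
      if (dn > d_cut || dn == 0) next
      ang <- acos(min(1, max(-1, sum(hd * da) / sqrt(sum(hd^2)) / dn))) * 180 / pi
      if (ang <= angle_cut) cnt <- cnt + 1L
    }
  }
  cnt
}

# Umbrella windows sampled from an arbitrary generating potential.
make_windows <- function(potential, zmax = 1, spacing = 0.1, k = 3000,
                         n = 2000, seed = 1, dt = 1) {
  z0s <- seq(-zmax, zmax, by = spacing)
  lapply(seq_along(z0s), function(i)
    sample_umbrella_window(potential, z0s[i], k = k, n = n,
                           seed = seed * 1000 + i, dt = dt,
                           z_range = c(-zmax - 0.5, zmax + 0.5)))
}

# RMS deviation from a generating potential after optimal additive shift,
# restricted to the window-center span.
wham_rms <- function(profile, potential, span) {
  sel <- profile$z >= -span & profile$z <= span
  d <- profile$G[sel] - potential(profile$z[sel])
  d <- d - mean(d)
  sqrt(mean(d^2))
}

# Isotropic random unit vectors.
iso_vectors <- function(n, seed) {
  with_seed2(seed, {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
  })
}

with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
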