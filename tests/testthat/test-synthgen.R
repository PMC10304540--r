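test_that("desorption barrier of a PMF family is affine in chain length", {
  # nominal parameter: exact affine relation
  fam <- make_pmf_family(n_set = c(4, 8, 12, 16), chain_coupling = c(10, 2.5))
  nominal <- vapply(fam, `[[`, numeric(1), "desorption_nominal")
  expect_equal(unname(nominal), c(20, 30, 40, 50))

  # numerically extracted barrier regresses to the coupling within 1%
  zg <- seq(-4, 4, by = 0.001)
  barrier <- vapply(fam, function(m) m$water_level - min(eval_pmf(m, zg)), numeric(1))
  fit <- stats::lm(barrier ~ c(4, 8, 12, 16))
  expect_lt(abs(stats::coef(fit)[2] / 2.5 - 1), 0.01)
  expect_lt(abs(stats::coef(fit)[1] / 10 - 1), 0.01)

  # degenerate coupling: identical barriers for every chain length
  flat <- make_pmf_family(n_set = c(4, 8, 16), chain_coupling = c(30, 0))
  b0 <- vapply(flat, function(m) m$water_level - min(eval_pmf(m, zg)), numeric(1))
  expect_equal(unname(b0), rep(b0[[1]], 3))
})

test_that("PMF model validates its inputs and honors the center dip", {
  expect_error(make_pmf_model(minima = data.frame(z_min = 1.7, depth = 30, width = 0)),
               "width")
  expect_error(make_pmf_model(z_range = c(0.5, 4)), "both leaflets")
  expect_error(make_pmf_model(minima = data.frame(z_min = 5, depth = 30, width = 0.25)),
               "contain all minima")

  # without a dip there is no stationary point at z = 0 other than the
  # barrier top (shallow wells so the center is a genuine maximum)
  shallow <- data.frame(z_min = 1.7, depth = 10, width = 0.25)
  m <- make_pmf_model(minima = shallow, center_barrier = 25, center_dip = 0)
  zg <- seq(-0.3, 0.3, by = 1e-3)
  g <- eval_pmf(m, zg)
  expect_equal(zg[which.max(g)], 0)
  expect_lt(max(g[abs(zg) > 0.01]), g[zg == 0])

  # with a dip, z = 0 becomes a local minimum between two flanking maxima
  md <- make_pmf_model(minima = shallow, center_barrier = 25, center_dip = 5)
  gd <- eval_pmf(md, zg)
  expect_lt(gd[zg == 0], min(gd[abs(abs(zg) - 0.25) < 1e-9]))
})

test_that("umbrella window sampling matches the Gaussian closed forms", {
  # flat potential: sd -> sqrt(RT/k) within 2% at n = 1e5
  w <- sample_umbrella_window(function(z) 0 * z, z0 = 0, k = 3000, n = 1e5,
                              seed = 11, z_range = c(-1, 1))
  expect_lt(abs(stats::sd(w$samples) / sqrt(rt_kj() / 3000) - 1), 0.02)
  expect_true(all(w$samples >= -1 & w$samples <= 1))

  # normality of the flat-potential window (moment check)
  x <- scale(w$samples)
  expect_lt(abs(mean(x^3)), 0.05)
  expect_lt(abs(mean(x^4) - 3), 0.1)

  # linear potential m*z tilts the mean to z0 - m/k
  wl <- sample_umbrella_window(function(z) 10 * z, z0 = 1, k = 3000, n = 1e5,
                               seed = 12, z_range = c(0, 2))
  expect_lt(abs(mean(wl$samples) - (1 - 10 / 3000)), 3e-4)

  # determinism: same seed reproduces the series exactly
  w2 <- sample_umbrella_window(function(z) 0 * z, z0 = 0, k = 3000, n = 1000,
                               seed = 7, z_range = c(-1, 1))
  w3 <- sample_umbrella_window(function(z) 0 * z, z0 = 0, k = 3000, n = 1000,
                               seed = 7, z_range = c(-1, 1))
  expect_identical(w2$samples, w3$samples)

  expect_error(sample_umbrella_window(function(z) 0 * z, 0, k = -1, n = 10,
                                      seed = 1, z_range = c(-1, 1)), "k must be")
  expect_error(sample_umbrella_window(function(z) 0 * z, 0, k = 10, n = 10,
                                      seed = 1, z_range = c(1, 1)), "degenerate")
})

test_that("OU force series has the prescribed stationary statistics", {
  spec <- ou_spec(variance = 100, tau = 1, dt = 0.1, n_samples = 2e5, seed = 3)
  s <- gen_force_series(spec)
  expect_equal(s$xi_true, 100 / rt_kj())
  expect_lt(abs(stats::var(s$force) / 100 - 1), 0.05)
  # empirical lag-ACF follows variance * exp(-t/tau)
  a <- autocorrelation(s, max_lag = 3)
  expect_lt(max(abs(a$acf / (100 * exp(-a$lag_ps)) - 1)[1:21]), 0.1)

  # two seeds: different series, same stationary variance
  s2 <- gen_force_series(ou_spec(100, 1, 0.1, 2e5, seed = 4))
  expect_false(identical(s$force, s2$force))
  expect_lt(abs(stats::var(s2$force) / stats::var(s$force) - 1), 0.1)

  # degenerate variance: constant zero series
  z <- gen_force_series(ou_spec(0, 1, 0.1, 100, seed = 1))
  expect_identical(z$force, rep(0, 100))

  # too-coarse sampling is flagged
  expect_warning(gen_force_series(ou_spec(1, tau = 0.5, dt = 1, 100, seed = 1)),
                 "coarse")
})

test_that("membrane frame carries composition and target order parameter", {
  fr <- gen_membrane_frame(n_lipid = 144, x_chol = 0.5, n_water = 5824,
                           a_box = 29, v_box = 314.8, target_scd = 0.3, seed = 5)
  expect_identical(sum(fr$species == "PL"), 72L)
  expect_identical(sum(fr$species == "CHOL"), 72L)
  s <- order_parameter(fr$chain_vectors, fr$normal)
  expect_equal(mean(s), 0.3, tolerance = 1e-12)

  # target_scd = 1: all vectors parallel to the normal
  f1 <- gen_membrane_frame(10, 0, 100, 5, 50, target_scd = 1, seed = 1)
  expect_equal(unname(f1$chain_vectors[, 3]), rep(1, nrow(f1$chain_vectors)))

  # target_scd = 0: vectors at the magic angle 54.74 deg
  f0 <- gen_membrane_frame(10, 0, 100, 5, 50, target_scd = 0, seed = 1)
  ang <- acos(f0$chain_vectors[, 3]) * 180 / pi
  expect_equal(unname(ang), rep(54.7356, length(ang)), tolerance = 1e-4)

  expect_error(gen_membrane_frame(10, 0, 100, 5, 50, target_scd = 1.2, seed = 1),
               "target_scd")
  expect_error(gen_membrane_frame(10, 0, 1e5, 5, 50, target_scd = 0, seed = 1),
               "water volume")
})
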