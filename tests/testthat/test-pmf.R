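test_that("window histograms conserve counts and flag coverage gaps", {
  w1 <- umbrella_window(0, 3000, rep(0.005, 50))
  h1 <- histogram_windows(list(w1), bin_width = 0.01)
  expect_identical(sum(h1$counts), 50L)
  expect_identical(max(h1$counts), 50L)  # all samples in one bin

  win <- make_windows(function(z) 0 * z, zmax = 0.3, n = 500, seed = 2)
  h <- histogram_windows(win)
  expect_identical(sum(h$counts), sum(vapply(win, function(w) length(w$samples), integer(1))))

  # two disjoint windows: the uncovered interval is reported
  wa <- umbrella_window(-1, 3000, stats::rnorm(200, -1, 0.03))
  wb <- umbrella_window(1, 3000, stats::rnorm(200, 1, 0.03))
  hg <- histogram_windows(list(wa, wb))
  expect_gt(nrow(hg$gaps), 0)
  expect_true(any(hg$gaps$z_lo < 0 & hg$gaps$z_hi > 0))
  expect_error(wham_solve(list(wa, wb)), "gap")
})

test_that("WHAM recovers a known generating potential", {
  kappa <- 10
  pot <- function(z) 0.5 * kappa * z^2
  win <- make_windows(pot, zmax = 1, n = 60000, seed = 31)
  prof <- wham_solve(win)
  expect_lt(wham_rms(prof, pot, span = 1), 0.2)
  expect_identical(prof$reference, "bilayer_center")
  expect_lt(abs(prof$G[which.min(abs(prof$z))]), 1e-9)

  # single flat window: profile flat within 3x the split-half noise
  w <- list(sample_umbrella_window(function(z) 0 * z, 0, 3000, 20000, seed = 9,
                                   z_range = c(-1, 1)))
  pf <- wham_solve(w)
  err <- split_half_uncertainty(w)
  dev <- abs(pf$G - mean(pf$G))
  expect_lt(stats::median(dev), 3 * stats::median(err$values) + 1e-6)

  # unreachable tolerance exercises the failure path with its residual
  expect_error(wham_solve(w, tol = 0, max_iter = 50), "did not converge")
})

test_that("reference changes are pure additive shifts", {
  z <- seq(-4, 4, by = 0.01)
  g <- eval_pmf(make_pmf_model(water_level = 30, center_barrier = 20), z)
  prof <- free_energy_profile(z, g, reference = "bilayer_center")

  pm <- set_reference(prof, "global_minimum")
  expect_equal(min(pm$G), 0)
  pw <- set_reference(prof, "bulk_water")
  expect_equal(mean(pw$G[abs(pw$z) >= 3.5]), 0, tolerance = 1e-12)
  # plateau value 30: shift down by 30
  expect_equal(pw$meta$shift, 30, tolerance = 1e-3)

  # any two conventions differ by one constant; differences preserved exactly
  d <- pm$G - pw$G
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  expect_equal(diff(pm$G), diff(pw$G), tolerance = 1e-12)

  # barriers are invariant under re-referencing
  b1 <- extract_barriers(pm)
  b2 <- extract_barriers(pw)
  expect_equal(b1$dG_desorption, b2$dG_desorption)
  expect_equal(b1$dG_translocation, b2$dG_translocation)

  short <- free_energy_profile(seq(-1, 1, 0.01), rep(0, 201))
  expect_error(set_reference(short, "bulk_water"), "plateau")
})

test_that("symmetrization averages leaflets, cancels odd parts, is idempotent", {
  z <- seq(-2, 2, by = 0.01)
  # odd profile: symmetrizes to zero
  podd <- free_energy_profile(z, z)
  expect_equal(symmetrize(podd)$G, rep(0, length(symmetrize(podd)$z)))

  # already symmetric: unchanged (on its own grid)
  psym <- free_energy_profile(z, z^2)
  s1 <- symmetrize(psym)
  expect_equal(stats::approx(s1$z, s1$G, xout = z)$y, z^2, tolerance = 1e-12)

  # idempotence and mean preservation
  s2 <- symmetrize(s1)
  expect_equal(s2$G, s1$G)
  expect_equal(mean(s1$G), mean(psym$G), tolerance = 1e-12)
  expect_equal(s1$G, rev(s1$G))
})

test_that("split-half uncertainty shrinks with more sampling", {
  pot <- function(z) 4 * z^2
  wins <- make_windows(pot, zmax = 0.5, n = 1000, seed = 77)
  u <- split_half_uncertainty(wins)
  expect_true(all(u$values >= 0))

  # identical halves by construction give zero everywhere
  w0 <- umbrella_window(0, 3000, rep(c(-0.01, 0.01), 100))
  dup <- list(umbrella_window(0, 3000, c(w0$samples, w0$samples)))
  u0 <- split_half_uncertainty(dup)
  expect_equal(max(u0$values), 0, tolerance = 1e-9)

  expect_error(split_half_uncertainty(list(umbrella_window(0, 3000, 0.1))),
               "too short")

  # quadrupling n lowers the median uncertainty (sign test over 10 seeds)
  wins_better <- 0L
  for (s in 1:10) {
    ua <- split_half_uncertainty(make_windows(pot, zmax = 0.5, n = 500, seed = 100 + s))
    ub <- split_half_uncertainty(make_windows(pot, zmax = 0.5, n = 2000, seed = 200 + s))
    if (stats::median(ub$values) < stats::median(ua$values)) wins_better <- wins_better + 1L
  }
  expect_gte(wins_better, 9L)
})

test_that("convergence scan truncates data as specified", {
  pot <- function(z) 2 * z^2
  wins <- make_windows(pot, zmax = 0.4, n = 1000, seed = 55, dt = 1)

  # scheme i at full length reproduces the plain solve exactly
  sc1 <- convergence_scan(wins, "i", step = 250, z_bulk = 0.35)
  plain <- wham_solve(wins)
  expect_equal(sc1$profiles[[length(sc1$profiles)]]$G, plain$G)
  expect_identical(length(sc1$t), 4L)

  # scheme iii window count = floor((total - span)/step) + 1
  sc3 <- convergence_scan(wins, "iii", step = 100, analysis_span = 500, z_bulk = 0.35)
  expect_identical(length(sc3$t), as.integer(floor((1000 - 500) / 100) + 1))
  expect_error(convergence_scan(wins, "iii", step = 100, analysis_span = 2000),
               "longer than the data")

  # stationary windows: schemes agree within 2x split-half noise
  noise <- stats::median(split_half_uncertainty(wins)$values)
  sc2 <- convergence_scan(wins, "ii", step = 500, z_bulk = 0.35)
  p_half <- sc2$profiles[[2]]   # last half of the data
  common <- intersect(signif(plain$z, 12), signif(p_half$z, 12))
  d <- plain$G[match(common, signif(plain$z, 12))] -
       p_half$G[match(common, signif(p_half$z, 12))]
  d <- d - mean(d)
  expect_lt(stats::median(abs(d)), 2 * noise + 1e-6)
})

test_that("barrier extraction reads out the expected heights", {
  z <- seq(-4, 4, by = 0.01)
  m <- make_pmf_model(water_level = 30, center_barrier = 20)
  prof <- set_reference(free_energy_profile(z, eval_pmf(m, z)), "global_minimum")
  b <- extract_barriers(prof)
  expect_false(b$degenerate)
  expect_equal(abs(b$z_eq), 1.7, tolerance = 0.05)
  expect_equal(b$dG_translocation, 20, tolerance = 0.3)
  expect_equal(b$dG_desorption, 30, tolerance = 0.3)
  expect_identical(nrow(b$per_leaflet), 2L)
  expect_equal(abs(b$per_leaflet$z_eq), c(1.7, 1.7), tolerance = 0.05)

  # flat profile: degenerate, zero barriers
  bf <- extract_barriers(free_energy_profile(z, rep(1, length(z))))
  expect_true(bf$degenerate)
  expect_equal(bf$dG_desorption, 0)
  expect_equal(bf$dG_translocation, 0)

  # monotone profile: degenerate, barriers against the endpoints
  bm <- extract_barriers(free_energy_profile(z, 2 * z))
  expect_true(bm$degenerate)

  expect_error(extract_barriers(free_energy_profile(seq(-1, 1, 0.01), rep(0, 201))),
               "z_bulk")
})
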