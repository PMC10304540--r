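rt <- rt_kj()

test_that("partition profile is the Boltzmann factor of the PMF", {
  z <- seq(-1, 1, by = 0.1)
  p0 <- partition_profile(free_energy_profile(z, rep(0, length(z))))
  expect_equal(p0$values, rep(1, length(z)))
  pk <- partition_profile(free_energy_profile(z, rep(rt, length(z))))
  expect_equal(pk$values, rep(exp(-1), length(z)), tolerance = 1e-12)
  pm <- partition_profile(free_energy_profile(z, rep(-rt, length(z))))
  expect_equal(pm$values, rep(exp(1), length(z)), tolerance = 1e-12)
  # overflow-safe for extreme free energies
  px <- partition_profile(free_energy_profile(z, rep(-1e5, length(z))))
  expect_true(all(is.finite(px$values)))
})

test_that("local resistance is exp(G/RT)/D with the documented identities", {
  z <- seq(-2, 2, by = 0.01)
  g0 <- free_energy_profile(z, rep(0, length(z)))
  r0 <- local_resistance(g0, 1e-3)
  expect_equal(r0$values, rep(1000, length(z)))

  # adding RT ln 10 multiplies the resistance by 10 everywhere
  g1 <- free_energy_profile(z, rep(rt * log(10), length(z)))
  r1 <- local_resistance(g1, 1e-3)
  expect_equal(r1$values, 10 * r0$values, tolerance = 1e-12)

  # flat D: the resistance extremes co-locate with the PMF extremes
  m <- make_pmf_model(water_level = 30, center_barrier = 40)
  gm <- free_energy_profile(z, eval_pmf(m, z))
  rm_ <- local_resistance(gm, 1e-3)
  expect_identical(rm_$z[which.max(rm_$values)], gm$z[which.max(gm$G)])
  expect_equal(abs(rm_$z[which.min(rm_$values)]), abs(gm$z[which.min(gm$G)]))

  # D interpolated onto the overlap of the two grids
  dprof <- depth_profile(seq(-1, 1, by = 0.5), rep(1e-3, 5), "diffusion")
  ro <- local_resistance(g0, dprof)
  expect_true(all(ro$z >= -1 & ro$z <= 1))
  far <- depth_profile(c(5, 6), c(1e-3, 1e-3), "diffusion")
  expect_error(local_resistance(g0, far), "overlap")
})

test_that("cumulative resistance integrates monotonically to R_total", {
  z <- seq(-2, 2, by = 0.01)
  rho <- depth_profile(z, rep(1000, length(z)), "resistance_density")
  cum <- cumulative_resistance(rho)
  expect_equal(cum$meta$R_total, 4000)
  expect_true(all(diff(cum$values) >= 0))
  expect_equal(cum$values[1], 0)
  expect_error(cumulative_resistance(rho, bounds = c(1, -1)), "inverted")

  # plateaus of the cumulative curve coincide with the low-resistance decile
  v <- 1000 * exp(5 * sin(pi * z))    # strongly varying density
  cum2 <- cumulative_resistance(depth_profile(z, v, "resistance_density"))
  slope <- diff(cum2$values) / diff(cum2$z)
  low <- v[-length(v)] <= stats::quantile(v, 0.1)
  expect_lt(max(slope[low]), 0.05 * max(slope))
})

test_that("permeability matches flat and square-barrier closed forms", {
  z <- seq(-2, 2, by = 2e-4)
  g0 <- free_energy_profile(z, rep(0, length(z)), reference = "bulk_water")
  pr <- permeability(g0, 1e-3, reference = "bulk_water", z_bulk = 1.9)
  expect_equal(pr$P_cm_per_s, 25, tolerance = 1e-9)   # P = D/d
  expect_equal(pr$R_total_ps_per_nm, 4000, tolerance = 1e-9)
  expect_equal(1 / pr$R_total_ps_per_nm * 1e5, pr$P_cm_per_s)

  gsq <- free_energy_profile(z, ifelse(abs(z) <= 0.5, rt * log(100), 0),
                             reference = "bulk_water")
  psq <- permeability(gsq, 1e-3, reference = "bulk_water", z_bulk = 1.9)
  expect_equal(psq$P_cm_per_s, 1e5 / 103000, tolerance = 1e-3)
})

test_that("re-referencing rescales P by a pure exponential", {
  z <- seq(-4, 4, by = 0.005)
  m <- make_pmf_model(water_level = 0, center_barrier = 25,
                      chain_coupling = c(10, 2.5), n_carbons = 12)
  g <- free_energy_profile(z, eval_pmf(m, z))
  pw <- permeability(g, 1e-3, reference = "bulk_water")
  pm <- permeability(g, 1e-3, reference = "global_minimum")
  gap <- set_reference(g, "global_minimum")$meta$shift -
         set_reference(g, "bulk_water")$meta$shift
  expect_equal(pm$P_cm_per_s, pw$P_cm_per_s * exp(gap / rt), tolerance = 1e-12)
  expect_match(paste(pm$notes, collapse = " "), "water")
})

test_that("grid refinement leaves P stable for smooth profiles", {
  m <- make_pmf_model(water_level = 0, center_barrier = 25)
  p_at <- function(h) {
    z <- seq(-4, 4, by = h)
    permeability(free_energy_profile(z, eval_pmf(m, z)), 1e-3,
                 reference = "bulk_water")$P_cm_per_s
  }
  expect_lt(abs(p_at(0.01) / p_at(0.02) - 1), 0.005)
})

test_that("regime classification follows the barrier ordering", {
  z <- seq(-4, 4, by = 0.01)
  mk <- function(des, tr) extract_barriers(set_reference(
    free_energy_profile(z, eval_pmf(make_pmf_model(water_level = des,
                                                   minima = data.frame(z_min = 1.7, depth = des, width = 0.25),
                                                   center_barrier = tr), z)),
    "global_minimum"))
  expect_identical(classify_regime(mk(30, 20), margin = 1), "desorption_limited")
  expect_identical(classify_regime(mk(20, 30), margin = 1), "translocation_limited")
  expect_identical(classify_regime(mk(25, 25), margin = 1), "indeterminate")
  # degenerate barriers propagate to indeterminate
  bf <- extract_barriers(free_energy_profile(z, rep(0, length(z))))
  expect_identical(classify_regime(bf), "indeterminate")
})

test_that("resistance decomposition partitions R_total exactly", {
  z <- seq(-2, 2, by = 0.01)
  cum <- cumulative_resistance(depth_profile(z, rep(1000, length(z)),
                                             "resistance_density"))
  d <- decompose_resistance(cum, c(-1, 1))
  expect_equal(unname(d$fractions), c(0.25, 0.5, 0.25), tolerance = 1e-9)
  expect_equal(d$entrance + d$center + d$desorption, d$R_total, tolerance = 1e-12)

  # all resistance concentrated at the center
  v <- 1e-6 + 1e6 * exp(-z^2 / (2 * 0.05^2))
  dc <- decompose_resistance(cumulative_resistance(
    depth_profile(z, v, "resistance_density")), c(-1, 1))
  expect_gt(dc$fractions[["center"]], 0.999)

  expect_error(decompose_resistance(cum, c(-1, 2)), "symmetric")
  expect_error(decompose_resistance(cum, c(-3, 3)), "outside")
})
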