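#' Parametric free-energy surface for an amphiphile in a bilayer
#'
#' Builds an evaluable model of a solute's free energy G(z) along the bilayer
#' normal, with the features typical of amphiphile PMFs: a flat water plateau
#' on both sides, an interface minimum in each leaflet (Gaussian well), a
#' translocation barrier at the bilayer midplane, and optionally a narrow
#' local minimum exactly at the center (as seen for several solutes in
#' cholesterol-rich bilayers). The desorption barrier (water plateau minus
#' the interface minimum) can be coupled affinely to the alkyl-chain carbon
#' count, which is how a homologous amphiphile family is emulated: the polar
#' group (and hence the translocation barrier) is shared, while the
#' hydrophobic driving force grows linearly with chain length.
#'
#' `center_barrier` is defined as the translocation barrier, i.e. the value
#' of G at z = 0 minus the value at the interface minimum; the amplitude of
#' the central Gaussian is solved internally so that this holds exactly at
#' the nominal minimum depth.
#'
#' @param water_level Free energy of the bulk-water plateau, kJ/mol.
#' @param minima data.frame with columns `z_min` (nm, > 0 for the upper
#'   leaflet), `depth` (kJ/mol, depth of the well below `water_level`) and
#'   `width` (nm, Gaussian sigma). Mirrored into the lower leaflet unless
#'   `asymmetric = TRUE`.
#' @param center_barrier Translocation barrier G(0) - G(z_min), kJ/mol.
#' @param center_dip Depth (>= 0, kJ/mol) of an optional narrow local
#'   minimum at z = 0; 0 disables it.
#' @param z_range Numeric length-2, nm; must span both leaflets.
#' @param chain_coupling `c(intercept, slope)` in kJ/mol and kJ/mol per
#'   carbon: with `n_carbons`, the primary minimum depth is overridden to
#'   `intercept + slope * n_carbons`.
#' @param n_carbons Alkyl-chain carbon count (used with `chain_coupling`).
#' @param barrier_width Gaussian sigma of the central barrier, nm.
#' @param dip_width Gaussian sigma of the central dip, nm.
#' @param asymmetric If TRUE, `minima` rows are used exactly as given
#'   (both leaflets must be supplied explicitly).
#' @return An object of class `pmf_model`; evaluate with [eval_pmf()].
#' @seealso [make_pmf_family()], [sample_umbrella_window()]
#' @export
make_pmf_model <- function(water_level = 0,
                           minima = data.frame(z_min = 1.7, depth = 30, width = 0.25),
                           center_barrier = 25,
                           center_dip = 0,
                           z_range = c(-4, 4),
                           chain_coupling = NULL,
                           n_carbons = NULL,
                           barrier_width = 0.5,
                           dip_width = 0.15,
                           asymmetric = FALSE) {
  minima <- as.data.frame(minima)
  stopifnot(all(c("z_min", "depth", "width") %in% names(minima)), nrow(minima) >= 1L)
  if (any(minima$width <= 0)) stop("all well widths must be > 0")
  if (barrier_width <= 0 || dip_width <= 0) stop("barrier_width and dip_width must be > 0")
  if (length(z_range) != 2L || z_range[1] >= z_range[2])
    stop("z_range must be an increasing length-2 interval")
  if (z_range[1] >= 0 || z_range[2] <= 0)
    stop("z_range must span both leaflets (contain negative and positive z)")
  if (center_dip < 0) stop("center_dip must be >= 0")

  if (!is.null(chain_coupling)) {
    stopifnot(length(chain_coupling) == 2L)
    if (is.null(n_carbons)) stop("n_carbons is required when chain_coupling is given")
    minima$depth[1] <- chain_coupling[1] + chain_coupling[2] * n_carbons
  }
  if (any(minima$depth < 0)) stop("well depths must be >= 0")

  if (!asymmetric) {
    mirr <- minima[minima$z_min != 0, , drop = FALSE]
    mirr$z_min <- -mirr$z_min
    minima <- rbind(minima, mirr)
  }
  if (any(minima$z_min < z_range[1] | minima$z_min > z_range[2]))
    stop("z_range must contain all minima")

  # nominal desorption barrier = depth of the primary (deepest) well
  a_star <- max(minima$depth)

  # central Gaussian amplitude solving G(0) = water_level - a_star + center_barrier
  base0 <- water_level - sum(minima$depth * exp(-minima$z_min^2 / (2 * minima$width^2)))
  bump_amp <- (water_level - a_star + center_barrier) - base0 + center_dip

  structure(list(
    water_level = water_level, minima = minima,
    center_barrier = center_barrier, center_dip = center_dip,
    z_range = z_range, chain_coupling = chain_coupling, n_carbons = n_carbons,
    barrier_width = barrier_width, dip_width = dip_width,
    bump_amp = bump_amp, asymmetric = asymmetric,
    desorption_nominal = a_star, translocation_nominal = center_barrier
  ), class = "pmf_model")
}

#' Evaluate a PMF model
#'
#' @param model A `pmf_model` (or any function of z, used as-is).
#' @param z Depths in nm; must lie within the model's `z_range`.
#' @return G(z) in kJ/mol.
#' @export
eval_pmf <- function(model, z) {
  if (is.function(model)) return(model(z))
  stopifnot(inherits(model, "pmf_model"))
  if (any(z < model$z_range[1] - 1e-9 | z > model$z_range[2] + 1e-9))
    stop("z outside the model z_range")
  g <- rep(model$water_level, length(z))
  for (i in seq_len(nrow(model$minima))) {
    m <- model$minima[i, ]
    g <- g - m$depth * exp(-(z - m$z_min)^2 / (2 * m$width^2))
  }
  g <- g + model$bump_amp * exp(-z^2 / (2 * model$barrier_width^2))
  if (model$center_dip > 0)
    g <- g - model$center_dip * exp(-z^2 / (2 * model$dip_width^2))
  g
}

#' @export
print.pmf_model <- function(x, ...) {
  cat("PMF model: water level", x$water_level, "kJ/mol,",
      nrow(x$minima), "well(s), translocation barrier", x$translocation_nominal,
      "kJ/mol, desorption barrier", x$desorption_nominal, "kJ/mol\n")
  invisible(x)
}

#' Homologous family of PMF models
#'
#' One model per chain length, sharing all parameters except the desorption
#' barrier, which follows the affine chain coupling.
#'
#' @param n_set Integer vector of alkyl-chain carbon counts.
#' @param chain_coupling `c(intercept, slope)`, kJ/mol and kJ/mol per carbon.
#' @param ... Passed to [make_pmf_model()].
#' @return Named list of `pmf_model` objects ("C4", "C8", ...).
#' @export
make_pmf_family <- function(n_set = c(4, 8, 12, 16),
                            chain_coupling = c(10, 2.5), ...) {
  out <- lapply(n_set, function(n)
    make_pmf_model(chain_coupling = chain_coupling, n_carbons = n, ...))
  names(out) <- paste0("C", n_set)
  out
}

#' Umbrella window constructor
#'
#' A single biased window: harmonic restraint of force constant `k` centered
#' at `z0`, with the recorded reaction-coordinate samples.
#'
#' @param z0 Bias center, nm.
#' @param k Bias force constant, kJ mol^-1 nm^-2.
#' @param samples Reaction-coordinate time series, nm.
#' @param dt Sampling interval, ps.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(z0, k, samples, dt = 1) {
  if (!is.numeric(k) || k <= 0) stop("k must be > 0")
  if (length(samples) < 1L) stop("samples must be non-empty")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(z0 = z0, k = k, dt = dt, samples = as.numeric(samples)),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("Umbrella window: z0 = %g nm, k = %g kJ/mol/nm^2, n = %d, dt = %g ps\n",
              x$z0, x$k, length(x$samples), x$dt))
  invisible(x)
}

#' Draw Boltzmann-distributed samples from a biased umbrella window
#'
#' Samples the stationary distribution of a harmonically restrained window,
#' with density proportional to exp(-(G(z) + k/2 (z - z0)^2)/RT), by
#' inverse-CDF interpolation on a fine grid. This yields exact independent
#' stationary draws (no Markov-chain burn-in), which is what the downstream
#' WHAM estimator assumes.
#'
#' @param model A `pmf_model` or a plain function G(z) (kJ/mol).
#' @param z0 Bias center, nm.
#' @param k Bias force constant, kJ mol^-1 nm^-2 (the reference setup uses
#'   3000 kJ mol^-1 nm^-2 with windows every 0.1 nm).
#' @param n Number of samples.
#' @param temperature K.
#' @param seed RNG seed (required; same seed reproduces the series exactly).
#' @param dt Nominal sampling interval attached to the window, ps.
#' @param z_range Evaluation range, nm; defaults to the model's range.
#' @param grid_spacing Inverse-CDF grid spacing, nm.
#' @return An [umbrella_window()].
#' @examples
#' w <- sample_umbrella_window(function(z) 0 * z, z0 = 0, k = 3000,
#'                             n = 1000, seed = 1, z_range = c(-1, 1))
#' sd(w$samples)  # ~ sqrt(RT/k) = 0.0287 nm
#' @export
sample_umbrella_window <- function(model, z0, k, n, temperature = 298.15,
                                   seed, dt = 1, z_range = NULL,
                                   grid_spacing = 1e-3) {
  if (k <= 0) stop("k must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (is.null(z_range)) {
    if (!inherits(model, "pmf_model")) stop("z_range is required for a plain function")
    z_range <- model$z_range
  }
  if (z_range[1] >= z_range[2]) stop("degenerate z_range")
  rt <- rt_kj(temperature)
  zg <- seq(z_range[1], z_range[2], by = grid_spacing)
  e <- eval_pmf(model, zg) + 0.5 * k * (zg - z0)^2
  w <- exp(-(e - min(e)) / rt)
  dz <- diff(zg)
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * dz))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  u <- with_seed(seed, stats::runif(n))
  s <- stats::approx(cdf[keep], zg[keep], xout = u, rule = 2)$y
  out <- umbrella_window(z0 = z0, k = k, samples = s, dt = dt)
  out$seed <- seed
  out$temperature <- temperature
  out
}

#' Ornstein-Uhlenbeck specification for a restraint-force series
#'
#' @param variance Stationary variance of the force fluctuations,
#'   (kJ mol^-1 nm^-1)^2.
#' @param tau Correlation time, ps.
#' @param dt Sampling interval, ps.
#' @param n_samples Series length.
#' @param seed RNG seed.
#' @return Object of class `ou_spec`. The implied static friction is
#'   `variance * tau / RT` and the implied local diffusion coefficient
#'   `RT / xi = RT^2 / (variance * tau)`.
#' @export
ou_spec <- function(variance, tau, dt, n_samples, seed) {
  if (variance < 0) stop("variance must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(list(variance = variance, tau = tau, dt = dt,
                 n_samples = as.integer(n_samples), seed = seed),
            class = "ou_spec")
}

#' Force time-series container
#'
#' @param z0 Window depth, nm.
#' @param dt Sampling interval, ps.
#' @param force Instantaneous force samples, kJ mol^-1 nm^-1.
#' @export
force_series <- function(z0, dt, force) {
  if (dt <= 0) stop("dt must be > 0")
  if (length(force) < 1L) stop("force must be non-empty")
  structure(list(z0 = z0, dt = dt, force = as.numeric(force)),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("Force series: z0 = %g nm, n = %d, dt = %g ps\n",
              x$z0, length(x$force), x$dt))
  invisible(x)
}

#' Generate a stationary Ornstein-Uhlenbeck force-fluctuation series
#'
#' Exact discrete OU update with stationary initialization:
#' F[t+1] = rho F[t] + sqrt(variance (1 - rho^2)) eps, rho = exp(-dt/tau),
#' F[1] ~ N(0, sqrt(variance)). The resulting autocovariance is
#' variance * exp(-lag/tau), so the implied static friction is
#' xi = variance * tau / RT and the implied diffusion D = RT / xi.
#'
#' @param spec An [ou_spec()].
#' @param temperature K (only stored; the series itself is
#'   temperature-independent, the friction interpretation is not).
#' @param z0 Depth label attached to the series, nm.
#' @return A [force_series()] with `xi_true` and `d_true` in its attributes.
#' @export
gen_force_series <- function(spec, temperature = 298.15, z0 = 0) {
  stopifnot(inherits(spec, "ou_spec"))
  if (spec$dt >= spec$tau)
    warning("dt >= tau: sampling too coarse to resolve the force-ACF decay")
  n <- spec$n_samples
  if (spec$variance == 0) {
    f <- rep(0, n)
  } else {
    rho <- exp(-spec$dt / spec$tau)
    f <- with_seed(spec$seed, {
      x0 <- stats::rnorm(1, 0, sqrt(spec$variance))
      eps <- if (n > 1) stats::rnorm(n - 1, 0, sqrt(spec$variance * (1 - rho^2))) else numeric(0)
      as.numeric(stats::filter(c(x0, eps), rho, method = "recursive"))
    })
  }
  out <- force_series(z0 = z0, dt = spec$dt, force = f)
  rt <- rt_kj(temperature)
  out$xi_true <- spec$variance * spec$tau / rt
  out$d_true <- if (out$xi_true > 0) rt / out$xi_true else NA_real_
  out$seed <- spec$seed
  out
}

#' Idealized membrane frame
#'
#' A minimal single-frame description of a hydrated bilayer: box geometry and
#' composition (inputs to the area decomposition), C-D chain vectors placed at
#' the fixed tilt angle that reproduces a target deuterium order parameter,
#' and labeled 3D positions (head group, terminal carbon of an all-trans
#' chain with a 0.127 nm per-carbon rise, phosphate analogs) for the
#' geometric descriptors. This is a synthetic fixture with exactly known
#' ground truth, not a parsed MD snapshot.
#'
#' @param n_lipid Total lipid count (phospholipid + cholesterol).
#' @param x_chol Cholesterol mole fraction in `[0, 1]`.
#' @param n_water Water count.
#' @param a_box Box xy area, nm^2.
#' @param v_box Box volume, nm^3.
#' @param target_scd Target S_CD in `[-0.5, 1]`; vectors are placed at the
#'   polar angle theta* with (3 cos^2 theta* - 1)/2 = target_scd.
#' @param seed RNG seed (azimuths of the chain vectors).
#' @param n_carbons Carbons per chain (default 16).
#' @param vectors_per_carbon C-D vectors per carbon index (default: one per
#'   phospholipid).
#' @param v_water,v_chol Molecular volumes, nm^3 (defaults 0.0312 and 0.593).
#' @return Object of class `membrane_frame`.
#' @export
gen_membrane_frame <- function(n_lipid, x_chol, n_water, a_box, v_box,
                               target_scd, seed, n_carbons = 16,
                               vectors_per_carbon = NULL,
                               v_water = 0.0312, v_chol = 0.593) {
  if (x_chol < 0 || x_chol > 1) stop("x_chol must be in [0, 1]")
  if (v_box <= n_water * v_water) stop("v_box must exceed the total water volume")
  if (target_scd < -0.5 || target_scd > 1) stop("target_scd must be in [-0.5, 1]")
  n_chol <- round(x_chol * n_lipid)
  n_pl <- n_lipid - n_chol
  if (is.null(vectors_per_carbon)) vectors_per_carbon <- max(n_pl, 1L)

  cos_t <- sqrt((2 * target_scd + 1) / 3)
  sin_t <- sqrt(max(0, 1 - cos_t^2))
  nv <- n_carbons * vectors_per_carbon
  phi <- with_seed(seed, stats::runif(nv, 0, 2 * pi))
  vecs <- cbind(sin_t * cos(phi), sin_t * sin(phi), rep(cos_t, nv))
  carbon <- rep(seq_len(n_carbons), each = vectors_per_carbon)

  rise <- 0.127  # nm per carbon, all-trans projection
  z_head <- 1.9
  construction_length <- rise * (n_carbons - 1)
  labeled <- list(
    head = c(0, 0, z_head),
    Cter = c(0, 0, z_head - construction_length),
    P_upper = c(0, 0, z_head),
    P_lower = c(0, 0, -z_head)
  )
  structure(list(
    a_box = a_box, v_box = v_box, n_water = n_water, n_lipid = n_lipid,
    x_chol = x_chol, v_water = v_water, v_chol = v_chol,
    chain_vectors = vecs, carbon_index = carbon,
    labeled_positions = labeled, normal = c(0, 0, 1),
    species = c(rep("PL", n_pl), rep("CHOL", n_chol)),
    target_scd = target_scd, construction_length = construction_length,
    seed = seed
  ), class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("Membrane frame: %d lipids (x_chol = %.2f), %d waters, A_box = %g nm^2, V_box = %g nm^3\n",
              x$n_lipid, x$x_chol, x$n_water, x$a_box, x$v_box))
  invisible(x)
}
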