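#' Generic quantity-vs-depth profile
#'
#' @param z Strictly increasing depth grid, nm.
#' @param values Quantity per grid point (finite).
#' @param quantity One of `"diffusion"` (nm^2/ps), `"partition"`
#'   (dimensionless), `"resistance_density"` (ps/nm^2),
#'   `"cumulative_resistance"` (ps/nm), `"uncertainty"` (kJ/mol).
#' @param meta Optional provenance list.
#' @return Object of class `depth_profile`.
#' @export
depth_profile <- function(z, values, quantity, meta = list()) {
  z <- as.numeric(z); values <- as.numeric(values)
  if (length(z) != length(values)) stop("z and values must have equal length")
  if (length(z) > 1L && any(diff(z) <= 0)) stop("z must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  quantity <- match.arg(quantity, c("diffusion", "partition",
                                    "resistance_density",
                                    "cumulative_resistance", "uncertainty"))
  if (quantity %in% c("diffusion", "partition", "resistance_density") &&
      any(values <= 0))
    stop(quantity, " values must be strictly positive")
  if (quantity == "cumulative_resistance" && any(values < 0))
    stop("cumulative resistance must be non-negative")
  structure(list(z = z, values = values, quantity = quantity, meta = meta),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile [%s]: %d points on [%.3g, %.3g] nm\n",
              x$quantity, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  out <- data.frame(z_nm = x$z, value = x$values)
  names(out)[2] <- x$quantity
  out
}

#' Depth-dependent partition coefficient
#'
#' K(z) = exp(-dG(z)/RT) relative to the profile's reference state: K = 1
#' wherever dG = 0 and K > 1 where the solute is stabilized relative to the
#' reference.
#'
#' @param G A [free_energy_profile()].
#' @return A [depth_profile()] of quantity `"partition"`.
#' @export
partition_profile <- function(G) {
  stopifnot(inherits(G, "free_energy_profile"))
  rt <- rt_kj(G$temperature)
  x <- pmin(pmax(-G$G / rt, -700), 700)   # overflow-safe
  depth_profile(G$z, exp(x), quantity = "partition",
                meta = list(reference = G$reference, temperature = G$temperature))
}

#' Local resistance density
#'
#' The inhomogeneous solubility-diffusion integrand
#' rho(z) = exp(dG(z)/RT) / D(z) in ps/nm^2. The diffusion profile is
#' linearly interpolated onto the free-energy grid (D is typically sampled
#' at sparse window centers); the output covers the overlap of the two
#' grids. With a flat D, the minimum of rho sits at the PMF minimum.
#'
#' @param G A [free_energy_profile()] (already set to the desired
#'   reference; the reference choice rescales rho by a pure exponential).
#' @param D A [depth_profile()] of quantity `"diffusion"`, or a single
#'   positive number for a depth-independent diffusion coefficient
#'   (nm^2/ps).
#' @return A [depth_profile()] of quantity `"resistance_density"`.
#' @export
local_resistance <- function(G, D) {
  stopifnot(inherits(G, "free_energy_profile"))
  rt <- rt_kj(G$temperature)
  if (is.numeric(D) && length(D) == 1L) {
    if (D <= 0) stop("D must be positive")
    zs <- G$z
    dv <- rep(D, length(zs))
    gv <- G$G
  } else {
    stopifnot(inherits(D, "depth_profile"), D$quantity == "diffusion")
    sel <- G$z >= min(D$z) - 1e-12 & G$z <= max(D$z) + 1e-12
    if (sum(sel) < 2L) stop("free-energy and diffusion grids do not overlap")
    zs <- G$z[sel]
    gv <- G$G[sel]
    dv <- stats::approx(D$z, D$values, xout = zs, rule = 2)$y
    if (any(dv <= 0)) stop("non-positive interpolated diffusion coefficient")
  }
  x <- pmin(gv / rt, 700)
  depth_profile(zs, exp(x) / dv, quantity = "resistance_density",
                meta = list(reference = G$reference, temperature = G$temperature))
}

#' Cumulative resistance across the bilayer
#'
#' Trapezoidal running integral of the local resistance density from the
#' lower to the upper integration bound; the endpoint value is the total
#' resistance R (ps/nm). Plateaus of the cumulative curve mark regions that
#' contribute nothing; its steep segments are the permeation bottlenecks.
#'
#' @param rho A [depth_profile()] of quantity `"resistance_density"`.
#' @param bounds Length-2 integration bounds, nm (default: full grid).
#' @return A [depth_profile()] of quantity `"cumulative_resistance"`;
#'   `meta$R_total` holds the endpoint.
#' @export
cumulative_resistance <- function(rho, bounds = NULL) {
  stopifnot(inherits(rho, "depth_profile"), rho$quantity == "resistance_density")
  bounds <- bounds %||% range(rho$z)
  if (bounds[1] >= bounds[2]) stop("inverted integration bounds")
  if (bounds[1] < min(rho$z) - 1e-12 || bounds[2] > max(rho$z) + 1e-12)
    stop("bounds outside the resistance grid")
  interior <- rho$z[rho$z > bounds[1] & rho$z < bounds[2]]
  zb <- unique(sort(c(bounds[1], interior, bounds[2])))
  vb <- stats::approx(rho$z, rho$values, xout = zb)$y
  cum <- as.numeric(pracma::cumtrapz(zb, vb))
  depth_profile(zb, cum, quantity = "cumulative_resistance",
                meta = c(rho$meta, list(R_total = cum[length(cum)],
                                        bounds = bounds)))
}

#' Permeability coefficient under the inhomogeneous solubility-diffusion model
#'
#' P = 1 / R with R the integral of exp(dG(z)/RT)/D(z) across the membrane,
#' after re-referencing the free-energy profile to the requested convention.
#' Shifting the reference by a constant c rescales P by exp(-c/RT) exactly;
#' with the global-minimum reference the resistance in the water region is
#' inflated by the full desorption free energy (a known artifact of that
#' convention, reported in `notes` rather than corrected). The permeability
#' is returned in cm/s (1 nm/ps = 1e5 cm/s).
#'
#' @param G A [free_energy_profile()].
#' @param D A [depth_profile()] of diffusion coefficients or a single
#'   number (nm^2/ps).
#' @param bounds Integration bounds, nm (default: the overlap grid range).
#' @param reference Reference convention applied before integration.
#' @param z_bulk Plateau edge for the bulk-water reference and barrier
#'   extraction, nm.
#' @param region_edges Edges (symmetric about 0) for the resistance
#'   decomposition, nm.
#' @param margin Regime-classification margin, kJ/mol (default 2, about RT,
#'   below typical split-half PMF noise).
#' @return Object of class `permeability_result`.
#' @export
permeability <- function(G, D, bounds = NULL,
                         reference = c("bulk_water", "global_minimum", "bilayer_center"),
                         z_bulk = 3.5, region_edges = c(-1, 1), margin = 2) {
  reference <- match.arg(reference)
  gref <- set_reference(G, reference, z_bulk = z_bulk)
  rho <- local_resistance(gref, D)
  bounds <- bounds %||% range(rho$z)
  cum <- cumulative_resistance(rho, bounds)
  r_total <- cum$meta$R_total
  p_cm_s <- 1 / r_total * 1e5

  barriers <- tryCatch(extract_barriers(gref, z_bulk = z_bulk),
                       error = function(e) NULL)
  regime <- if (is.null(barriers)) "indeterminate"
            else classify_regime(barriers, margin = margin)
  decomp <- tryCatch(decompose_resistance(cum, region_edges),
                     error = function(e) NULL)
  notes <- character(0)
  if (reference == "global_minimum")
    notes <- paste("global-minimum reference offsets the whole profile,",
                   "inflating the apparent resistance in the water phase")
  structure(list(P_cm_per_s = p_cm_s, R_total_ps_per_nm = r_total,
                 reference = reference, regime = regime,
                 integration_bounds = bounds, decomposition = decomp,
                 barriers = barriers, resistance = rho, cumulative = cum,
                 notes = notes),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("Permeability: P = %.4g cm/s (R = %.4g ps/nm), reference = %s, regime = %s\n",
              x$P_cm_per_s, x$R_total_ps_per_nm, x$reference, x$regime))
  if (!is.null(x$decomposition))
    cat(sprintf("  resistance fractions: entrance %.2f, center %.2f, desorption %.2f\n",
                x$decomposition$fractions["entrance"],
                x$decomposition$fractions["center"],
                x$decomposition$fractions["desorption"]))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Classify the rate-limiting permeation regime
#'
#' Desorption-limited when the desorption barrier exceeds the translocation
#' barrier by more than `margin`, translocation-limited in the reversed
#' case, indeterminate within the margin or for degenerate profiles.
#'
#' @param barriers A `barrier_set` from [extract_barriers()].
#' @param margin kJ/mol (default 2).
#' @return `"desorption_limited"`, `"translocation_limited"` or
#'   `"indeterminate"`.
#' @export
classify_regime <- function(barriers, margin = 2) {
  stopifnot(inherits(barriers, "barrier_set"))
  if (isTRUE(barriers$degenerate)) return("indeterminate")
  d <- barriers$dG_desorption - barriers$dG_translocation
  if (d > margin) "desorption_limited"
  else if (d < -margin) "translocation_limited"
  else "indeterminate"
}

#' Decompose the total resistance into entrance, center, desorption regions
#'
#' Splits the cumulative resistance at `region_edges` (symmetric about the
#' bilayer center): the three contributions are exact partial integrals and
#' sum to R_total to machine precision.
#'
#' @param cum A [depth_profile()] of quantity `"cumulative_resistance"`.
#' @param region_edges Scalar e (interpreted as c(-e, e)) or a symmetric
#'   length-2 vector, nm. Default c(-1, 1).
#' @return Object of class `resistance_decomposition`: contributions
#'   (ps/nm), `fractions` (summing to 1) and `R_total`.
#' @export
decompose_resistance <- function(cum, region_edges = c(-1, 1)) {
  stopifnot(inherits(cum, "depth_profile"), cum$quantity == "cumulative_resistance")
  if (length(region_edges) == 1L) region_edges <- c(-region_edges, region_edges)
  if (abs(region_edges[1] + region_edges[2]) > 1e-9)
    stop("region_edges must be symmetric about 0")
  zr <- range(cum$z)
  if (region_edges[1] < zr[1] - 1e-12 || region_edges[2] > zr[2] + 1e-12)
    stop("region edges outside the integration bounds")
  cv <- stats::approx(cum$z, cum$values, xout = region_edges)$y
  r_total <- cum$values[length(cum$values)]
  contrib <- c(entrance = cv[1],
               center = cv[2] - cv[1],
               desorption = r_total - cv[2])
  structure(list(entrance = contrib[["entrance"]], center = contrib[["center"]],
                 desorption = contrib[["desorption"]],
                 fractions = contrib / r_total, R_total = r_total,
                 region_edges = region_edges),
            class = "resistance_decomposition")
}

#' @export
print.resistance_decomposition <- function(x, ...) {
  cat(sprintf("Resistance decomposition (edges at %s nm): entrance %.4g, center %.4g, desorption %.4g ps/nm (total %.4g)\n",
              paste(x$region_edges, collapse = ", "),
              x$entrance, x$center, x$desorption, x$R_total))
  invisible(x)
}
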