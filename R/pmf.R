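#' Free-energy profile container
#'
#' G(z) on a depth grid, with an explicit reference convention. The profile
#' is only ever defined up to an additive constant; the reference names the
#' point (or region) where it has been pinned to zero.
#'
#' @param z Strictly increasing depth grid, nm.
#' @param G Free energy per grid point, kJ/mol (finite).
#' @param reference One of `"bulk_water"`, `"global_minimum"`,
#'   `"bilayer_center"`.
#' @param temperature K.
#' @param uncertainty Optional per-point uncertainty, kJ/mol.
#' @param meta Optional list of provenance (iterations, residual, ...).
#' @return Object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(z, G, reference = "bilayer_center",
                                temperature = 298.15, uncertainty = NULL,
                                meta = list()) {
  z <- as.numeric(z); G <- as.numeric(G)
  if (length(z) != length(G)) stop("z and G must have equal length")
  if (length(z) > 1L && any(diff(z) <= 0)) stop("z must be strictly increasing")
  if (any(!is.finite(G))) stop("G must be finite on the covered grid")
  reference <- match.arg(reference, c("bulk_water", "global_minimum", "bilayer_center"))
  if (!is.null(uncertainty) && length(uncertainty) != length(z))
    stop("uncertainty must match the grid length")
  structure(list(z = z, G = G, reference = reference,
                 temperature = temperature, uncertainty = uncertainty,
                 meta = meta),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile: %d points on [%.3g, %.3g] nm, reference = %s, T = %g K\n",
              length(x$z), min(x$z), max(x$z), x$reference, x$temperature))
  if (!is.null(x$meta$n_iter))
    cat(sprintf("  WHAM: %d iterations, residual %.3g kJ/mol\n",
                x$meta$n_iter, x$meta$residual))
  invisible(x)
}

#' @export
as.data.frame.free_energy_profile <- function(x, ...) {
  data.frame(z_nm = x$z, G_kJmol = x$G,
             err_kJmol = x$uncertainty %||% rep(NA_real_, length(x$z)))
}

#' Histogram umbrella windows on a shared grid
#'
#' Bins every window's samples on one common grid spanning the union of the
#' window supports. Interior bins with zero total counts are recorded as
#' coverage gaps (uncovered intervals), which [wham_solve()] refuses to
#' bridge.
#'
#' @param windows List of [umbrella_window()].
#' @param bin_width Bin width, nm (default 0.01 nm, about three bins per
#'   sqrt(RT/k) ~ 0.029 nm bias width at k = 3000 kJ mol^-1 nm^-2).
#' @param breaks Optional explicit bin breaks (overrides `bin_width`).
#' @return Object of class `window_histograms`: `breaks`, `centers`,
#'   `counts` (windows x bins), `n` (samples per window), `gaps`
#'   (data.frame of uncovered intervals).
#' @export
histogram_windows <- function(windows, bin_width = 0.01, breaks = NULL) {
  stopifnot(length(windows) >= 1L)
  if (is.null(breaks)) {
    if (bin_width <= 0) stop("bin_width must be > 0")
    lo <- min(vapply(windows, function(w) min(w$samples), numeric(1)))
    hi <- max(vapply(windows, function(w) max(w$samples), numeric(1)))
    breaks <- seq(floor(lo / bin_width) * bin_width,
                  ceiling(hi / bin_width + 1e-9) * bin_width,
                  by = bin_width)
    if (length(breaks) < 2L) breaks <- c(breaks[1], breaks[1] + bin_width)
  }
  m <- length(breaks) - 1L
  counts <- t(vapply(windows, function(w) {
    idx <- findInterval(w$samples, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = m)
  }, integer(m)))
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  total <- colSums(counts)
  nz <- which(total > 0)
  gaps <- data.frame(z_lo = numeric(0), z_hi = numeric(0), n_bins = integer(0))
  if (length(nz) > 0L) {
    first <- nz[1]; last <- nz[length(nz)]
    run <- rle(total[first:last] == 0)
    pos <- first
    for (i in seq_along(run$lengths)) {
      if (run$values[i]) {
        gaps <- rbind(gaps, data.frame(z_lo = breaks[pos],
                                       z_hi = breaks[pos + run$lengths[i]],
                                       n_bins = run$lengths[i]))
      }
      pos <- pos + run$lengths[i]
    }
  }
  structure(list(breaks = breaks, centers = centers, counts = counts,
                 n = rowSums(counts), bin_width = stats::median(diff(breaks)),
                 gaps = gaps),
            class = "window_histograms")
}

#' Weighted histogram analysis method (WHAM)
#'
#' Combines biased umbrella-window histograms into one unbiased free-energy
#' profile by self-consistent iteration of the window free energies. The
#' iteration stops when the maximum absolute change of any window free
#' energy per sweep falls below `tol` (kJ/mol); non-convergence raises an
#' error carrying the last residual. A coverage gap (a run of three or more
#' empty interior bins) is a hard failure; isolated empty bins are simply
#' dropped from the returned grid.
#'
#' @param windows List of [umbrella_window()] (all with `k > 0`).
#' @param temperature K.
#' @param tol Convergence tolerance on the window free energies, kJ/mol.
#' @param max_iter Maximum self-consistency sweeps.
#' @param bin_width Histogram bin width, nm.
#' @param breaks Optional shared bin breaks (e.g. for split-half or
#'   convergence comparisons on a fixed grid).
#' @return A [free_energy_profile()] with reference `"bilayer_center"`
#'   (G = 0 at the grid point nearest z = 0); `meta` carries the iteration
#'   count, final residual and window free energies.
#' @export
wham_solve <- function(windows, temperature = 298.15, tol = 1e-7,
                       max_iter = 1e5, bin_width = 0.01, breaks = NULL) {
  stopifnot(length(windows) >= 1L)
  h <- histogram_windows(windows, bin_width = bin_width, breaks = breaks)
  z0r <- range(vapply(windows, `[[`, numeric(1), "z0"))
  # a gap is fatal only inside the window-center span; sparse tail bins
  # beyond the outermost centers are simply dropped
  fatal <- h$gaps$n_bins >= 3L & h$gaps$z_hi > z0r[1] & h$gaps$z_lo < z0r[2]
  if (any(fatal)) {
    g <- h$gaps[fatal, ][1, ]
    stop(sprintf("coverage gap: no samples on [%.4g, %.4g] nm; windows do not overlap",
                 g$z_lo, g$z_hi), call. = FALSE)
  }
  keep <- colSums(h$counts) > 0
  zc <- h$centers[keep]
  counts <- h$counts[, keep, drop = FALSE]
  bw <- h$bin_width
  rt <- rt_kj(temperature)

  z0 <- vapply(windows, `[[`, numeric(1), "z0")
  kk <- vapply(windows, `[[`, numeric(1), "k")
  ni <- rowSums(counts)
  # Bin-averaged Boltzmann factor of the harmonic bias, exact via the
  # Gaussian CDF. Mid-point evaluation biases the window free energies by
  # O(h^2 (k/RT)^2) per bin, which compounds across the window chain; the
  # averaged factor removes that at any bin width.
  blo <- h$breaks[-length(h$breaks)][keep]
  bhi <- h$breaks[-1][keep]
  bias <- t(vapply(seq_along(z0), function(i) {
    sig <- sqrt(rt / kk[i])
    up <- blo > z0[i]
    d <- ifelse(up,
                stats::pnorm(blo, z0[i], sig, lower.tail = FALSE) -
                  stats::pnorm(bhi, z0[i], sig, lower.tail = FALSE),
                stats::pnorm(bhi, z0[i], sig) - stats::pnorm(blo, z0[i], sig))
    sig * sqrt(2 * pi) * pmax(d, 0) / (bhi - blo)
  }, numeric(length(zc))))
  ctot <- colSums(counts)

  f <- rep(1, length(windows))
  g_old <- rep(0, length(windows))
  converged <- FALSE
  it <- 0L
  resid <- Inf
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.numeric(crossprod(bias, ni * f))   # per-bin normalization
    p <- ctot / denom
    p <- p / (sum(p) * bw)                         # pin the arbitrary scale
    f <- 1 / (as.numeric(bias %*% p) * bw)
    g_new <- -rt * log(f)
    resid <- max(abs(g_new - g_old))
    g_old <- g_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("WHAM did not converge in %d iterations (last residual %.3g kJ/mol > tol %.3g)",
                 as.integer(max_iter), resid, tol), call. = FALSE)

  G <- -rt * log(p)
  G <- G - G[which.min(abs(zc))]   # bilayer-center reference by default
  free_energy_profile(zc, G, reference = "bilayer_center",
                      temperature = temperature,
                      meta = list(n_iter = it, residual = resid,
                                  window_free_energies = g_old,
                                  bin_width = bw, z0 = z0, k = kk))
}

#' Re-reference a free-energy profile
#'
#' Applies a pure additive shift: `bulk_water` zeroes the mean of G over the
#' plateau `|z| >= z_bulk`, `global_minimum` zeroes min(G), and
#' `bilayer_center` zeroes G at the grid point nearest z = 0. Pairwise free
#' energy differences (and hence barrier heights) are preserved exactly.
#'
#' @param profile A [free_energy_profile()].
#' @param reference Target convention.
#' @param z_bulk Plateau edge for `bulk_water`, nm (default 3.5 nm).
#' @return The shifted profile; `meta$shift` records the constant removed.
#' @export
set_reference <- function(profile,
                          reference = c("bulk_water", "global_minimum", "bilayer_center"),
                          z_bulk = 3.5) {
  stopifnot(inherits(profile, "free_energy_profile"))
  reference <- match.arg(reference)
  shift <- switch(reference,
    bulk_water = {
      sel <- abs(profile$z) >= z_bulk
      if (!any(sel)) stop("grid does not reach the bulk plateau |z| >= ", z_bulk)
      mean(profile$G[sel])
    },
    global_minimum = min(profile$G),
    bilayer_center = profile$G[which.min(abs(profile$z))]
  )
  out <- profile
  out$G <- profile$G - shift
  out$reference <- reference
  out$meta$shift <- shift
  out
}

#' Symmetrize a free-energy profile about the bilayer center
#'
#' Averages the two leaflets: G_sym(z) = (G(z) + G(-z))/2 on a grid made
#' symmetric about 0 (off-grid mirror points are linearly interpolated).
#' Idempotent; intended for symmetric bilayers where both leaflets estimate
#' the same physical profile.
#'
#' @param profile A [free_energy_profile()] covering both sides of z = 0.
#' @return A symmetric [free_energy_profile()].
#' @export
symmetrize <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  z <- profile$z
  zmax <- min(max(z), -min(z))
  if (zmax <= 0) stop("profile must straddle z = 0 to be symmetrized")
  dz <- stats::median(diff(z))
  zs <- seq(0, zmax, by = dz)
  grid <- sort(unique(c(-zs, zs)))
  gp <- stats::approx(z, profile$G, xout = grid)$y
  gm <- stats::approx(z, profile$G, xout = -grid)$y
  free_energy_profile(grid, (gp + gm) / 2, reference = profile$reference,
                      temperature = profile$temperature,
                      meta = c(profile$meta, list(symmetrized = TRUE)))
}

#' Split-half uncertainty of a WHAM profile
#'
#' Re-solves WHAM from the first and second halves of every window's
#' sampling time and returns the per-grid-point absolute difference between
#' the two half-profiles after aligning them to a common reference (their
#' mean over the shared grid). This is the standard sampling-error estimate
#' when only one run per window exists.
#'
#' @param windows List of [umbrella_window()] with at least 2 samples each.
#' @param temperature K.
#' @param bin_width Histogram bin width, nm.
#' @param ... Passed to [wham_solve()] (`tol`, `max_iter`).
#' @return A [depth_profile()] of quantity `"uncertainty"`, kJ/mol.
#' @export
split_half_uncertainty <- function(windows, temperature = 298.15,
                                   bin_width = 0.01, ...) {
  short <- vapply(windows, function(w) length(w$samples) < 2L, logical(1))
  if (any(short)) stop("window too short to split (need >= 2 samples)")
  full <- histogram_windows(windows, bin_width = bin_width)
  halves <- function(which_half) {
    lapply(windows, function(w) {
      n <- length(w$samples)
      idx <- if (which_half == 1L) seq_len(floor(n / 2)) else (floor(n / 2) + 1L):n
      umbrella_window(w$z0, w$k, w$samples[idx], w$dt)
    })
  }
  p1 <- wham_solve(halves(1L), temperature = temperature, breaks = full$breaks, ...)
  p2 <- wham_solve(halves(2L), temperature = temperature, breaks = full$breaks, ...)
  key1 <- signif(p1$z, 12); key2 <- signif(p2$z, 12)
  common <- intersect(key1, key2)
  i1 <- match(common, key1); i2 <- match(common, key2)
  d <- p1$G[i1] - p2$G[i2]
  d <- d - mean(d)
  depth_profile(p1$z[i1], abs(d), quantity = "uncertainty")
}

#' Convergence scan of the free-energy profile
#'
#' Recomputes the profile from systematically truncated window data under
#' three schemes: (i) increasing total sampling time from the start,
#' (ii) increasing the initial slice discarded as equilibration with the
#' remainder analyzed, (iii) increasing the discarded slice while analyzing
#' a fixed-length span. All profiles are solved on the full-data histogram
#' grid so they are directly comparable, and the barrier heights are
#' extracted for each truncation point.
#'
#' @param windows List of [umbrella_window()] sharing the same series span.
#' @param scheme `"i"`, `"ii"` or `"iii"`.
#' @param step Truncation increment, ps; must divide the series span.
#' @param analysis_span Fixed analysis length for scheme `"iii"`, ps.
#' @param temperature K.
#' @param z_bulk Passed to [extract_barriers()].
#' @param bin_width Histogram bin width, nm.
#' @param ... Passed to [wham_solve()].
#' @return A list of class `convergence_scan`: `scheme`, `t` (truncation
#'   parameter per point, ps), `profiles` (list of profiles), `barriers`
#'   (data.frame of t, dG_desorption, dG_translocation).
#' @export
convergence_scan <- function(windows, scheme = c("i", "ii", "iii"), step,
                             analysis_span = NULL, temperature = 298.15,
                             z_bulk = 3.5, bin_width = 0.01, ...) {
  scheme <- match.arg(scheme)
  if (step <= 0) stop("step must be > 0")
  spans <- vapply(windows, function(w) length(w$samples) * w$dt, numeric(1))
  total <- spans[1]
  if (any(abs(spans - total) > 1e-9 * total))
    stop("all windows must share the same series span")
  if (abs(total / step - round(total / step)) > 1e-6)
    stop("step must divide the series span (", total, " ps)")
  if (scheme == "iii") {
    if (is.null(analysis_span)) stop("analysis_span is required for scheme iii")
    if (analysis_span > total) stop("analysis_span longer than the data")
  }
  tpar <- switch(scheme,
    i   = seq(step, total, by = step),
    ii  = seq(0, total - step, by = step),
    iii = seq(0, total - analysis_span, by = step))
  full <- histogram_windows(windows, bin_width = bin_width)
  subset_window <- function(w, t0, t1) {
    tt <- (seq_along(w$samples) - 1) * w$dt
    idx <- which(tt >= t0 - 1e-12 & tt < t1 - 1e-12)
    umbrella_window(w$z0, w$k, w$samples[idx], w$dt)
  }
  profiles <- vector("list", length(tpar))
  bars <- data.frame(t = tpar, dG_desorption = NA_real_, dG_translocation = NA_real_)
  for (j in seq_along(tpar)) {
    lim <- switch(scheme,
      i   = c(0, tpar[j]),
      ii  = c(tpar[j], total),
      iii = c(tpar[j], tpar[j] + analysis_span))
    sub <- lapply(windows, subset_window, t0 = lim[1], t1 = lim[2])
    profiles[[j]] <- wham_solve(sub, temperature = temperature,
                                breaks = full$breaks, ...)
    b <- tryCatch(extract_barriers(profiles[[j]], z_bulk = z_bulk),
                  error = function(e) NULL)
    if (!is.null(b)) {
      bars$dG_desorption[j] <- b$dG_desorption
      bars$dG_translocation[j] <- b$dG_translocation
    }
  }
  structure(list(scheme = scheme, t = tpar, profiles = profiles, barriers = bars),
            class = "convergence_scan")
}

#' Extract equilibrium position and barrier heights from a profile
#'
#' The equilibrium position is the argmin of a moving-average-smoothed copy
#' of the profile (raw PMFs can be rugged; smoothing stabilizes the argmin),
#' with ties broken toward smaller `|z|`. The translocation barrier is
#' G(0) - G(z_eq) and the desorption barrier is the bulk plateau mean
#' (over `|z| >= z_bulk`) minus G(z_eq), both read from the unsmoothed
#' profile. Per-leaflet values are also returned, which is what matters for
#' asymmetric bilayers sampled through the entire membrane. A profile with
#' no interior minimum is flagged degenerate and the barriers are reported
#' against the grid endpoints.
#'
#' @param profile A [free_energy_profile()] covering z = 0 and the plateau.
#' @param z_bulk Plateau edge, nm (default 3.5 nm).
#' @param smooth_window Moving-average width, nm (default 0.3 nm).
#' @return Object of class `barrier_set`: `z_eq`, `dG_desorption`,
#'   `dG_translocation` (kJ/mol), `degenerate` flag and a `per_leaflet`
#'   data.frame.
#' @export
extract_barriers <- function(profile, z_bulk = 3.5, smooth_window = 0.3) {
  stopifnot(inherits(profile, "free_energy_profile"))
  z <- profile$z; G <- profile$G
  if (length(z) < 3L) stop("profile too short")
  bulk_sel <- abs(z) >= z_bulk
  if (!any(bulk_sel)) stop("profile does not cover |z| >= z_bulk = ", z_bulk)
  dz <- stats::median(diff(z))
  w <- max(1L, round(smooth_window / dz))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- if (w > 1L) as.numeric(stats::filter(G, rep(1 / w, w), sides = 2)) else G
  valid <- which(is.finite(sm))

  argmin_tie <- function(idx_set) {
    v <- sm[idx_set]
    cand <- idx_set[v <= min(v) + 1e-12]
    cand[order(abs(z[cand]), z[cand])][1]
  }
  pick <- function(idx_set) {
    i_min <- argmin_tie(idx_set)
    flat <- diff(range(sm[idx_set])) < 1e-9
    degen <- flat || i_min == idx_set[1] || i_min == idx_set[length(idx_set)]
    list(i = i_min, degenerate = degen)
  }

  i0 <- which.min(abs(z))
  g0 <- G[i0]
  g_bulk_all <- mean(G[bulk_sel])

  glob <- pick(valid)
  z_eq <- z[glob$i]
  dG_tr <- g0 - G[glob$i]
  dG_de <- g_bulk_all - G[glob$i]
  if (glob$degenerate && diff(range(sm[valid])) < 1e-9) { dG_tr <- 0; dG_de <- 0 }

  leaflet_row <- function(side) {
    idx <- if (side == "lower") valid[z[valid] <= 0] else valid[z[valid] >= 0]
    bsel <- if (side == "lower") which(z <= -z_bulk) else which(z >= z_bulk)
    if (length(idx) < 3L || length(bsel) == 0L)
      return(data.frame(leaflet = side, z_eq = NA_real_, dG_translocation = NA_real_,
                        dG_desorption = NA_real_, degenerate = NA))
    p <- pick(idx)
    data.frame(leaflet = side, z_eq = z[p$i],
               dG_translocation = g0 - G[p$i],
               dG_desorption = mean(G[bsel]) - G[p$i],
               degenerate = p$degenerate)
  }
  per_leaflet <- rbind(leaflet_row("lower"), leaflet_row("upper"))

  structure(list(z_eq = z_eq, dG_desorption = dG_de, dG_translocation = dG_tr,
                 degenerate = glob$degenerate, per_leaflet = per_leaflet,
                 z_bulk = z_bulk, smooth_window = smooth_window),
            class = "barrier_set")
}

#' @export
print.barrier_set <- function(x, ...) {
  cat(sprintf("Barriers: z_eq = %.3g nm, translocation %.3g kJ/mol, desorption %.3g kJ/mol%s\n",
              x$z_eq, x$dG_translocation, x$dG_desorption,
              if (isTRUE(x$degenerate)) " [degenerate: no interior minimum]" else ""))
  invisible(x)
}
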