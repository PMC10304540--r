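#' Force fluctuations about the window mean
#'
#' dF(t) = F(t) - mean(F). The mean of the returned series is zero to
#' machine precision.
#'
#' @param series A [force_series()] or a plain numeric vector.
#' @return Numeric fluctuation series, kJ mol^-1 nm^-1.
#' @export
force_fluctuations <- function(series) {
  f <- if (inherits(series, "force_series")) series$force else as.numeric(series)
  if (length(f) < 1L) stop("empty force series")
  f - mean(f)
}

#' Biased lag autocovariance of a fluctuation series
#'
#' Computes ACF(k) = (1/N) sum_t dF(t) dF(t+k) for lags 0..max_lag. The
#' biased 1/N normalization guarantees a positive-semidefinite estimate and
#' a bounded time integral. Evaluated via zero-padded FFT, which is exactly
#' the direct sum up to floating-point roundoff.
#'
#' The input is taken as already centered (see [force_fluctuations()]); no
#' mean is subtracted here.
#'
#' @param x Fluctuation series (numeric), or a [force_series()] whose
#'   fluctuations are computed first.
#' @param max_lag Maximum lag, ps; must be smaller than the series span.
#' @param dt Sampling interval, ps (taken from `x` when it is a
#'   [force_series()]).
#' @return Object of class `acf_estimate`: `lag_ps`, `acf`, `dt`, `n`.
#' @export
autocorrelation <- function(x, max_lag, dt = NULL) {
  if (inherits(x, "force_series")) {
    dt <- x$dt
    x <- force_fluctuations(x)
  }
  if (is.null(dt) || dt <= 0) stop("dt must be supplied (> 0) for a plain numeric series")
  n <- length(x)
  span <- (n - 1) * dt
  if (max_lag >= span) stop("max_lag must be smaller than the series span (", span, " ps)")
  k_max <- floor(max_lag / dt + 1e-9)
  L <- 2^ceiling(log2(max(2L, 2L * n)))
  fx <- stats::fft(c(x, rep(0, L - n)))
  s <- Re(stats::fft(Mod(fx)^2, inverse = TRUE)) / L
  acov <- s[seq_len(k_max + 1L)] / n
  structure(list(lag_ps = (0:k_max) * dt, acf = acov, dt = dt, n = n),
            class = "acf_estimate")
}

#' Static friction coefficient from the force ACF
#'
#' xi = (1/RT) * integral of the force-fluctuation autocovariance over time,
#' evaluated by the trapezoidal rule. A finite noisy ACF cannot be summed to
#' infinity, so the integral is truncated by default at the ACF's first
#' zero crossing (the first nonpositive lag); the cutoff actually used is
#' recorded in the result for audit.
#'
#' @param acf An `acf_estimate` from [autocorrelation()].
#' @param dt Sampling interval, ps (default: taken from `acf`).
#' @param temperature K.
#' @param cutoff `"first_zero"` (default) or `"full"` (integrate all lags).
#' @return Object of class `friction_result`: `xi` (kJ mol^-1 nm^-2 ps),
#'   `acf`, `lag_ps`, `cutoff_lag` (ps), `temperature`.
#' @export
static_friction <- function(acf, dt = NULL, temperature = 298.15,
                            cutoff = c("first_zero", "full")) {
  stopifnot(inherits(acf, "acf_estimate"))
  cutoff <- match.arg(cutoff)
  dt <- dt %||% acf$dt
  a <- acf$acf
  if (all(a == 0)) stop("zero-fluctuation series: friction (and D) undefined")
  ci <- length(a)
  if (cutoff == "first_zero") {
    nz <- which(a <= 0)
    if (length(nz) > 0L) ci <- nz[1]
    else warning("ACF never crosses zero within max_lag; integrating the full range")
  }
  xi <- pracma::trapz(acf$lag_ps[seq_len(ci)], a[seq_len(ci)]) / rt_kj(temperature)
  structure(list(xi = xi, acf = a, lag_ps = acf$lag_ps,
                 cutoff_lag = acf$lag_ps[ci], temperature = temperature),
            class = "friction_result")
}

#' @export
print.friction_result <- function(x, ...) {
  cat(sprintf("Static friction xi = %.4g kJ/mol/nm^2 ps (ACF integrated to %.4g ps); D = RT/xi = %.4g nm^2/ps\n",
              x$xi, x$cutoff_lag, rt_kj(x$temperature) / x$xi))
  invisible(x)
}

#' Local diffusion profile from per-window force series
#'
#' For each restrained window, D(z0) = RT / xi(z0) with the static friction
#' from the force-fluctuation autocorrelation. Windows are assembled into a
#' depth profile sorted by z0. Unit: nm^2/ps; 1 nm^2/ps = 1e-2 cm^2/s.
#'
#' @param series_list List of [force_series()] with distinct `z0`.
#' @param temperature K.
#' @param max_lag Maximum ACF lag, ps; default one tenth of the series span.
#' @param cutoff Passed to [static_friction()].
#' @return A [depth_profile()] of quantity `"diffusion"`; `meta` carries the
#'   per-window friction and integration cutoff (`cutoff_ps`).
#' @export
diffusion_profile <- function(series_list, temperature = 298.15,
                              max_lag = NULL, cutoff = "first_zero") {
  stopifnot(length(series_list) >= 1L)
  z0 <- vapply(series_list, `[[`, numeric(1), "z0")
  dup <- z0[duplicated(z0)]
  if (length(dup) > 0L)
    stop("duplicate window depth z0 = ", dup[1], " nm")
  ord <- order(z0)
  res <- lapply(series_list[ord], function(s) {
    ml <- max_lag %||% ((length(s$force) - 1) * s$dt / 10)
    fr <- static_friction(autocorrelation(s, max_lag = ml),
                          temperature = temperature, cutoff = cutoff)
    c(D = rt_kj(temperature) / fr$xi, xi = fr$xi, cutoff = fr$cutoff_lag)
  })
  m <- do.call(rbind, res)
  depth_profile(z0[ord], m[, "D"], quantity = "diffusion",
                meta = list(xi = m[, "xi"], cutoff_ps = m[, "cutoff"],
                            temperature = temperature))
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = kB T / (6 pi eta r), returned in nm^2/ps. For a small aqueous solute
#' (r ~ 0.25 nm) in water at 298.15 K this is ~1e-3 nm^2/ps = 1e-5 cm^2/s,
#' the expected bulk-water magnitude.
#'
#' @param radius_nm Hydrodynamic radius, nm.
#' @param temperature K.
#' @param viscosity Dynamic viscosity, Pa s (default water, 8.9e-4).
#' @return D in nm^2/ps.
#' @export
stokes_einstein_d <- function(radius_nm, temperature = 298.15,
                              viscosity = 8.9e-4) {
  if (radius_nm <= 0) stop("radius must be > 0")
  kb <- 1.380649e-23
  d_m2s <- kb * temperature / (6 * pi * viscosity * radius_nm * 1e-9)
  d_m2s * 1e6   # m^2/s -> nm^2/ps
}
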