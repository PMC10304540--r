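# Molar gas constant, kJ mol^-1 K^-1 (CODATA 2018)
.R_GAS_KJ <- 8.314462618e-3

#' Thermal energy RT
#'
#' Returns the thermal energy \eqn{RT} in kJ/mol at the given absolute
#' temperature. All free energies in this package are in kJ/mol, so this one
#' constant links energies, Boltzmann factors, and the friction/diffusion
#' relation \eqn{D = RT/\xi}.
#'
#' @param temperature Absolute temperature in K (default 298.15 K).
#' @return Thermal energy in kJ/mol.
#' @examples
#' rt_kj()            # 2.4790 kJ/mol at 298.15 K
#' rt_kj(310)
#' @export
rt_kj <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive number (K)")
  .R_GAS_KJ * temperature
}

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Format a double so that it round-trips exactly through as.numeric().
fmt_g17 <- function(x) sprintf("%.17g", x)
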