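---
title: "Free-energy profiles, local diffusion and membrane permeability: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy profiles, local diffusion and membrane permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidperm)
```

## The model

An amphiphile permeating a lipid bilayer is described by two depth-resolved
quantities along the bilayer normal $z$ (with $z = 0$ at the bilayer
center): the free-energy profile $\Delta G(z)$ (the potential of mean force,
PMF) and the local diffusion coefficient $D(z)$. The partition coefficient
at depth $z$ is the Boltzmann factor $K(z) = \exp(-\Delta G(z)/RT)$, and the
inhomogeneous solubility–diffusion model (ISDM) writes the total membrane
resistance as the integral of the local resistances,

$$ R \;=\; \frac{1}{P} \;=\; \int \frac{\exp(\Delta G(z)/RT)}{D(z)}\,dz, $$

with the permeability coefficient $P = 1/R$ (reported in cm/s;
1 nm/ps = $10^5$ cm/s). The ISDM assumes diffusive (overdamped) motion
along $z$ and local equilibrium in the orthogonal degrees of freedom; it is
known to underweight desorption for hydrophobic solutes, which motivates
carrying **two reference conventions** through the whole pipeline:

* `bulk_water`: $\Delta G = 0$ on the water plateau (the textbook ISDM);
* `global_minimum`: $\Delta G = 0$ at the solute's equilibrium position in
  the membrane, which re-weights the integral so that desorption dominates
  for strongly membrane-bound amphiphiles.

Because a PMF is only defined up to an additive constant, switching
convention multiplies every local resistance by one factor and therefore
rescales $P$ by exactly $\exp(\pm\Delta G_{\rm gap}/RT)$, where
$\Delta G_{\rm gap}$ is the water-plateau-to-minimum gap (the desorption
barrier). The package tests enforce this identity to machine precision. The
minimum convention also inflates the apparent resistance of the water
region — molecules with identical aqueous diffusion coefficients acquire
different water-phase resistances. This artifact is deliberately *not*
corrected; it is recorded in the result's notes so downstream consumers see
it.

### PMF estimation

Umbrella windows restrain the solute at depths $z_0$ (defaults: spacing
0.1 nm, harmonic force constant $k = 3000$ kJ mol$^{-1}$ nm$^{-2}$, giving a
bias width $\sqrt{RT/k} \approx 0.029$ nm at 298.15 K). `wham_solve()`
combines the window histograms by self-consistent iteration of the window
free energies. Numerical choices that matter:

* **Bin width, default 0.01 nm.** WHAM's histogram approximation is
  second-order in the bin width $h$ relative to the bias width. At
  $h = 0.02$ nm (about 1.4 bins per bias sigma) the residual quadrature
  bias on a harmonic test potential is $\approx 0.26$ kJ/mol RMS — larger
  than typical split-half noise — while $h = 0.01$ nm reduces it below
  0.09 kJ/mol and $h = 0.005$ nm brings the interior error to
  $\approx 0.014$ kJ/mol. The default is therefore 0.01 nm (about three
  bins per bias sigma).
* **Bin-averaged bias factor.** The Boltzmann factor of the harmonic bias
  is integrated analytically over each bin (a Gaussian-CDF difference)
  rather than evaluated at the bin center; mid-point evaluation biases the
  window free energies by $O(h^2 (k/RT)^2)$ per bin, and those errors
  compound across the chain of windows.
* **Convergence.** Tolerance $10^{-7}$ kJ/mol on the maximum change of any
  window free energy per sweep, with up to $10^5$ sweeps; this removes the
  iteration count as a result-affecting knob. The unbiased density is
  renormalized every sweep, which pins the arbitrary multiplicative scale
  of the self-consistent pair (density, window free energies) — without
  this the scale drifts geometrically and overflows. Non-convergence is a
  hard error carrying the last residual.
* **Coverage.** Windows whose histograms do not chain together cannot be
  combined: a run of three or more empty interior bins inside the
  window-center span aborts the solve with the uncovered interval. Sparse
  tail bins beyond the outermost window centers are merely dropped — the
  profile out there is a single-window tail extrapolation with
  $O(1$ kJ/mol$)$ noise regardless of sampling, which is also why recovery
  tests compare profiles over the window-center span only.
* **Profiles stay on the histogram grid.** No spline smoothing is applied
  to the stored profile, keeping the WHAM output auditable.

Uncertainties come from the standard split-half estimate: WHAM is re-solved
from the first and second halves of every window's series and the aligned
absolute difference is reported per grid point. Convergence is probed by
three truncation schemes (growing sampling time; growing discarded
equilibration; growing equilibration with a fixed-length analysis span),
all solved on the full-data grid so profiles are directly comparable.

Barrier extraction smooths the profile with a 0.3 nm moving average before
locating the equilibrium depth (raw PMFs are rugged and the raw argmin is
unstable); ties break toward smaller $|z|$ for determinism. The
translocation barrier is $G(0) - G(z_{\rm eq})$ and the desorption barrier
is the bulk-plateau mean (over $|z| \ge z_{\rm bulk}$, default 3.5 nm, the
inner edge of the outermost window band) minus $G(z_{\rm eq})$, both read
from the unsmoothed profile. Per-leaflet values are returned as well, which
is what matters when an asymmetric bilayer is sampled through the entire
membrane. A profile with no interior minimum is flagged degenerate and the
regime classification propagates that to "indeterminate".

### Local diffusion from force fluctuations

In a harmonically restrained window the static friction is the time
integral of the restraint-force fluctuation autocovariance divided by $RT$,
and $D(z_0) = RT/\xi$. Choices:

* **Biased ($1/N$) autocovariance**, evaluated by zero-padded FFT (agreeing
  with the direct $O(N^2)$ sum to machine precision). The biased
  normalization guarantees a positive-semidefinite estimate and a bounded
  integral.
* **Integration cutoff at the first zero crossing** of the ACF. A finite
  noisy ACF cannot be integrated to infinite time; truncating where the
  estimate first touches zero is the standard positive-plateau rule, and
  the cutoff actually used is recorded per window. For an
  Ornstein–Uhlenbeck series with variance $\sigma^2$ and correlation time
  $\tau$ the integral is $\sigma^2\tau$, and the estimator recovers
  $\xi = \sigma^2\tau/RT$ within a few percent at $10^6$ samples with
  $\Delta t = \tau/10$ (a small negative bias, under 2 %, comes from
  truncating the exponential tail at the crossing).
* **The restraint force is used as the fluctuating force.** This is the
  quantity available per window; it is an approximation whose validity
  requires the free-energy slope over the friction decay length to stay
  below $RT$ — well satisfied for the smooth profiles generated here.

### Membrane descriptors

The area decomposition attributes a fixed molecular volume to water
(0.0312 nm³) and cholesterol (0.593 nm³) and assigns cholesterol a
cross-section proportional to its volume share of the lipid slab,
$A_{Chol} = 2 A_{box} V_{Chol}/(V_{box} - N_W V_W)$, with the phospholipid
area carrying the remainder; the identity
$(1-x) N A_{PL} + x N A_{Chol} = 2 A_{box}$ then holds exactly, which the
tests verify over a thousand random compositions. Deuterium order
parameters, orientation histograms (degrees on $[0, 180]$, normal $+z$
unless overridden), chain elongation and transverse distances operate on
vectors and labeled positions supplied in the frame. The hydrogen-bond
count uses the common geometric criterion — donor–acceptor distance
$\le 0.35$ nm and hydrogen–donor–acceptor angle $\le 30^\circ$ — because no
single definition is universal; both cuts are exposed as arguments, and
each (donor, acceptor) pair counts once regardless of how many hydrogens
qualify.

## What the synthetic generator emulates — and what it does not

The generator provides every input the analysis consumes, with exactly
known ground truth:

* **PMF families.** $G(z)$ is a water plateau plus Gaussian interface wells
  (default at $\pm 1.7$ nm, width 0.25 nm), a central Gaussian feature
  (width 0.5 nm) and an optional narrow mid-plane dip (width 0.15 nm, as
  seen for several solutes in cholesterol-rich bilayers). The
  `center_barrier` parameter *is* the translocation barrier
  $G(0) - G(z_{\min})$ — the central amplitude is solved for it — and the
  desorption barrier is coupled affinely to the alkyl-chain carbon count
  (`intercept + slope * n`, default 10 + 2.5 n kJ/mol). A homologous family
  built this way shares its polar-group (translocation) barrier while the
  hydrophobic driving force grows with chain length, which is exactly the
  regime structure the trend tests probe. The functional form is a
  stand-in: real PMFs are empirical curves, and no claim is made that the
  shapes match any particular measured profile point-wise.
* **Window samples** are exact independent stationary draws from
  $\propto \exp(-(G + \text{bias})/RT)$ by inverse-CDF interpolation on a
  $10^{-3}$ nm grid — no Markov-chain burn-in or autocorrelation. Real MD
  window series are time-correlated; split-half errors on real data
  therefore measure an effective sample size, not the raw count, and the
  package deliberately applies no statistical-inefficiency weighting (an
  open choice documented here rather than hidden).
* **Force series** are exact discrete Ornstein–Uhlenbeck updates with
  stationary initialization, so the implied friction
  $\xi = \sigma^2\tau/RT$ is known in closed form. Real restraint forces
  have non-exponential short-time structure; the OU family tests the
  estimator, not the force field.
* **Membrane frames** place C–D vectors at the fixed tilt reproducing a
  target $S_{CD}$ with random azimuths, and an all-trans chain with a
  0.127 nm per-carbon rise. They are fixtures for the descriptor formulas,
  labeled synthetic, not parsed MD snapshots.

Consequently, a green test suite demonstrates the correctness of the
estimators and the integration chain under the stated statistical
assumptions; it does not validate any force field or sampling protocol.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (one per generator
call); re-running any pipeline with the same configuration reproduces its
output files byte for byte. The shipped checks use desk-scale problems
chosen once from the estimators' convergence behavior: $10^5$ samples for
single-window statistics (closed-form variance to 2 %), $41$ windows
$\times\,1.2\times10^5$ samples for PMF recovery (the window chain at
0.1 nm spacing and $k = 3000$ overlaps at $3.5\sigma$, so window-offset
noise performs a random walk along the chain and falls as $1/\sqrt{n}$;
this size puts the RMS recovery error near 0.1 kJ/mol), and $10^6$-step
force series for friction recovery within 10 %. The full synthetic pipeline
in `scripts/acceptance.R` (81 windows, 4000 samples each, 20000-step force
series per window) runs in about a minute on one CPU.

## Known limitations

* WHAM is the only estimator (no MBAR), and no autocorrelation-aware
  weighting of window samples is applied.
* The first-zero ACF cutoff slightly underestimates the friction integral
  (and thus overestimates $D$) when the ACF is strongly stretched; memory
  kernels and Bayesian $D(z)$ inference are out of scope.
* The ISDM itself — not this implementation — misranks strongly hydrophobic
  solutes under the bulk-water reference; the minimum-reference variant
  restores the qualitative chain-length trend at the cost of the water-phase
  artifact described above. Both are reported side by side rather than
  merged into a single "best" number.
* Integration bounds for the resistance integral are exposed as parameters
  (default: the full overlap of the free-energy and diffusion grids), since
  the "membrane span" of a real profile is itself a judgment call.
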