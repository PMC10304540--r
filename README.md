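# lipidperm

Membrane permeability of amphiphiles from umbrella-sampling data, in R.

Passive permeation of drug-like amphiphiles through a lipid bilayer is
governed by the free-energy profile ("potential of mean force", PMF) of the
solute along the bilayer normal *z* and by its depth-dependent diffusion
coefficient. `lipidperm` implements the complete desk-side analysis chain
used in molecular-dynamics permeation studies:

* **PMF reconstruction** from biased umbrella-sampling windows with the
  weighted histogram analysis method (WHAM), including split-half
  uncertainties, three convergence-scan schemes, leaflet symmetrization,
  re-referencing, and extraction of the equilibrium insertion depth and the
  desorption / translocation barriers;
* **local diffusion coefficients** D(z) from the autocorrelation of the
  restraint-force fluctuations: the static friction is
  ξ = (1/RT) ∫ ⟨ΔF(z,t)·ΔF(z,0)⟩ dt and D(z) = RT/ξ;
* **permeability coefficients** under the inhomogeneous solubility-diffusion
  model (ISDM),

      R = 1/P = ∫ exp(ΔG(z)/RT) / D(z) dz ,

  with the PMF zero set either in bulk water or at the solute's equilibrium
  position (the two conventions differ by a pure factor exp(−ΔG_gap/RT) in P
  and reverse the chain-length trend for a homologous amphiphile family),
  plus cumulative-resistance profiles, a three-region resistance
  decomposition, and classification of the rate-limiting step
  (translocation- vs desorption-limited);
* **membrane descriptors**: area decomposition of mixed
  phospholipid/cholesterol bilayers
  (A_Chol = 2·A_box·V_Chol/(V_box − N_W·V_W), with A_PL carrying the
  remainder so that (1−x)·N·A_PL + x·N·A_Chol = 2·A_box exactly), deuterium
  order parameters S_CD = ⟨(3cos²θ − 1)/2⟩, orientation histograms, chain
  elongation, transverse distances and geometric hydrogen-bond counts;
* **a synthetic-data generator** with exactly known ground truth: parametric
  PMF families whose desorption barrier grows affinely with the alkyl-chain
  carbon count, exact Boltzmann window sampling by inverse-CDF, stationary
  Ornstein–Uhlenbeck restraint-force series with prescribed friction, and
  idealized membrane frames;
* **plain-text I/O** (XVG-dialect time series, TSV profiles, JSON configs)
  and a one-call [`run_pipeline()`] driver plus a small command-line front
  end (`exec/lipidperm`).

## Worked example

Reconstruct the PMF of a synthetic C12 amphiphile (desorption barrier
10 + 2.5·12 = 40 kJ/mol, translocation barrier 25 kJ/mol by construction)
from 81 umbrella windows and compute its permeability under both reference
conventions, with a flat D = 10⁻³ nm²/ps:

```r
library(lipidperm)

model   <- make_pmf_model(chain_coupling = c(10, 2.5), n_carbons = 12,
                          center_barrier = 25)
z0s     <- seq(-4, 4, by = 0.1)
windows <- lapply(seq_along(z0s), function(i)
  sample_umbrella_window(model, z0s[i], k = 3000, n = 2000, seed = i))

profile <- set_reference(wham_solve(windows), "bulk_water")
extract_barriers(profile)
#> Barriers: z_eq = -1.69 nm, translocation 25.7 kJ/mol, desorption 40.7 kJ/mol

permeability(profile, 1e-3, reference = "bulk_water")
#> Permeability: P = 27.93 cm/s (R = 3580 ps/nm), reference = bulk_water, regime = desorption_limited
#>   resistance fractions: entrance 0.31, center 0.04, desorption 0.65

permeability(profile, 1e-3, reference = "global_minimum")
#> Permeability: P = 1.843e-06 cm/s (R = 5.427e+10 ps/nm), reference = global_minimum, regime = desorption_limited
#>   resistance fractions: entrance 0.31, center 0.04, desorption 0.65
#>   note: global-minimum reference offsets the whole profile, inflating the apparent resistance in the water phase
```

The recovered barriers match the generator's ground truth to within the
split-half sampling noise, and the two reference conventions differ by
exp(−40.7/RT) ≈ 10⁻⁷, as the additive-shift law requires. For a homologous
family (n = 4…16 carbons) the water-referenced P increases with chain length
while the minimum-referenced P decreases once desorption becomes
rate-limiting; `classify_regime()` reports the crossover.

The full pipeline — file reading, WHAM, uncertainties, diffusion,
permeability under both conventions, TSV/JSON outputs and a run log — is one
call:

```r
run_pipeline(pipeline_config(window_glob = "sim/window_*.xvg",
                             force_glob  = "sim/force_*.xvg",
                             outdir      = "out"))
```

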