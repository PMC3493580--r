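# tidytraj

Comparative analysis of protein and protein–ligand molecular-dynamics
trajectories, and the binding thermodynamics built on top of it — in a
tidyverse-native R package. `tidytraj` targets the standard workflow for
rationalising inhibitor activity on a flexible enzyme (the motivating case is
a matrix-metalloproteinase catalytic domain bound by non-zinc-binding
inhibitors in its S1′ pocket):

* **Fluctuation profiling** — per-frame RMSD, per-atom RMSF, time-averaged
  per-residue deviations and the ΔRMSD difference profile
  (RMSD<sub>residue,complex</sub> − RMSD<sub>residue,apo</sub>) that
  localises binding-induced structural perturbation; block standard errors
  from contiguous sub-trajectories.
* **Essential dynamics (ED)** — the covariance matrix of positional
  fluctuations C = ⟨(x−⟨x⟩)(x−⟨x⟩)ᵀ⟩, its eigenvalue spectrum and trace,
  projection onto the essential plane (first two eigenvectors),
  conformational-basin extraction with representative frames, and
  overlap coefficients between the conformational spaces sampled by
  different systems.
* **Interaction geometry** — geometric hydrogen-bond occupancy
  (donor–acceptor ≤ 0.35 nm, H–D–A ≤ 30° by default) and the π-stacking
  descriptors (r, φ, Ψ): centroid separation, elevation of the
  centroid–centroid vector over the reference ring plane (φ = 90° for
  face-to-face stacks), and the inter-normal angle (Ψ = 0° for parallel
  rings).
* **Thermodynamic integration (TI)** — ΔF = ∫₀¹ ⟨∂H/∂λ⟩ dλ by trapezoidal
  (or Simpson) quadrature with per-λ block errors propagated through the
  quadrature weights; relative binding free energies against a reference
  system; an enthalpy/entropy decomposition from two-temperature data,
  ΔΔS = −∂ΔΔG/∂T.
* **Tautomer linkage** — Boltzmann summation of conformer free energies
  (gas-phase + hydration) into a tautomeric equilibrium constant
  K = [a]/[b], the Cheng–Prusoff conversion Ki = IC50/(1+S/Km), and the
  linkage-cycle ratio of the two bound complexes,
  [complex·a]/[complex·b] = exp(−(ΔΔμ_a−ΔΔμ_b)/RT)·K.

Every analysis stage has a matching **synthetic-data generator with planted,
analytically known structure** (`gen_gaussian_traj()`, `gen_two_state_loop()`,
`gen_ring_pair_series()`, `gen_hbond_series()`, `gen_ti_samples()`), so the
whole pipeline is testable against closed-form oracles. Results are tibbles
that chain with the pipe; fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Recover a planted low-rank covariance by essential dynamics, integrate a
harmonic alchemical path with a known answer, and run the tautomer linkage
on the bundled conformer table:

```r
library(tidytraj)

## plant two internal modes (0.5 and 0.3 nm^2) on 50 atoms
V <- random_internal_modes(50, 2, seed = 7)
modes <- list(list(direction = V[, 1], variance = 0.5),
              list(direction = V[, 2], variance = 0.3))
trj <- gen_gaussian_traj(50, modes, iso_noise = 0.001,
                         n_frames = 5000, seed = 7)
build_covariance(trj)
#> <covariance_model> 50 atoms, 5000 frames, trace 0.9533 nm^2
#> leading eigenvalues (nm^2): 0.5032, 0.3079, 0.001364, 0.001338, 0.001333
```

The two leading eigenvalues sit at the planted variances (plus the 0.001 nm²
noise floor) and the rest collapse onto the noise floor — the spectrum reads
exactly like an enzyme with two dominant collective motions.

```r
## harmonic TI path: k 1 -> 4 kJ/(mol nm^2); exact answer (RT/2) ln 4 = 1.729
prof <- gen_ti_samples(k1 = 1, k2 = 4, temperature = 300,
                       n_per_lambda = 5000, seed = 7)
integrate_ti(prof)
#> Delta F = 1.733 +/- 0.00961 kJ/mol at 300 K

## tautomer equilibrium from conformer free energies, and the linkage cycle
tautomer_equilibrium(mmp2_conformer_table(), temperature = 300)
#> K ([a]/[b]) = 0.06062 at 300 K (delta mu = 6.992 kJ/mol)
bound_tautomer_ratio(0.21, ddmu_a = 16, ddmu_b = 0, temperature = 300)
#> [1] 0.0003438953
```

The TI estimate covers the closed form within one standard error. The last
call is the linkage worked example: with a free-solution tautomer constant
of 0.21 and relative binding free energies of 16 and 0 kJ/mol, the less
stable tautomer is essentially absent from the bound ensemble
(ratio ≈ 3.4×10⁻⁴).

A configuration-driven run of the full protocol (simulate → fluctuation →
ED → interactions → TI → tautomer → linkage) is available through
`validate_config()` / `run_pipeline()`; see the methods vignette
(`vignettes/tidytraj-methods.Rmd`) for the models, parameter choices and
limitations.

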