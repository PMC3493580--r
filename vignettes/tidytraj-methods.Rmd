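---
title: "Models and methods behind tidytraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tidytraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidytraj)
```

`tidytraj` implements the analysis layer of a comparative molecular-dynamics
study of ligand binding: fluctuation profiles, essential dynamics,
interaction-geometry descriptors, thermodynamic-integration free energies and
a tautomer-binding linkage cycle. This vignette explains the models, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Units, conventions and containers

All lengths are nanometres, times picoseconds, energies kJ/mol, temperatures
kelvin; the molar gas constant is R = 8.314462618 J/(mol K). PDB input and
output convert Å ↔ nm at the boundary, and a read→write→read cycle is
idempotent at the PDB's three-decimal Å precision (1e-4 nm). Frame and atom
indices are 1-based, as everywhere in R; residue ids are the 1-based PDB
numbers. A trajectory is an atom tibble plus a `frames × atoms × 3` array —
coordinates are deliberately *not* stored long, since a typical problem here
(20 000 frames × 100 atoms) would be an 6-million-row table for no analytic
gain; everything the user consumes downstream is a tibble.

## Superposition and fluctuation profiles

Rigid-body superposition solves the least-squares Kabsch problem with the
determinant correction, so reflections are never returned even for chiral
coordinate sets; fits are mass-unweighted, which is exact for the usual
Cα-only selections and a negligible approximation for heavy-atom ligand
selections. Fewer than three non-collinear fit atoms is a degeneracy error.

RMSF and the covariance model superpose frames on their *iterated mean*: fit
all frames to a running mean, recompute the mean, repeat until the mean moves
by less than 1e-9 nm (at most 10 iterations). The tight tolerance is what
makes two cross-module identities hold numerically rather than
approximately: trace(C) = Σᵢ RMSFᵢ² on a shared selection, and
var(projectionⱼ) = eigenvalueⱼ for the model's own trajectory. A
fit-to-reference mode is available for RMSD series, whose reference defaults
to the first frame (the simulation starting structure); the fit and measure
selections are separate arguments everywhere, because for ligand analyses it
is often right to fit on the receptor and measure on the ligand, and no
single convention suits all systems.

ΔRMSD profiles are the elementwise difference of two *time-averaged*
per-residue deviation profiles aligned by residue id (a mismatch is an error
listing the offending residues). Time-averaging, rather than taking a final
frame, is the stabler reading when the underlying series has not fully
plateaued; it is the package's choice and a per-frame profile can be built
from `rmsd_series()` if wanted.

Block standard errors split a series into `n_blocks` contiguous equal blocks
(default 3 — the three-subportion convention for correlated MD data),
dropping any remainder frames at the tail so blocks stay equal-weight, and
report sd(block means)/√n_blocks.

## Essential dynamics

The covariance matrix is the time average C = ⟨(x−⟨x⟩)(x−⟨x⟩)ᵀ⟩ (divisor n,
matching the time-average definition of the projections' variance),
mass-unweighted, on a user selection of at least two atoms. The symmetric
eigensolver is used and eigenvalues below 1e-12 nm² are clamped to zero;
`tidy()` reports the first 20 by default, the informative head of a typical
spectrum. Cross-system comparisons build *one* model on concatenated
trajectories (`concat_trajectories()`) and project each system separately,
so every cloud lives on the same essential plane; the overlap coefficient
Σ min(fᵢ, fⱼ) of the shared 2D histograms is 1 for identical sampling and 0
for disjoint supports.

Basin extraction histograms the essential-plane projection on a square grid
(bounding box padded 5%, 50 bins per axis by default). Raw occupancy
histograms of finite samples carry Poisson noise whose local maxima are not
conformational basins; the histogram is therefore smoothed twice with a 3×3
box filter before maxima detection, and candidates below 20% of the global
smoothed maximum (`min_density`) are discarded. Remaining maxima must be at
least 2 cells apart (ties broken by lexicographic cell order, for
determinism); each basin reports the fraction of frames nearest its centre
and the frame closest to the centre, the natural starting structure for a
free-energy calculation. Asking for more basins than the density supports
returns what exists, with a warning and an `underpopulated` flag — an
honesty contract, not an error.

## Interaction geometry

A hydrogen bond exists in a frame when the donor–acceptor distance is at
most 0.35 nm and the H–D–A angle at most 30°, the widely used geometric
default of common MD analysis tooling; both cutoffs are configurable through
`hbond_criterion()`. A hydrogen coincident with its donor is a definition
error, not a zero.

Ring geometry uses the unweighted centroid (ring atoms are near-equal mass)
and the least-squares plane normal — the smallest principal axis of the ring
atoms' scatter — with a sign-free contract: all consumers take |dot
products|. For rings A (reference, receptor side) and B, the stacking
descriptors are r = |c_B − c_A|; φ = 90° − arccos(|u·n_A|), the elevation of
the centroid–centroid unit vector u over A's plane, so facing rings give
φ = 90° and coplanar side-by-side rings φ = 0°; and Ψ = arccos(|n_A·n_B|) ∈
[0°, 90°], zero for parallel planes. φ is pinned to the *first* ring's plane;
swapping the rings leaves r and Ψ unchanged by construction. The published
verbal definitions of such shift angles are often ambiguous; this
elevation-angle reading is fixed by its two anchors (φ = 90° face-to-face,
φ = 0° in-plane) and is exactly inverted by the ring-pair generator, which
is the package's operational definition.

A stacking interaction is counted "formed" inside the box r ≤ 0.55 nm,
φ ≥ 60°, Ψ ≤ 30°. These thresholds delimit near-face-to-face, near-parallel
geometries at van-der-Waals contact; published analyses typically draw this
region graphically rather than numerically, so the defaults are package
choices — they are configurable, and the occupancy result carries them as
metadata so downstream reports are self-describing.

## Thermodynamic integration and the linkage cycle

`integrate_ti()` evaluates ΔF = ∫₀¹ ⟨∂H/∂λ⟩ dλ with the trapezoidal rule on
the profile's own grid — robust on the non-uniform λ spacings practitioners
actually use; Simpson's rule is available for uniform odd-length grids. Each
per-λ mean carries a block standard error (3 blocks by default, configurable)
and the result's error is √(Σ w_k² SE_k²) with the quadrature weights w_k.
Soft-core metadata (α = 1.51, σ = 0.3 nm, Δλ = 0.001) is carried for
provenance only; the package never evaluates the alchemical potential
itself — it consumes finished ∂H/∂λ tables (two-column text, `#`/`@`
comments ignored, XVG-compatible).

Relative binding free energies subtract a reference system, propagate errors
in quadrature and report the reference as exactly 0 ± 0. The two-temperature
decomposition uses the finite difference ΔΔS = −(ΔΔG(T₂)−ΔΔG(T₁))/(T₂−T₁)
and ΔΔH = ΔΔG(T₁) + T₁ΔΔS; its `consistent_with_zero_entropy` flag is a
1-SE statement — with typical TI uncertainties this is a qualitative
instrument, which is precisely its intended use: deciding whether affinity
differences must be read as enthalpic.

The tautomer equilibrium combines conformer free energies
G = Δμ°gas + Δμ°hydration per tautomer by Boltzmann summation,
μ_X = −RT ln Σᵢ exp(−Gᵢ/RT), computed with log-sum-exp so arbitrarily deep
or shallow conformers cannot overflow; an unreachable conformer (G → +∞)
provably leaves K unchanged. Gas-phase values are consumed as supplied (1 M
standard state); no additional standard-state correction is applied. On the
bundled six-conformer table this summation gives K = [a]/[b] ≈ 0.061
(Δμ ≈ 7.0 kJ/mol). Larger constants (≈0.2) can be quoted for the same data
under other combination conventions; `tautomer_equilibrium()` implements
exactly the model above and never rescales its output, and the linkage
worked example therefore takes its equilibrium constant as an explicit
input. The linkage cycle itself is
[complex·a]/[complex·b] = exp(−(ΔΔμ_a−ΔΔμ_b)/RT)·K, monotone increasing in
K and decreasing in the binding gap.

## What the synthetic generators emulate — and what they do not

Each generator plants the one statistical feature its paired analysis
measures, with everything else held ideal:

* `gen_gaussian_traj()` draws frames as mean + Σ aₖvₖ + noise with
  aₖ ~ N(0, varianceₖ) along orthonormal *internal* directions
  (`random_internal_modes()` orthogonalises against the six rigid-body
  degrees of freedom, as collective modes of a real molecule are), so the
  population covariance — and hence the ED oracle — is exactly
  Σ varianceₖ vₖvₖᵀ + iso_noise·I.
* `gen_two_state_loop()` mixes two jittered centres with Bernoulli state
  draws and returns its labels, so basin extraction is scored against truth
  without a clustering oracle.
* `gen_ring_pair_series()` builds rigid hexagons/pentagons (side 0.14 /
  0.137 nm, geometric conveniences mimicking six- and five-membered
  aromatics) whose (r, φ, Ψ) follow the schedule exactly — the
  generator/measurer pair is an inverse pair to 1e-6.
* `gen_hbond_series()` places a linear D–H···A triple at 0.28 nm when
  formed and 0.42 nm otherwise — margins of 0.07 nm inside and 0.05 nm
  outside the default criterion.
* `gen_ti_samples()` uses the harmonic λ-coupling k(λ) = (1−λ)k₁ + λk₂,
  for which ∂H/∂λ = ½(k₂−k₁)x², x ~ N(0, RT/k(λ)), and
  ΔF = (RT/2) ln(k₂/k₁) in closed form.

Every generator is a bit-reproducible function of one integer seed with no
hidden global state.

What passing these tests does *not* show: the generators have no
force-field energetics, no solvent, no autocorrelation in time (frames are
i.i.d., so block errors on synthetic data are conservative relative to real
correlated trajectories), no anharmonicity in the TI path, and no
periodic-boundary effects. Recovery of planted parameters validates the
*estimators*; it cannot validate a force field or a sampling protocol.

## Problem sizes and numerical tolerances

The test suite and acceptance script use the sizes at which the planted
effects are resolvable with comfortable margins: 20 000 frames × 100 atoms
for eigenvalue/eigenvector recovery (top-2 eigenvalues within 5%, angles
below 5°), 10 000 frames for two-state basin scoring (≥99% label
agreement), 21 λ × 5000 samples for stochastic TI (within 3 propagated SE
of the closed form) and 101 points for noise-free quadrature (error below
1e-3 kJ/mol, consistent with the h² trapezoid bound), 2000 frames for
hydrogen-bond occupancy (±0.03). Degenerate inputs error early and
specifically: empty selections, collinear rings, coincident ring centres,
zero two-state displacement, non-orthogonal planted modes, λ grids not
spanning [0, 1], donors without hydrogens.

## The pipeline

`validate_config()` reads one YAML/JSON document and reports *all*
validation failures at once, by field name. `run_pipeline()` executes the
requested stages in dependency order — only `linkage` depends on another
stage (`tautomer`, for its equilibrium constant); a failing stage is
recorded and aborts its dependents while independent stages complete, the
report is always written, and the run is byte-reproducible for a fixed
config and seed. Provenance (package version, seed, stage list, config
hash) accompanies every report.

## Known limitations

Binary trajectory formats, periodic-boundary unwrapping and topology
perception are out of scope (multi-model PDB is the interchange format);
covariance analysis is mass-unweighted and offers no quasi-harmonic entropy;
the basin extractor is a histogram-mode method — two basins closer than two
grid cells merge, and its populations depend (weakly) on the bin count;
stacking "formed" thresholds are conventions, not physics; the entropy
decomposition assumes ΔΔS constant over the temperature interval; and the
TI module never checks that the supplied ∂H/∂λ samples are equilibrated —
that responsibility stays with the simulation engine that produced them.
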