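---
title: "Modeling polarization-resolved 2D spectroscopy of helical cylindrical aggregates"
author: "excitube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling polarization-resolved 2D spectroscopy of helical cylindrical aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitube)
```

## The scientific problem

Chlorosomes, the light-harvesting organelles of green bacteria, are
self-assembled cylindrical aggregates of bacteriochlorophyll *c*
molecules.  Their optical properties are collective: the tightly packed
transition dipoles couple into delocalized Frenkel excitons whose
polarization and dynamics depend on how the molecular sheet is rolled
into a cylinder.  Two helicities have been proposed in the literature.
In one, the molecular transition dipoles end up nearly parallel to the
cylinder axis (mean angle β ≈ 18°); in the other they sit near the magic
angle (β ≈ 54°).  The package simulates how this single structural
difference changes linear absorption, linear dichroism, and — most
discriminating — the ultrafast anisotropy measured by
polarization-resolved two-dimensional electronic spectroscopy (2D ES):
low-helicity cylinders keep the fundamental anisotropy r ≈ 0.4 over
sub-picosecond waiting times, while high-helicity cylinders start near
r ≈ 0.3 and decay, because energy transfers between exciton states with
different transition-dipole directions within one cylinder.

## Model

### Geometry

A cylinder is built by rolling a two-dimensional Bravais lattice of
dipole-carrying sites (`lattice_spec()`, `cylinder_spec()`,
`build_cylinder()`).  The chiral angle δ selects the in-sheet direction
that wraps around the circumference.  The realized rolling direction is
the integer lattice (chiral) vector closest in direction to δ with
length near the target circumference 2πR, so the wrapped lattice closes
seamlessly; the radius is re-derived from that vector.  Dipoles are
carried by the local tangent frame, so the angle β between each dipole
and the cylinder axis is fixed by δ and the in-sheet dipole angle
(`beta_angles()`, `summarize_beta()`; β is folded to [0°, 90°] because a
transition dipole has no sign).

Three presets are provided (`preset_cylinder()`).  `"system1-like"`
(δ = 49.6°) targets β = 18 ± 7°; `"system2-like"` (δ = 112.3°) targets
β = 54 ± 5°; `"homogeneous-test"` is a disorder-free achiral cylinder
whose exact Bloch structure (one axially polarized k₂ = 0 band, a
degenerate perpendicular k₂ = ±1 pair) is used for diagnostics
(`band_polarization()`).  Because the atomistic unit cell behind the
published structures is not available, the preset lattices are
*calibrated surrogates*: their spacings and dipole angles were chosen
once so that (i) the rolled β statistics match the targets, and (ii) for
the high-helicity preset the parallel and perpendicular optical
components overlap spectrally, which is the defining feature of that
organization.  On a cylinder with β ≈ 54° the direct azimuthal coupling
is necessarily J-type (negative), which pushes the perpendicular band
above the parallel one; spectral overlap requires an H-type (positive)
coupling chain at a large angle to the dipole with a substantial
azimuthal component, which the 7.7/7.5 Å, γ = 60° lattice provides.
Per-molecule Gaussian orientational jitter (σ = 8° and 5° for the two
presets) emulates the molecular-scale disorder that molecular-dynamics
sampling would produce; it reproduces the published spreads σ_β.

### Site-energy bath

Nuclear dynamics enter only through stochastic site-energy trajectories
Δω_n(t) (`bath_spec()`, `generate_site_energies()`).  Each site is an
independent Ornstein–Uhlenbeck process with mean −300 cm⁻¹, stationary
standard deviation σ_dyn = 200 cm⁻¹, correlation time τ_c = 50 fs, plus
a frozen Gaussian offset of σ_stat = 150 cm⁻¹, discretized exactly
(`x[t+1] = ρ x[t] + sqrt(1−ρ²) σ ξ`, ρ = e^(−dt/τ_c)), so there is no
Euler bias and the process is stationary from the first frame.  These
four numbers are calibration choices, not measured values; the sources
they stand in for (molecular dynamics plus electrostatic-shift
calculations) report neither amplitude nor correlation time directly.
Sites are uncorrelated, and dipole orientations are frozen during the
dynamics — two deliberate simplifications relative to an atomistic
treatment.

### Hamiltonian

The single-exciton Frenkel Hamiltonian has diagonal ω₀ + Δω_n(t) with
ω₀ = 15390 cm⁻¹ (the Q_y transition of the isolated chromophore) and
static point-dipole couplings J_mn = C·κ_mn·μ²/R³ with μ = 5.48 D and
C = 5034.12 cm⁻¹·Å³·D⁻² (`point_dipole_coupling()`,
`build_hamiltonian_trajectory()`).  No distance cutoff is applied by
default, so small-system results are exact.  The doubly excited manifold
uses hard-core (Paulion) statistics — each molecule can be excited only
once, with no biexciton binding shift — and is built on demand in the
unordered-pair basis (`two_exciton_hamiltonian()`); it is capped at 150
sites (11 175 pair states) because excited-state absorption is only
computed at small scale.

### Propagation

Wavefunctions are propagated in the numerical-integration (NISE) scheme:
the Hamiltonian is frozen over each 4 fs interval and the exact
propagator `exp(−i 2πc H dt)` is built by eigendecomposition
(`step_propagator()`, `propagate()`).  Amplitudes evolve under the
classical bath with no detailed balance (the high-temperature limit), so
a fluctuating resonant dimer equilibrates to equal site populations.
Internally all energies are shifted by ω₀ (2ω₀ in the pair space) into a
rotating frame; this is pure numerical conditioning and is undone on the
frequency axes.

### Response functions

Linear absorption is the Fourier transform of the two-point
transition-dipole correlation function averaged over staggered
trajectory start points (`linear_response()`); the parallel and
perpendicular channels use the cylinder-frame z versus x, y dipole
components, and `ld_components()` gives the stick-spectrum decomposition
I∥(ω) = Σ M²_{i,z}, I⊥(ω) = ½ Σ (M²_{i,x} + M²_{i,y}) from
`eigendecompose_frame()` (which also enforces the oscillator-strength
sum rule).

Third-order response (`twod_response()`) includes ground-state bleach
and stimulated emission through single-exciton propagation over
(t₁, t₂, t₃) and excited-state absorption through pair-space propagation
during t₃, for both rephasing and nonrephasing time orderings.  The
isotropic orientational average is analytic: the all-parallel ⟨ZZZZ⟩ and
pump-perpendicular-probe ⟨ZZXX⟩ lab schemes are linear combinations of
molecular-frame tensor contractions with weights (1,1,1)/15 and
(4,−1,−1)/30, so no orientation sampling is needed and a rigid rotation
of the aggregate leaves every channel invariant to machine precision.
The hot loop is implemented in C++ (RcppArmadillo); an independent
sum-over-states oracle written in R validates every pathway on static
Hamiltonians in the test suite.

The absorptive 2D map (`spectrum_2d()`) is the real part of the
rephasing signal (ω₁ sign-flipped) plus the nonrephasing signal after
four-fold zero padding, with the t = 0 samples half-weighted (trapezoid
endpoint rule).  For presentation, spectra are conventionally normalized
to the maximum of the parallel-scheme map; anisotropy is always computed
from the two schemes on their common raw scale.

### Apodization

Mesoscale disorder and processes not captured by the explicit bath are
folded in by apodizing the response (`apodize()`): an exponential
`exp(−(t₁+t₃)/τ_homo)` with τ_homo = 300 fs and a Gaussian with
τ_inhomo = 166 fs.  The exponential convention is chosen so that the
linear lineshape is a Lorentzian of full width 1/(π c τ_homo) =
35.4 cm⁻¹ — the pure-dephasing convention in which τ_homo is the
coherence decay time of the signal field; the Gaussian
`exp(−t²/(2 τ_inhomo²))` gives a 75.3 cm⁻¹ full width.  Whether the
Gaussian should act on t₁ and t₃ independently or on their
combinations (t₁ − t₃ for rephasing, t₁ + t₃ for nonrephasing, as
echo physics of frozen mesoscale disorder would imply) is not uniquely
determined; both are implemented (`mode = "independent"`, the default,
and `mode = "correlated"`).

### Anisotropy

`anisotropy_map()` forms r = (I∥ − I⊥)/(I∥ + 2 I⊥) pointwise — the
standard pump-probe definition, consistent with the single-dipole
maximum r = 0.4 and the ⟨ZZZZ⟩/⟨ZZXX⟩ = 3 ratio — and masks points where
the isotropic denominator is below 5% of its maximum, because spectral
overlap of oppositely signed signals makes the ratio meaningless there.
`anisotropy_spectrum_diagonal()` samples the ω₁ = ω₃ diagonal,
`anisotropy_trace()` follows a fixed spectral point across waiting
times, and `fit_exponential()` fits r(t₂) = r_∞ + (r₀ − r_∞)e^(−t₂/τ).

**Fit window.**  The fit excludes t₂ < 24 fs (one waiting-time step) by
default.  At t₂ = 0 the second and third pulses overlap and coherences
between excitons of different orientation contribute sharply; for
θ > 54.7° between state dipoles their ⟨ZZXX⟩ weight,
(3cos²θ − 1)/30, is negative, which can push the measured r above 0.4.
On desk-scale aggregates (N ≲ 100) this transient is pronounced at the
superradiant band-bottom state and decays within one 24 fs step; fitting
through it drives τ to zero and makes the problem degenerate.  The
population (energy-transfer) decay the exponential is meant to quantify
starts after the pulse-overlap region, so the default window starts
there; `t2_min = 0` restores the full-trace fit.  A fitted amplitude
below 0.02 is flagged as "no decay".

## Study conditions and problem sizes

All demonstration and validation runs use single cylinders of roughly
60–90 molecules, coherence times up to 196 fs on a 4 fs grid, waiting
times 0–336 fs in 24 fs steps, responses averaged over 4–8 trajectory
start points (spaced ≥ 64 fs, beyond the bath correlation time) and 3–8
independent bath/disorder realizations.  These sizes resolve the
mechanism — flat r(t₂) ≈ 0.4 for the low-helicity preset, r ≈ 0.3 with a
slow decay for the high-helicity one, and a ≥ 40% linewidth contrast —
within minutes on one core.  They are far from the 10⁴-molecule,
MD-driven regime of full-scale studies: absolute peak positions and
widths, the exact shape of the anisotropy spectrum, and the literal
t₂ = 0 anisotropy at the band maximum (which is inflated by the
small-system coherence transient discussed above) should not be read
quantitatively.  What the passing tests do show is that every building
block is exact where an exact answer exists, and that the
helicity-controls-anisotropy-decay mechanism survives aggressive
coarse-graining.

## Numerical choices

* Exact OU discretization (no integration bias); all random stages are
  seeded and bit-reproducible.
* Propagators by full eigendecomposition per 4 fs frame — exact within
  the piecewise-constant approximation; unitarity ~1e−15, so norms are
  conserved to 1e−10 over hundreds of steps.
* Fourier transforms use half-weighted t = 0 samples and four-fold zero
  padding; frequency axes are exact bin frequencies shifted back by ω₀.
* The chiral vector search accepts a ±30% circumference mismatch and up
  to 5° of chiral-angle mismatch before erroring; the realized angle and
  radius are stored on the aggregate.
* Degenerate inputs error early with informative messages (coincident
  sites, non-Hermitian frames, trajectories too short for the requested
  sampling, ESA beyond the pair-space cap, masked trace points).

## Known limitations

* Site energies are spatially uncorrelated; hydrogen-bond-class
  correlations seen in atomistic work are an extension point.
* Couplings are static point dipoles on a frozen geometry; extended
  dipoles, transition charges, and coupling fluctuations are out of
  scope.
* Single cylinders only; the concentric multi-wall architecture and
  inter-cylinder transfer (≈ 1 ps and slower) are not modeled, which is
  acceptable for sub-picosecond observables.
* The high-temperature limit has no detailed balance: long-time
  populations equalize rather than thermalize, so only ultrafast
  dynamics should be interpreted.
* Impulsive limit: no finite pulse envelopes; circular dichroism and
  cross-polarized schemes beyond ⟨ZZZZ⟩/⟨ZZXX⟩ are not implemented.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(preset = "system2-like", n_molecules = 70,
                       n_samples = 4, n_realizations = 3, seed = 1,
                       out_dir = "run_system2")
manifest <- run_pipeline(cfg)
res <- attr(manifest, "results")
res$trace          # r(t2) at the maximum-intensity point, with fit
```

The manifest lists every artifact (geometry, site energies, linear and
2D spectra, anisotropy diagonal and trace, resolved configuration) with
MD5 checksums; rerunning the same configuration and seed reproduces all
scientific artifacts bit for bit.
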