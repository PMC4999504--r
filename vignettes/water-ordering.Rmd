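---
title: "Water ordering and peptide-amphiphile self-assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water ordering and peptide-amphiphile self-assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrafibre)
```

# The scientific problem

Peptide amphiphiles (PAs) couple a hydrophobic alkyl tail (here a palmitoyl
C16 chain) to a short peptide head group (an AHL~3~K~3~ sequence), and in
water they self-assemble hierarchically: monomers collapse into spherical
micelles, micelles fuse into cylindrical nanofibres, and fibres bundle into
hexagonally packed networks. The hypothesis this package is built to
examine is that *interfacial water* drives both transitions: cage-like
water around the hydrophobic tails must break for micelles to form
(hydrophobic collapse), while increasingly ordered water around the
hydrophilic lysine/histidine head groups stabilises the fibre phase before
any β-sheet network exists.

`hydrafibre` supplies the full measurement chain for that programme at desk
scale: readers for the common MD file formats, a periodic-boundary-aware
selection language, water-structure order parameters, vibrational spectra,
residence times, an aggregate census with micelle/fibre classification,
atomistic↔coarse-grained (CG) coupling with density-targeted water
reinsertion, and umbrella-sampling free energies. Because no reference
trajectories are distributed, every analysis is validated against *seeded
synthetic generators* that emulate the statistical structure the analyses
assume — ideal gases, perfect lattices, hydration shells, micelles, fibre
bundles, harmonic oscillators and Langevin walkers.

Units are fixed package-wide: Ångström, picosecond, amu, Kelvin, kcal/mol,
cm^-1^, and g/cc for densities. Boxes are orthorhombic; triclinic input is
rejected explicitly, and every distance in the package goes through the
minimum-image convention.

# Structural metrics of water

## Radial distribution functions

`compute_rdf()` histograms minimum-image pair distances and normalises by
the ideal-gas shell count, `g(r) = n(r) / (N_f n_a ρ_b 4πr²dr)`. Self
pairs are always excluded and intramolecular pairs are excluded by default
(a flag restores them). `r_max` may not exceed half the shortest box edge;
asking for more is a minimum-image violation and an error rather than a
silent bias. On the hydration-shell generator (first shell of 4 waters at
2.85 Å, second of 12 at 5.0 Å — the hydrogen-bonding distances of water
around polar head-group atoms) the first maximum of the site–oxygen RDF
recovers the generator radius to within one bin over shell radii 2.5–3.5 Å.

## Orientational order: Steinhardt Q6

For each particle *i* with neighbour unit vectors *r̂~ij~*,

q6(i) = sqrt( (4π/13) Σ~m~ | ⟨Y~6m~(r̂~ij~)⟩~j~ |² ),

with the spherical harmonics evaluated from associated Legendre
polynomials. The reported series is the per-particle average per frame;
`global = TRUE` instead averages the q~6m~ vectors over all bonds first
(the ensemble variant), since published work is not always explicit about
which of the two is meant. The neighbour convention (cutoff, default
3.5 Å for atomistic water oxygens and ~6.5 Å recommended for CG beads, or
`k_nearest`) is recorded in every result object. Perfect lattices give the
textbook constants (FCC ≈ 0.5745, SC ≈ 0.3536) and many uniformly random
bond directions annihilate the spherical-harmonic average (q6 < 0.1). The
test-suite oracle evaluates q6 through the Legendre addition theorem,
q6² = N^-2^ Σ~jk~ P~6~(r̂~ij~·r̂~ik~), a fully independent code path.

## Tetrahedral order

`compute_tetrahedral_order()` uses the Errington–Debenedetti form over the
four nearest minimum-image neighbours,
q = 1 − (3/8) Σ~j<k~ (cos ψ~jk~ + 1/3)². It is exactly 1 on the
diamond/cubic-ice lattice, averages 0 over uniformly random neighbour
directions, and reaches −3 in the fully degenerate case of four collinear
neighbours (all six pair cosines equal 1, so q = 1 − (3/8)·6·(4/3)² = −3).
A `pool` argument lets the four neighbours be drawn from a wider selection
than the particles being scored, which is how one scores a single tagged
molecule against the full solvent.

## Translational order

t = (1/ξ~c~) ∫~0~^ξc^ |g(ξ) − 1| dξ with ξ = r·ρ^1/3^ and ξ~c~ = 2.843 (a
conventional reduced cutoff), integrated trapezoidally on the RDF grid.
One caveat is documented rather than hidden: because the integrand is
rectified, sampling noise biases t upward, so a finite ideal-gas sample
never reaches 0 (about 0.16 at 600 particles in the suite's fixture). The
meaningful statements, and the ones the tests assert, are relative: gas ≪
jittered lattice < perfect crystal, and t falls monotonically as generator
jitter grows.

## Hydrogen bonds and shells

`find_hbonds()` applies the common geometric criterion — donor–acceptor
distance ≤ 3.5 Å and H–donor–acceptor angle ≤ 30°, both configurable since
conventions differ across force fields — with hydrogens taken from the
topology's bond list. The selection language's `within` operator
("`group water within 5.0 of group hydrophilic_head`") completes hits to
whole molecules of the left operand, so a water whose oxygen is inside the
shell contributes all three atoms; this matches how proximal-water shells
are used downstream (VDOS of shell hydrogens, residence of shell
molecules).

# Dynamics and spectra

`compute_vacf()` averages `⟨v_i(t)·v_i(t+τ)⟩` over atoms and all valid
time origins (FFT-accelerated) and normalises C(0) = 1. The vibrational
density of states is the discrete cosine transform of the (Hann-windowed)
VACF, with the wavenumber axis ν~k~ = k/(cT) and resolution 1/(cT) — the
stated transform-of-the-autocorrelation route rather than a direct
velocity periodogram, so windowing choices are explicit. On
harmonic-oscillator trajectories the peak position is recovered within one
resolution element across 400–3400 cm^-1^, covering the libration, bend
and O–H stretch bands (reported by default as 300–1,100, 1,500–1,800 and
2,800–3,800 cm^-1^; the band edges are conventions, not measurements).
Physically, a *red shift* of the O–H stretch peak signals stronger, more
ordered hydrogen bonding of proximal water; `band_metrics()` measures such
shifts differentially on pairs of spectra with a parabolic peak
interpolation. Absolute stretch positions depend on the water force field
and are deliberately out of scope for synthetic validation.

Residence times use the intermittent survival function: a molecule inside
a region at an origin survives lag τ if it stays continuously inside,
tolerating excursions up to `allowed_blip` frames (default 2, a
recrossing tolerance). Origins are restricted to frames where the whole
lag window is observable; that fixed-origin-window estimator is
nonincreasing by construction and equals 1 identically for molecules that
never leave, whereas per-lag renormalisation can rise under
end-of-trajectory censoring. τ comes from a least-squares exponential fit
over S ≥ 0.01. The quantitative fixture stores harmonic Langevin walkers
every ~4 relaxation times so occupancy is effectively memoryless; the
fitted τ then matches an independent transition-counting estimate of the
escape rate within 15%. A diffusive escape from a flat well is *not*
single-exponential, which is why the calibrated fixture is the memoryless
one.

# Aggregate census

Molecules are clustered by single-linkage over minimum-image bead
contacts (default cutoff 6.0 Å for CG beads, 4.5 Å for atomistic carbons;
always echoed in the result). Labels are deterministic: clusters ordered
by size, ties broken by lowest molecule id. An aggregate is classified as
a **fibre** when its extent along its principal axis reaches 90% of the
box edge — the operational meaning of "periodic-spanning", since the
paper's fibres run through the periodic boundary — and as a **micelle**
otherwise. The axis is estimated from the tail-bead core: head beads
spread radially and would tilt a whole-aggregate principal component by
several degrees. Fibre metrics are the linear density (PAs per nm of
axial box length; 50 PAs in a 45.5 Å box give 10.99 ≈ 11 per nm) and a
diameter defined as twice the 95th percentile of member radial distances
(≈ 50 Å for the default geometry). `lattice_spacing()` reports
minimum-image nearest-neighbour centroid distances and a coordination
count within 1.2× the minimum spacing.

Ramachandran analysis computes φ = dihedral(C′, N, Cα, C) and
ψ = dihedral(N, Cα, C, N′) in the IUPAC sign convention and labels
residues from a configurable region table. Only the polyproline-II box is
anchored to a literature value — centred at (−65°, +145°) with 25°
half-widths — because P~II~ is the extended, water-exposed conformation
PAs adopt before β-sheet formation; the α/β boxes follow common
conventions. Chirality is the sign of the N–Cα–C–Cβ improper dihedral,
with the convention fixed so ideal L-alanine geometry returns `"L"`
(negative improper); mirroring coordinates flips every label, and
back-mapping from CG beads can legitimately produce D labels since no
chirality restraint is applied by default.

# Multiscale coupling

`forward_map()` computes mass-weighted bead centres after unwrapping each
member group about its first atom (groups whose unwrapped extent exceeds
half the box are rejected as ill-defined). `back_map()` places template
atoms under a random rigid rotation plus Gaussian jitter (σ = 0.3 Å) and
then shifts the group rigidly so its mass-weighted centre coincides with
the bead *exactly* — the centre-of-mass restraint is a projection, so
forward∘backward round trips are exact to numerical precision and do not
drift over repeated cycles. The shipped 12-bead PA map (4 tail + 8 head
beads, 72 amu each) and its back-mapping templates are a documented
synthetic stand-in; the TSV map file format is the real contract, and a
CG water bead represents 4 molecules by default (the usual MARTINI ratio).

`reinsert_water()` implements the stage-3 solvation strategy: rigid
3-site waters are placed by rejection sampling with a hard 2.4 Å oxygen
exclusion (compiled cell-list acceptance), region targets first — e.g.
1.15 g/cc in the channel *between* two fibres, emulating the densified
first hydration shell of ordered interfacial water — then the rest of the
box outside the target regions until the box mean is 1.0 g/cc. "Between
the fibres" is operationalised as the set of points farther than one
fibre radius from every axis but within one radius of the segment network
joining neighbouring axes; its volume is computed by seeded Monte-Carlo
integration. Placement guarantees geometry only: the subsequent
force-field relaxation that a simulation campaign would run is out of
scope, and no energy criterion is applied.

# Free energies

`wham()` solves the standard weighted-histogram self-consistency
equations with k~B~ = 0.0019872041 kcal/mol/K, initial f~i~ = 0,
tolerance 10^-8^ kcal/mol on the window free energies, 10^5^ iteration
cap, a 5-sample occupancy floor per bin, and an explicit overlap check
between centre-adjacent windows. All windows must share one temperature
(atomistic and CG stages are simulated at different temperatures, so
mixing them in one solve is a user error the function refuses).
Uncertainties come from a seeded block bootstrap (20 blocks, 200
resamples by default). Validation is entirely against analytic
potentials sampled by the package's own overdamped Langevin integrator:
a harmonic PMF is recovered to < 0.1 kcal/mol RMS and a 2 kcal/mol
quartic double-well barrier to within 15%.

`decompose_pmf()` implements the two-temperature finite difference:
ΔS(ξ) = −[W(ξ,T₂) − W(ξ,T₁)]/(T₂−T₁), reported at T̄ with
ΔH = W(ξ,T̄) + T̄ΔS, so W = ΔH − T̄ΔS holds exactly on the grid. A
temperature-independent profile gives ΔS ≡ 0; a purely entropic spring
W = c·k~B~T·ξ² gives ΔH ≈ 0 — the signature used to argue that entropy
(water-cage release), not enthalpy, stabilises the PA contact pair.
PMF offsets are arbitrary, so sign statements about ΔS are meaningful
only for profiles anchored on a common reference.

# The synthetic generators as study conditions

The generator defaults *are* the study conditions, chosen once:

* `gen_pa_bundle()`: 6 fibres × 50 PAs (300 PAs total), fibre radius
  25 Å (so the diameter metric lands at the ~50 Å scale), centroid
  spacing 50 Å on a regular hexagon, axial box 45.5 Å (50 PAs / 4.55 nm
  ≈ 11 per nm). PAs are 12-bead chains (4 tail + 8 head), stratified
  along z and wound with golden-angle azimuths — a helical wall packing
  that is cylindrically uniform and leaves centroids on the axes.
* `gen_solvation_shell()`: 200 sites, shells (2.85, 5.0) Å with (4, 12)
  waters and 0.05 Å radial jitter, sites separated by at least twice the
  outer radius so shells never overlap.
* `gen_micelle()`: radial tails-in chains on a sphere; 41+ PAs exceed
  the free-energy micellization threshold of N~agg~ = 40.
* `langevin_sample()`: Euler–Maruyama overdamped dynamics with a
  stability guard (k·dt/γ ≤ 0.5) and a divergence error suggesting a
  smaller step.

What these fixtures deliberately do **not** emulate: force-field-faithful
water structure (no real H-bond network topology), thermostatted 3-D
many-body dynamics, β-sheet formation, or kinetic pathways between
micelle and fibre states. A passing suite therefore certifies the
*measurement chain* — that each estimator returns the right number when
the answer is known — not any claim about real PA thermodynamics.

# Numerical choices and degenerate inputs

* Minimum-image components lie in (−L/2, +L/2]; the 27-image enumeration
  is the test oracle.
* Isolated particles (q6) and particles with under-populated neighbour
  shells (q~tet~) are excluded with a logged count; an all-excluded
  selection is an error.
* RDF bins use `findInterval` with closed right edge; fixtures avoid
  placing mass exactly on bin boundaries.
* Single-linkage ties cannot occur in labels (ordering by size then
  lowest molecule id is total).
* WHAM bins with fewer than 5 pooled samples report `NA` rather than an
  extrapolated free energy.
* The problem sizes used throughout the suite (≤ 500 particles for
  oracle equality, 2×10⁴ samples per umbrella window, 4096-step
  oscillator trajectories, one 34,000-water solvation box) were chosen
  as the smallest sizes at which each estimator's own statistical error
  is comfortably below the assertion tolerance.

# Known limitations

Orthorhombic boxes only; no PSF/XTC/TRR readers; no MBAR or 2-D PMFs;
no DSSP-style secondary structure beyond dihedral-region classification;
cage topology is captured only indirectly through RDF and order
parameters. The CG bead map and back-mapping templates are synthetic
stand-ins pending a real mapping table supplied through the documented
TSV interface.
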