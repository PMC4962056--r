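---
title: "Methods: hydration-shell statistics, Phi-value analysis and restrained annealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydration-shell statistics, Phi-value analysis and restrained annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, conventions and numerical choices behind
`hydrophi`, in the order a user meets them: containers and units, the
water-structure analyses, the contact/Phi machinery, the transition-state
sampler, the bulk-water sampler, and the synthetic-data generators that the
test suite is built on.  Where a convention was genuinely open we say what
was chosen and why.

## Containers, units, conventions

Coordinates are in nm, energies in kJ/mol, temperatures in K, times in ps;
PDB records (Angstrom) are converted at the I/O boundary.  Boxes are
orthorhombic only and all distances use the minimum-image convention;
triclinic input is rejected with an explicit error rather than silently
mis-wrapped.  Atom and residue indexing is R-native (1-based) throughout,
including in reports.  Water topologies carry the three real atoms (O, H1,
H2); the massless M site of the four-site water model is reconstructed
inside the energy and sampling code from the O–H geometry, because a
massless particle would violate the atom-mass invariant of the topology
container.

## Hydrogen bonds and the interface/bulk split

A hydrogen bond is purely geometric: donor–acceptor minimum-image distance
at most `max_da_distance` (default 0.35 nm) and hydrogen–donor–acceptor
angle at most `max_hda_angle` (default 30 degrees).  These defaults are the
widespread MD-analysis convention; both are exposed because different
criteria shift absolute bond counts by a few percent, and any comparison
across studies should state its criterion.  Protein N/O/S atoms donate when
they carry a covalently bound hydrogen (assigned by a 0.125 nm proximity
rule) and accept when they do not; water oxygens both donate and accept.

Per-molecule counts use the donated-plus-accepted convention — every bond
increments both partners — which is what places bulk water near 3.6–3.8
bonds per molecule at ambient conditions (counting donations only would
halve it).

A water molecule is *interface* water when its oxygen lies within
`shell_cutoff` (default 0.4 nm, the usual heavy-atom first-shell cutoff) of
the nearest protein heavy atom; hydrogens are excluded from the surface
definition because they would inflate it.  Averages are pooled per frame
and then weight-averaged over frames; frames without interface waters are
dropped from the interface means with the weights renormalised.  The
identity `total = ww + wp` for interface waters holds exactly by
construction, and the test suite asserts it on every input it generates.

## Rotational anisotropy

For every (water oxygen, protein atom) pair at distance r the profile
accumulates 3cos²ϑ−1, with ϑ the angle between the O→atom vector and the
water-plane normal (normalised cross product of the two O–H vectors).  The
per-bin mean times the bin's unnormalised pair count gives
A(r) = ⟨3cos²ϑ−1⟩·RDF(r); the absolute integral Σ|A_b|·Δr summarises the
orientational-order burden of the hydration shell.  All protein atoms are
used (not only the nearest), matching the profile's definition as a pair
sum.  Defaults: bin width 0.01 nm, range 1.5 nm — wide enough to cover the
first two hydration shells (features up to ≈0.7 nm) with a flat tail as an
internal control.  Isotropic orientations give zero in expectation; the
generators draw water orientations uniformly on SO(3) via random unit
quaternions precisely so that this null case is exact, and the suite checks
the per-bin mean against its 3-standard-error band and the decay of the
statistic with system size.

## Native contacts, Q and Phi

Native contacts are pairs of heavy side-chain atoms within 0.65 nm in the
native structure, between residues with |i−j| ≥ 2 ("not nearest
neighbours" read literally; the exclusion is configurable).  Glycine
carries no side-chain heavy atom and hence no contacts; alanine
contributes its C-beta.  Q is the hard-cutoff fraction of native atom
pairs formed, with the formation cutoff defaulting to the native cutoff
(no tolerance inflation — a smoothed Q variant exists in the literature
but a hard count keeps Q and Phi mutually consistent here).  Phi of
residue i is the weight-averaged formed fraction of the atom-pair contacts
involving i; residues without contacts are flagged invalid rather than
given a value.  The residue-level contact-formation map marginalises back
to Phi exactly (atom-pair-weighted), which the suite asserts.

From mutational data, Phi = (ΔΔG_D-N − ΔΔG_TS-N)/ΔΔG_D-N with
destabilisation energies (mutant − wild type).  Mutants with
|ΔΔG_D-N| < 2.5 kJ/mol (≈0.6 kcal/mol, the community reliability floor)
are flagged invalid, as are Phi-values outside [0, 1], which have no
interpretation as a contact fraction; multiple mutants at one residue are
averaged with a warning.  The Brønsted analysis is an ordinary
least-squares line and Pearson correlation of ΔΔG_TS-N against ΔΔG_D-N.

## The transition-state sampler

The sampler re-realises a Phi-restrained simulated-annealing protocol on a
C-alpha native-centric (Gō-type) model rather than an all-atom force
field: one bead per residue, harmonic bonds (r₀ from the native, k = 2000
kJ/mol/nm²), harmonic angles (k = 40 kJ/mol/rad²), a 1−cos dihedral term
(k = 1 kJ/mol), a 12-10 well per native residue-pair contact at the native
bead distance with depth ε per native atom pair (default ε = 6 kJ/mol,
chosen so that an unrestrained low-temperature anneal keeps the toy fold
at Q near 1 — the folded-control calibration in the test suite), and an
r⁻¹² excluded volume (σ = 0.4 nm) on non-native pairs.

The restraint is harmonic on *per-conformation* Phi-values,
E = k·Σ(Φᵢ − Φᵢ^exp)², with k defaulting to 50 kJ/mol, and only targets
inside [0, 1] are restrained.  Two numerical points matter:

* Inside the restraint, contact formed-ness is a logistic switch of width
  λ = 0.025 nm centred on 1.2× the native distance, while reported Q and
  Phi always use the hard 1.2× cutoff.  With a hard step the restraint has
  no gradient — a residue with one contact can only ever have Phi 0 or 1 —
  and intermediate targets are unreachable; the smooth switch restores a
  usable gradient, and the retained-ensemble *mean* of the hard Phi then
  matches intermediate targets.  Very large k over-pins contacts at the
  switching midpoint and degrades the hard-Phi statistics, which is why
  the default is moderate; the suite's recovery experiment (target
  Phi from a reference synthetic ensemble, 150 cycles) checks a mean
  absolute deviation of at most 0.1.
* Each annealing cycle restarts from the native conformation by default
  (`restart_native`), making retained structures independent anneals;
  continuing across cycles instead lets the chain drift into frustrated
  side-minima whose restraint energy grows with cycle number.

Moves are single-bead displacements (±0.025 nm) and crankshaft rotations
about the neighbour axis (±0.6 rad), giving 40–65% acceptance at the
reference temperatures.  Temperature ramps linearly from `t_high` (500 K
analogue) to `t_low` (272 or 323 K) within each cycle and the end-of-cycle
structure is retained, so the ensemble size equals the cycle count
(default 300).  Monte Carlo has no physical time, so cycle length is
expressed in sweeps (default 5000); the tests and examples use 120–200
sweeps and 20–150 cycles on a 16-residue hairpin, sizes chosen to keep an
experiment in seconds while leaving the calibration margins wide.

## Bulk-water sampling

`simulate_bulk_water` is a rigid-body Metropolis Monte Carlo sampler for
TIP4P/2005 water (LJ on oxygen: σ = 0.31589 nm, ε = 0.7749 kJ/mol; charges
+0.5564 e on the hydrogens and −1.1128 e on the in-plane M site at
0.01546 nm from the oxygen along the bisector).  Electrostatics use a
molecule-based spherical truncation on the O–O distance (default 0.9 nm)
with a conducting-boundary reaction field; plain truncation
under-structures water noticeably, while the reaction field tracks
Ewald-quality hydrogen-bond statistics closely at a fraction of the cost.
Runs are NVT at the model's 1-bar density for the requested temperature
(interpolated from published equation-of-state values; the density enters
only weakly).  Move amplitudes adapt toward 40% acceptance during the
first half of equilibration and are then frozen so production sampling
satisfies detailed balance.

The slow degree of freedom is the decay of the random initial
orientations: at 272 K several thousand sweeps are needed before the
energy and the hydrogen-bond count plateau, which is why the defaults (and
the acceptance script: 512 molecules, 6000 equilibration + 2000 production
sweeps, sampling every 100) look generous.  Lattice vacancies for
non-cubic molecule counts are scattered uniformly; filling grid sites in
order would leave a vacuum slab and simulate an interface instead of bulk.

## Synthetic data: what it does and does not emulate

The generators produce every input the pipeline needs: idealised peptides
grown by natural-extension with standard backbone geometry and exact
target dihedrals (classes: alpha (−57,−47), beta (−135,135), ppii
(−75,145), coil (−90,60)); water boxes with exact rigid-model internal
geometry and exactly isotropic orientations; solvated systems (waters
deleted within 0.24 nm of protein heavy atoms); ensembles in which each
native contact is independently formed with a prescribed probability
(side chains moved on their fixed-bond-length spheres by a stochastic
local search with random restarts until the drawn pattern is realised);
and ΔΔG tables whose sample correlation equals the target exactly by
Gram–Schmidt construction.

These fixtures validate bookkeeping, estimators and samplers — limits,
conservation identities, binomial recovery, isotropic nulls — not physics.
A jittered-lattice water box is not equilibrated liquid (no claim about
its RDF); peptides carry C-beta-level side chains only, so an idealised
helix has no side-chain contacts at 0.65 nm and the contact-bearing toy
fold is a beta-hairpin; contact independence across frames is a modelling
convenience real ensembles do not share.  Passing these tests therefore
shows the machinery is correct, not that any particular protein's
ensembles are reproduced.  The equilibrium bulk-water hydrogen-bond counts
are the one physical quantity recomputed from first principles, by the
Monte Carlo sampler above.

## Degenerate inputs and edge rules

Hydrogen-free topologies are refused by the bond detector with advice to
supply all-atom input; collinear O–H geometry (undefined water plane) is an
error; empty contact maps are errors for Q/Phi; a ΔΔG column with zero
variance is an error for the Brønsted fit; frames with no interface water
simply drop out of the interface averages.  Ramachandran boxes are
half-open ([lo, hi)) so the beta and polyproline-II regions sharing the
φ = −90° edge stay disjoint; chain termini, whose φ or ψ is undefined, are
always coil.

## Known limitations

The energy decomposition uses plain truncation at 0.9 nm without any
long-range correction, so its absolute values are not comparable to
Ewald-based references — the exhaustive-and-exclusive six-term identity is
the supported contract.  The interface/bulk split is binary at 0.4 nm with
no smoothing. The trajectory reader supports multi-model PDB and DCD but
not XTC.  The transition-state sampler is a coarse-grained re-realisation:
its temperatures are nominal labels on a Gō-model energy scale, and its
ensembles are meaningful relative to each other (cold versus hot targets,
restrained versus free), not as all-atom structural predictions.
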