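---
title: "Models and methods behind capsidgo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capsidgo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`capsidgo` studies maturation-associated expansion of icosahedral protein
shells and the trans-shell translocation of their terminal tails with a
single-basin structure-based model.  This vignette is the package's own
account of the model, the numerical choices, the synthetic study system and
its limits.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The energy model

All stabilising interactions are defined from one reference conformation,
the expanded ("mature") shell, which therefore becomes the global potential
energy minimum — the standard single-basin construction for studying
downhill conformational transitions whose true driving process (here, DNA
packaging) is not represented explicitly.

* **Contacts.**  Non-bonded pairs of the reference within 0.6 nm are
  screened with the Shadow construction: a pair is a contact only if no
  third atom, modelled as a 0.1 nm sphere centred within the pair distance
  of the first atom, intersects the line of sight (atoms directly bonded to
  either endpoint screen with a shrunken 0.05 nm radius).  Intra-chain
  pairs closer than 3 in sequence and all 1-2/1-3/1-4 pairs are excluded.
  Each contact is a 6–12 interaction `eps [ (s/r)^12 - 2 (s/r)^6 ]` with
  depth `eps = 1` reduced unit and minimum at `s = 0.95 r_native`.  The
  0.95 scaling keeps the free-energy minimum in the radius of gyration at
  the mature structure instead of slightly beyond it; it also means the
  *literal* reference coordinates are not a stationary point — the model's
  minimum is the uniformly ~5% contracted shell.  Tests that assert the
  strict local-minimum property therefore build the check topology with
  scale factor 1, where reference coordinates and energy minimum coincide
  exactly.  A Gaussian contact form is available as an option.
* **Bonds and angles.**  Bonds are harmonic (`k_b = 500` reduced
  units/nm²) with equilibrium lengths from a bundled subset of the Amber
  ff03 parameter set (backbone terms for all residues, generic heavy-atom
  classes plus residue-specific aromatic/carboxylate/amide rows); a missing
  entry falls back to the reference geometry and is logged, or errors when
  the fallback is disabled.  Angles use a cosine-harmonic form,
  `0.5 k_a / sin²(θ₀) (cos θ − cos θ₀)²` with `k_a = 40`: its curvature at
  the equilibrium matches the plain harmonic form, but its gradient stays
  bounded when a triple passes through collinearity — a real occurrence for
  coarse bead chains, where the 1/sin θ factor of the harmonic-angle force
  otherwise injects unphysical energy.
* **Dihedrals.**  One proper dihedral per rotatable central bond.  A bond
  joining two planar/sp²-hybridised atoms (peptide bond, ring systems,
  side-chain carboxyl/amide planes, classified from a bundled
  hybridisation table) is *rigid*: `k (1 − cos 2φ)`, minima at 0 and 180°.
  All others are *flexible*: `k [(1 − cos Δ) + ½(1 − cos 3Δ)]` with the
  minimum at the reference value.  Flexible strengths are normalised so
  their total stabilising energy is a configurable fraction of the total
  contact energy (default 0.5, the common convention for all-atom
  structure-based models).  Near-collinear dihedrals (within ~6° of a
  degenerate backbone) are skipped because their torque is undefined.
* **Excluded volume.**  `(0.25 nm / r)^12` for every non-excluded,
  non-contact pair within 0.6 nm — sterics are the central object of study,
  so the steric radius is an explicit, visible parameter.
* **Restraints.**  Optional per-atom harmonic Cartesian restraints and an
  optional half-harmonic radial containment wall (used only in the
  disordered-tail protocol, below).

Energies and forces are evaluated in C++ with a cell-list/Verlet-skin
neighbour search (rebuild at half-skin displacement); the analytic forces
of every term are validated against finite differences in the test suite.

## Dynamics

The integrator is the BAOAB splitting of Langevin dynamics in reduced
units (kB = 1, unit masses by default): half kick, half drift,
Ornstein–Uhlenbeck velocity refresh, half drift, half kick.  At zero
friction the scheme is exactly velocity Verlet, which the tests use to
verify energy conservation.  Production runs use reduced temperature
0.582 and timestep 0.002; friction defaults to 1.0 inverse reduced time
(the model literature leaves this free; it sets the time unit's meaning
but not the ordering of barrier-controlled rates).  All noise comes from a
per-run seeded generator, so trajectories are bit-reproducible on a given
build.

Disordered terminal-tail ensembles are produced by the restrained
high-temperature protocol: reduced temperature 1.0 with every non-tail
atom held at its compact position (k = 1000 reduced units/nm²), samples
taken at a fixed stride after an equilibration stride.  Two supporting
choices matter here:

* a half-harmonic radial wall at the compact shell's mid-surface confines
  the tails during this stage only.  It emulates the sealed cavities of a
  procapsid — in the toy shell the pores are wide enough that a
  high-temperature tail would otherwise pre-translocate, which the real
  compact state does not allow.  The wall never acts in production runs;
* the sampling stride is compared against the integrated autocorrelation
  time of the tail radius of gyration measured in the same run; a stride
  below it triggers a warning that is recorded in the run manifest.  The
  default stride (4500 steps) sits above the autocorrelation times we
  measure for the default shells.  This stage uses a timestep of 0.0015,
  slightly below the production value, because high-temperature collisions
  of the unstructured tails are the stiffest events the model produces.

## The synthetic shell

The generator builds a closed spherical shell of coarse one-bead-per-
residue chains, emitted as standard `GLY`/`CA` pseudo-atoms so that every
downstream module (including PDB export) runs unmodified.

* **Body.**  A quasi-uniform Fibonacci lattice on the sphere, opened at
  every pore by a smooth geodesic push-out map `s → sqrt(s² + a²)` away
  from the pore centre.  Because the map is continuous the lattice keeps
  its neighbour structure — no ragged holes — while every pore acquires a
  clean circular edge.  A six-bead rim ring sits at the pore half-width;
  chords and diameters brace it into a stiff hexagon, making the cavity
  half-width a controlled parameter rather than a soft degree of freedom.
  At the default bead spacing the lattice is sterically sealed: passing
  between beads costs several reduced units, far above thermal energy.
* **Tails.**  Each chain's terminal tail (default 8 residues) is interior
  in the compact state and, in the expanded reference, wraps its own pore
  on the exterior surface at 0.30 nm height in a zigzag spiral.
* **Cages.**  The tail's *intermolecular* native contacts are carried by a
  separate scaffold chain per capsomer: pad beads hovering 0.85 nm above
  the surface, directly over the distal tail residues (with half-step pads
  refining the Q resolution to ~13 pairs per chain).  The geometry is
  chosen so that 1.5 × the pad–tail native distance is smaller than the
  pad's height above the sealed shell: no pad contact can satisfy the
  formed criterion from the shell interior, so Q can only grow by genuine
  trans-shell displacement.  The generator verifies this property for every
  chain and refuses to emit a shell that violates it.  A one-bead-thin
  shell cannot provide such partners itself — any contact partner lying in
  the shell plane is reachable from both sides — which is why the scaffold
  exists.
* **Scaffold rigidity and the global frame.**  In production runs the cage
  chains are restrained (k = 50) and the shell body weakly anchored
  (k = 3) to the *scaled* mature geometry (0.95 ×, the model's actual
  minimum).  The cage models the rigid steric environment whose width is
  the study's controlled variable; the weak body anchoring removes
  whole-shell rotational diffusion, which a million-atom capsid does not
  exhibit on simulated timescales but a thousand-bead miniature does.
  Expansion itself remains contact-driven; tails are never restrained.
* **Sizing.**  Radii and per-chain residue counts are derived from the
  cavity-width table and chain count unless given explicitly: every chain
  needs room for its pore, its tail spiral and a clearance band such that
  no two tails share body beads (the generator assigns body beads under a
  tail's native path to that tail's chain, so all tail–body contacts are
  intramolecular).  The defaults (7 classes × 3 chains, ~50 residues per
  chain, expanded radius ≈ 3.3 nm with the compact radius at the 25:28.5
  capsid ratio) keep a full production run at around a thousand beads.
* **Widths.**  The default half-width table follows the qualitative
  ordering observed for maturing shells, E > D > C ≈ F ≈ G ≈ B > A.
  Width-ordered *ladders* (strictly increasing, evenly spaced) are used
  for rank-correlation studies; the usable range runs from ~0.34 nm
  (barely passable for a 0.25 nm bead) to ~0.5 nm (essentially free).
* **Kinked cavities.**  The `kinked_cavity` option adds a low three-bead
  lintel directly over tail residue 3 of each native path: a strong steric
  squeeze early in the zipper.  Its short-range native distances keep its
  contacts interior-safe; its mid-range pairs are blacklisted from the
  contact map (they stay sterically active) because their formed radii
  would otherwise overlap interior-accessible space.  Stalling under the
  lintel populates a distinct intermediate near Q ≈ 0.4, well separated
  from the high-Q states of natural threading traps.

### What the toy reproduces, and what it does not

Passing the toy-based suites demonstrates that the *pipeline* — topology
construction, disordered-tail generation, seeded Langevin dynamics,
first-passage analysis — faithfully turns an engineered steric hierarchy
into the expected ordered kinetics, that translocated states are detected
exactly when tails genuinely cross the shell, and that geometric traps
produce detectable intermediates.  The toy does not reproduce real T=7
icosahedral geometry, real sequences, the quantitative event counts of the
1.07-million-atom system, or emergent cavity dynamics such as
neighbour-tail competition; its cavities are engineered, not emergent.
Conclusions about a real capsid require the real structures, read through
the same interfaces (`read_structure()`, `expand_assembly()`).

## Observables and conventions

* `Q_i` is computed over the mature-specific *intermolecular* contacts of
  the chain's tail residues (the translocation criterion's scope); an
  all-contacts scope exists as an option.  A contact is formed when its
  distance is below 1.5 × its native distance.
* Translocation is the first passage of `Q_i ≥ 0.8`, inclusive.  No
  hysteresis by default; an optional hold window exists for noisy traces.
* `N_i(t)` uses cumulative first-passage counts on the saved-frame grid;
  ensemble statistics use the sample (n−1) standard deviation.
* Q histograms use 50 uniform bins on [0, 1]; peaks are local maxima above
  a configurable prominence (computed with the standard
  higher-of-the-two-saddles definition), classified endpoint (centre < 0.2
  or > 0.8) versus intermediate.  Stored distributions are never floored;
  any display flooring is left to plotting code.
* The equilibration prefix removed before histogramming is the expansion
  phase: frames before the radius of gyration first reaches 95% of its
  plateau (mean over the final fifth of the trace).

## Numerical choices and degenerate inputs

* Timesteps: 0.002 production, 0.0015 tail generation, 5 × 10⁻⁴ for
  energy-conservation checks.  Neighbour-list energies match the direct
  path by construction (same cutoff, rebuild at half skin).
* Collinearity: angle forces are bounded by the cosine-harmonic form;
  dihedrals within ~6° of backbone collinearity are skipped.
* Zero-step runs return the initial frame; empty structures, empty contact
  subsets, non-finite coordinates, mismatched shapes, improper rotations
  and contradictory configurations raise explicit errors; dynamics
  blow-ups report the step number.
* Ties in first-passage detection cannot arise (strictly increasing frame
  times are enforced); duplicate events for one (run, chain) are a
  consistency error.
* All pipeline randomness derives from one master seed through a
  documented Lehmer-style splitting kept inside the 32-bit signed range.

## Study sizes

The bundled studies are sized for a single CPU: hierarchy runs use
14-chain shells (two per class), ten seeded production runs of 10⁵ steps
each; the kinked-versus-straight comparison uses three runs per variant.
These sizes are the package's chosen study conditions; larger shells
(`chains_per_class` up to 8 with single-character chain identifiers) and
longer runs only sharpen the statistics.

## Known limitations

* The pipeline's end-to-end mode is toy-only; file-based studies compose
  the same module functions manually.
* Masses default to unity (element masses are accepted by the integrator
  but unused by the bundled studies), and there is no constraint
  algorithm, replica exchange or targeted dynamics.
* The GROMACS-dialect topology export is an interoperability convenience,
  not a validated round-trip.
* Criterion-scale checks on deposited capsid structures (420 chains,
  ~10⁶ atoms, 25 → 28.5 nm radius of gyration) exercise the same
  `read_structure()`/`expand_assembly()`/`radius_of_gyration()` code paths
  but require downloading the deposited models.
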