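---
title: "Restraint-based structure determination of quadruplex-duplex hybrids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-based structure determination of quadruplex-duplex hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdhfold)
```

## The problem

A quadruplex-duplex hybrid (QDH) is a DNA fold in which a G-quadruplex
core — stacked planar G·G·G·G tetrads held together by cyclic Hoogsteen
hydrogen bonds — is joined to a Watson-Crick duplex stem, usually stacked
coaxially against one face of the core. The *PIM1* oncogene promoter
contains a stem-loop quadruplex-forming sequence that adopts two such
folds. Form 1 (on the 27-nt construct `GCGGGAGGGCGCGCCAGCGGGGTCGGG`) is a
three-tetrad (3+1) hybrid: tetrads G3·G25·G22·G7, G4·G8·G21·G26 and
G5·G9·G20·G27, a three-base-pair stem (G19·C10, G11·C18, G17·C12) capped
by the hairpin G13–C14–C15–A16, a propeller loop (A6) and a lateral loop
(T23–C24), with syn guanines G1, G3, G7, G20, G21 and G25. Form 2 (on the
26-nt construct `GGGAGGGCGCGCCAGCGGGGTCGGGC`) is a chair-type antiparallel
fold: two tetrads (G2·G7·G18·G25, G3·G24·G19·G6), a slipped G·C·G·C tetrad
built from the junction pairs G1·C26 and G17·C8, a two-pair stem and three
lateral loops, with syn guanines G2, G6, G18 and G24.

Solution NMR determines such structures indirectly: NOESY cross-peak
intensities are converted into inter-proton distance classes, glycosidic
(chi) conformations are read from intra-residue H8–H1' intensities, and
the hydrogen-bonding pattern is inferred from imino-proton spectra. A
structure calculation then searches for all-atom conformations consistent
with these restraints. `qdhfold` implements that entire workflow at desk
scale: declarative fold topologies, restraint generation, a
distance-geometry / simulated-annealing engine, ensemble statistics, the
companion circular-dichroism (CD) analyses, and seeded synthetic-data
generators that make every stage testable against known ground truth.

## Topology model

A `qdh_topology` records the sequence, tetrads (with member order encoding
the cyclic Hoogsteen donor-to-acceptor direction), Watson-Crick pairs
(stem or junction), syn residues, loops, and groove-width labels. Groove
labels are annotations only; no groove geometry is computed. Residue
numbering is 1-based on the construct. `validate_topology()` returns one
diagnostic per violated invariant instead of raising, so a model can be
repaired interactively. The imino census (`imino_census()`) counts one
imino proton per G-tetrad guanine and one per Watson-Crick pair; guanines
of a G·C·G·C tetrad are hydrogen-bonded *within* Watson-Crick pairs and
are therefore counted in the Watson-Crick tally — this reproduces the
observed 12 + 3 (Form 1) and 8 + 4 (Form 2) peak counts.

## Restraints

Four restraint classes are generated:

* **NOE distances** — flat-bottom windows by intensity class:
  2.7 ± 0.8, 3.8 ± 0.9 and 5.5 ± 1.7 Å (non-exchangeable strong / medium /
  weak) and 4.0 ± 1.0, 4.8 ± 1.4 and 5.5 ± 1.7 Å (exchangeable). Peaks
  involving thymine methyls are redirected to the methyl carbon with both
  edges loosened by 0.5 Å.
* **Hydrogen bonds** — four distances per cyclic Hoogsteen G→G edge
  (H21–N7 and H1–O6 at 2.0 ± 0.2 Å; N2–N7 and N1–O6 at 2.9 ± 0.3 Å) and
  six per Watson-Crick G·C pair (H21–O2, H1–N3, O6–H41 at 2.0 ± 0.2 Å;
  N2–O2, N1–N3, O6–N4 at 2.9 ± 0.3 Å), giving 66 restraints for Form 1
  and 56 for Form 2.
* **Chi dihedrals** — O4'–C1'–N9–C4 (G) or O4'–C1'–N1–C2 (C), centered at
  60° (syn) or 240° (anti) with a ±70° halfwidth by default and ±40° as a
  per-residue or global tightening. Which residues carry chi restraints is
  a genuine design choice: restraining every tetrad or Watson-Crick-paired
  G/C plus explicitly syn-marked extras (Form 1's 5'-terminal G1) is the
  unique simple rule that yields 19 restraints for Form 1 and 16 for
  Form 2, so that rule is adopted. Loop residues carry no chi or planarity
  restraints.
* **Planarity** — one unit per G-tetrad, per G·C·G·C tetrad, and per
  Watson-Crick pair not already inside a G·C·G·C tetrad (6 units Form 1,
  5 units Form 2), acting on all base heavy atoms of the member residues.

A note on proton naming: restraints follow the NMR convention in which
H21 (G), H41 (C) and H61 (A) denote the hydrogen-bonding amino proton
(cis to N1/N3). The shipped residue templates use that convention.

## Engine

The engine re-implements the standard distance-geometry /
simulated-annealing protocol in Cartesian space:

1. **Extended chain.** `build_chain()` places idealized nucleotides
   (standard residue geometry, wwPDB atom naming) head-to-tail with exact
   phosphodiester junction geometry, so the start conformation has zero
   covalent strain. All bond / angle / improper ideals are *measured on
   the residue templates*, which makes the covalent force field exactly
   consistent with the geometry used to build chains and references.
2. **Bounds and embedding.** `build_bounds()` fixes 1-2/1-3 distances,
   applies restraint windows, floors all other pairs at a scaled van der
   Waals contact and triangle-smooths the upper bounds (Floyd pass in
   compiled code, plus one inverse-triangle pass on the lower bounds).
   `embed_coords()` samples one distance matrix between the bounds
   (seeded), double-centers it and projects on the three dominant
   eigenvectors. Handedness is unresolved by construction;
   `fix_chirality()` scores the chiral sugar impropers against their
   template signs and mirrors the coordinates when the majority is
   inverted.
3. **Annealing.** Velocity-Verlet dynamics with a velocity-rescaling
   thermostat runs the staged protocol: heat 300→1000 K over 14 ps and
   equilibrate 6 ps with distance constants at 2 kcal/mol/Å²; ramp the
   constants to 16 (non-exchangeable) and 8 (exchangeable) over 20 ps;
   equilibrate 50 ps at 1000 K; cool to 300 K over 42 ps; equilibrate
   18 ps, averaging coordinates saved every 0.5 ps over the final 10 ps.
   Dihedral (50 kcal/mol/rad²) and planarity (1 kcal/mol/Å²) constants are
   held throughout. `scale_factor` multiplies every stage duration
   uniformly for desk-scale runs.
4. **Minimization and refinement.** The averaged structure is minimized
   (FIRE relaxation in compiled code) to an RMS gradient of
   0.1 kcal/mol/Å. A final *violation-annealed* refinement then
   re-minimizes with the distance constants stiffened fourfold and
   iteratively shrinks the windows of any still-violated restraints,
   escalating their pull until no restraint is violated beyond 0.2 Å or a
   round cap is reached; clearly unsatisfiable (misfolded) runs are left
   untouched and eliminated later by energy selection. This step is the
   desk-scale substitute for the convergence a full-length annealing
   schedule would buy: it never changes which structures are *possible*
   (the windows only ever shrink toward the original targets), it only
   helps the minimizer find the basin that satisfies the data.
5. **Pipeline.** `run_pipeline()` performs `n_structures` independent
   embed → regularize → anneal → minimize runs (run seeds are
   `seed + run index`), collects the survivors with their energies and
   flags the `n_select` lowest-energy conformers.

### Numerical choices

* Covalent terms are quadratic bonds (200 kcal/mol/Å²), angles
  (50 kcal/mol/rad²) and impropers (30 kcal/mol/rad²; one improper per
  ≥3-coordinate center preserves planarity and chirality), with a purely
  repulsive soft-sphere nonbonded term (k = 4 kcal/mol/Å², radii scaled by
  0.8, 1-2/1-3/1-4 exclusions) and no electrostatics — the standard
  minimal force field for restraint-driven NMR annealing. There are no
  rotatable-bond torsion potentials: conformation is determined by the
  restraints.
* The integration timestep defaults to 2 fs with velocity rescaling every
  5 steps; the nonbonded neighbor list is refreshed every 10 steps.
* Annealing can deposit chemically equivalent prochiral pairs (H5'/H5'',
  H2'/H2'', OP1/OP2) in exchanged positions, which a gradient minimizer
  cannot undo; a deterministic coordinate swap repairs any center where
  the swap improves the local improper agreement.
* Two optional mechanisms — a soft-core repulsion ramp during the hot
  stages and a sugar-ring pucker bias (`k_ring`) — are implemented but off
  by default: in desk-scale experiments both made the annealing landscape
  more rugged and degraded convergence.
* Minimization reports a warning status (attribute `converged = FALSE`)
  when the iteration cap is reached, never an error.

## Ensemble statistics

`kabsch_rmsd()` computes the minimal RMSD under optimal rotation and
translation (no reflection) over name-matched atom selections;
`pairwise_rmsd()` averages it over all unordered pairs of flagged
conformers. The "G-tetrad core" selection is the heavy atoms of all
G-tetrad member residues (G·C·G·C tetrads excluded), matching the usual
table label; it is exposed as an ordinary selection function so users can
redefine it. Restraint violations are counted with a strict 0.2 Å
threshold (a violation of exactly 0.2 Å does not count). Mean ± sd
statistics use the population (n-divisor) standard deviation. Pairwise
RMSD is computed over pairs, not against a mean structure, because that is
what a "pairwise" label denotes.

## CD analyses

`decompose_two_state()` models a mixture spectrum as a convex combination
`w1·comp1 + (1−w1)·comp2` (weights on the simplex, so the result is always
an interpretable pair of populations) and solves the one-dimensional
least-squares problem in closed form after linear interpolation onto the
common wavelength support. With the two pure-form spectra as components,
this is the estimator behind a population split such as 81% / 19%.

`fit_baselines()` fits the completely-folded and completely-unfolded
linear baselines over user-chosen temperature windows (≥3 points each,
non-overlapping), and `melt_tm()` converts the curve into a folded
fraction `theta(T)`, clips it to [0, 1] (tolerating noisy baselines) and
locates the melting temperature — equal folded and unfolded fractions —
by linear interpolation between the grid points bracketing
`theta = 0.5`. The estimate is invariant to affine rescaling of the
ellipticity axis.

## Synthetic data: what it emulates, and what it does not

The generators provide ground truth for every stage:

* `build_idealized_coords()` assembles an all-atom reference from the
  topology alone: G-tetrads as C4-symmetric planar squares whose in-plane
  geometry is *fitted* to the Hoogsteen distance targets, Watson-Crick
  pairs from a fitted ideal pair geometry, layers stacked coaxially
  (rise 3.4 Å; twist 25° between tetrad layers, 36° in the stem — typical
  quadruplex and B-form values), inter-layer registry by rigid in-plane
  registration of sequential residues, chi set exactly to 60°/240°, and
  loops interpolated between their anchors with an outward bulge. Rigid
  base placement leaves the backbone unclosed, so a deterministic
  restrained regularization (strong hydrogen-bond / chi / planarity
  constants) closes the chain while holding the base arrangement. The
  result satisfies every hydrogen-bond window and is a physically
  consistent minimum of the engine's own force field — it is an
  *idealized reference*, not an experimental structure.
* `simulate_noe_peaks()` emits every inter-proton pair within 6 Å,
  jitters the distance (seeded), and quantizes it into strong / medium /
  weak at class boundaries of 3.0 and 4.5 Å (non-exchangeable) or 4.2 and
  5.5 Å (exchangeable; chosen so each class window contains its distance
  range), with thymine methyls represented by their carbon. Pairs below
  the classification range (geminal protons) are not emitted. At zero
  jitter the emitted classes round-trip through `classify_noe()` to
  windows containing the true distances, which is what makes noise-free
  recovery experiments well-posed.
* `simulate_cd_mixture()` and `cd_component_spectrum()` build noisy linear
  mixtures of Gaussian-band mock spectra qualitatively matching the two
  pure forms (positive 265 nm with a 290 nm shoulder versus positive
  290 nm with negative 255 nm); only their linear independence matters.
* `simulate_melting_curve()` produces two-state van't Hoff curves
  (`theta(Tm) = 0.5` exactly) mixed over sloping linear baselines. The
  default unfolding enthalpy is 70 kcal/mol — a typical cooperative
  van't Hoff enthalpy for a three-tetrad quadruplex with a hairpin stem of
  this size. Enthalpies much below ~60 kcal/mol leave a percent-level
  unfolded tail inside the 85–95 °C baseline window of a 15–95 °C scan,
  which biases any linear-baseline Tm method by a few tenths of a degree;
  that bias is a property of the analysis, not of the generator.

What recovery experiments on these data do **not** show: performance on
real spectra (peak overlap, spin diffusion, chemical-exchange losses,
mis-assignments), intensity-to-class calibration, or the ruggedness of
real conformational ensembles. The experimental restraint sets behind the
deposited structures (PDB 7CV3 / 7CV4) are not distributed with the
package; `read_pdb()` can load the deposited coordinates as an alternative
reference if the user obtains them, but nothing requires it.

## Desk-scale study sizes

Recovery experiments in the test-suite run the Form 1 pipeline with 10
structures (5 selected) at `scale_factor = 0.1` — a 15 ps protocol per
structure — and the selection-contract experiment runs 100 structures of a
6-mer hairpin at `scale_factor = 0.01`. These sizes keep a full run in
minutes on one core while preserving the protocol's structure; the
schedule defaults encode the full-scale (150 ps, 100-structure) protocol.

## Known limitations

* The force field is a geometric restraint engine, not a thermodynamic
  model: no electrostatics, no attractive dispersion, no solvent, no ions
  (no explicit potassium in the tetrad channel), no base-stacking
  potential. Energies rank restraint satisfaction and covalent strain
  only.
* Sugar puckers are soft: the NOE class quantization cannot always pin a
  pucker, so individual sugars may settle in a different pucker family
  than a reference while satisfying every window.
* Misfolded annealing runs (a minority at desk scale) are handled by
  energy selection, exactly as in the full-scale protocol where 10 of 100
  structures are kept.
* The hydrogen-bond directionality of the Form 2 tetrads is not annotated
  (the source data do not state it); the geometry builder derives the
  relative tetrad handedness from the member order and sequential-residue
  registry instead.
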