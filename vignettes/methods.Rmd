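---
title: "Rigid-body modeling of TCR inter-domain association angles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body modeling of TCR inter-domain association angles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

T cell receptors recognize peptide antigens presented by MHC molecules.
The two variable domains of the receptor, Valpha and Vbeta, pack against
each other at an association angle that differs between receptors and can
shift on ligand binding, repositioning the CDR loops that contact the
pMHC. The packing is anchored by a conserved pair of interface glutamines,
one per domain, whose hydrogen-bonded carboxamide groups sit at a center
of rotation (CoR_beta) about which the observed angular variation can be
described. `tcrdom` treats the prediction of these association angles --
and, in complex mode, of the pMHC position relative to the receptor -- as
a multi-rigid-body energy minimization problem.

Each structural unit (Valpha, Vbeta, and optionally the class-I pMHC,
i.e. the alpha1/alpha2 platform with its peptide) is reduced to an
oriented cuboid: center, covariance-eigenvector axes over the backbone of
the unit, extents from the maximal axis projections. The Valpha cuboid
fixes the internal coordinate frame; the placement of a mobile unit is
then a rotation about its center of rotation (CoR_beta for Vbeta, CoR_mu
-- the peptide-groove center, operationalized as the peptide backbone
centroid -- for the pMHC) plus a translation. Orientations are *measured*
as three Euler-angle components of the mobile cuboid axes in the Valpha
frame, but *optimized* as exponential-map rotation vectors, which have no
gimbal singularity and admit simple analytic derivatives. The Euler
convention is fixed and documented: intrinsic rotations about the frame's
first, second and third axes in that order (the z-y'-x'' convention under
the labeling z = axis 1).

## Energy model

Pose quality is scored with an OPLS-style all-atom nonbonded energy:
12-6 Lennard-Jones plus Coulomb terms with the constant
332.0636 kcal·Å/mol/e². The packaged plain-text parameter table follows
OPLS-AA conventions -- geometric-mean combination for both sigma and
epsilon, 1-2 and 1-3 bonded pairs excluded, 1-4 pairs scaled by 0.5 for
both terms -- and covers the residues the fixture systems and tests use;
it is versioned and its hash is available for run logs. Defaults the
energy model leaves open are collected in `energy_options()`: vacuum
electrostatics (relative dielectric 1.0) and no cutoff, because the
modeled systems are desk-scale; a finite cutoff with a smooth switching
taper is available as a knob. Intra-unit energy is constant under rigid
motion and excluded from the optimization objectives, with one exception:
the sampled carboxamide dihedrals, whose bonded (cosine-series torsion)
and nonbonded terms are included.

Candidate models are ranked by the binding energy

  E_bind = E_complex − (E_alpha + E_beta + E_mu),

where the unit self-energies are constant within a prediction run and are
computed once, after the initial per-domain flip correction. Because of
that caching convention, reported E_bind values within a run are mutually
comparable but can differ from an instantaneous `binding_energy()` call
by the (constant) offset the later carboxamide adjustments introduce to
the unit terms.

## Sub-process operators and the optimization pipeline

Three operator families compose every optimization step:

* **Rigid-body operators** move one unit about its center of rotation
  (3 rotation-vector parameters plus either a free 3-vector translation
  or a scalar translation along a fixed axis). Their objective is the
  inter-unit nonbonded energy; intra-cuboid pairs are excluded.
* **Carboxamide operators** rotate the terminal amide group of an
  Asn/Gln about the adjacent carbon-carbon bond (Cbeta-Cgamma for Asn,
  Cgamma-Cdelta for Gln); one dihedral parameter. The objective adds the
  side-chain torsion terms that change with the dihedral and all
  nonbonded terms involving the moved atoms, intra-unit included.
* **Restraint operators** add a flat-bottom harmonic penalty on the
  displacement of a unit's CoR anchor: zero within the threshold
  (7.5 Å for Vbeta, 13.0 Å for pMHC), `0.5 k (d - threshold)^2` beyond
  it, `k` = 10 kcal/mol/Å² by default (the threshold values are protocol
  constants; the force constant is this package's choice, exposed in the
  configuration). Restraint reference points are captured at the start of
  the concurrent optimization step, so they bound drift around the
  approached pose rather than penalizing the deliberate pre-placement
  translation.

Concurrently active operators are bound into one global objective; shared
nonbonded pairs are counted exactly once (inter-unit pairs come from the
rigid contexts, carboxamide operators contribute only the pairs those
contexts do not cover). The gradient is assembled analytically by the
chain rule from per-atom derivatives, the closed-form derivative of the
exponential map, and the axis tangent field for dihedral parameters; the
test suite checks it against central finite differences for every family.

The minimization driver is BFGS with a strong-Wolfe line search
(c1 = 1e-4, c2 = 0.1, derivative-secant extrapolation with a
quadratic-interpolating zoom, initial inverse-Hessian rescaling after the
first update). The tight curvature constant makes the search exact on
quadratic objectives at the cost of about one extra evaluation, which
gives near-Newton behavior on well-conditioned steps. Runs stop at a
gradient infinity-norm tolerance (default 1e-3 kcal/mol per parameter
unit), the step limit, or stagnation; limit-capped runs typically sit on
a flat plateau and are treated as usable models, with the `converged`
flag preserving the distinction.

The standard remodeling protocol is: (1) cuboid assembly in the Valpha
frame; (2) independent two-state flip correction of each conserved
glutamine within its own domain (original versus 180 degrees, then up to
30 refinement steps); (3) generation of the Vbeta starting orientations
(11 by default); (4, complex mode) pMHC pre-placement -- general
orientation, translated 15 Å along the platform-normal axis away from the
receptor -- followed by pre-optimization against the fixed TCR for up to
150 steps (3 rotation + 1 axis-translation parameters); (5) joint
sampling of the two glutamine dihedrals on an 18-degree factorial grid
(400 combinations) in the whole-assembly context, then up to 30
refinement steps; (6) concurrent rigid-body plus carboxamide
optimization: a preliminary 50 steps, step (5) again, then up to 2950
steps; (7) binding-energy evaluation. One model per start; models are
ranked by E_bind. With a reference structure, success is assessed as C_R
(any model under the 2 Å all-atom RMSD threshold) and C_E (the
best-energy model under it). RMSD is computed over mobile-unit atoms in
the shared Valpha frame without re-superposition, so placement error is
measured rather than masked; the frozen Valpha would only dilute the
value and is excluded.

## Design choices where the protocol was open

* **The 11 default start rotations.** The packaged set is identity, ±8°
  and ±16° about the Vbeta cuboid long axis, ±8° about each minor axis,
  and two combined 8°/8° twists -- weighted toward the long-axis torsion
  that dominates the observed angular spread. The set is plain text and
  fully overridable from the pipeline configuration.
* **Conserved-glutamine identification.** By default the Gln pair (one
  per variable domain) with the smallest inter-carboxamide distance;
  explicit residue selectors override this for nonstandard cases.
  Structures lacking the pair degrade gracefully: flip steps are skipped
  with a warning and a single identity start is used.
* **Flip-state semantics.** The 180-degree "flip" is a rotation of the
  carboxamide dihedral, never an atom-label swap; hydrogens travel with
  the nitrogen. Intermediate final angles are permitted -- this is what
  lets the optimizer resolve bifurcated (roughly perpendicular) Q-Q
  pairings that two-state flippers cannot represent. Classification
  against a reference calls a pairing bifurcated above a 60° angle
  between carboxamide planes (config-exposed), otherwise paired or
  mispaired by which O/N labeling minimizes positional deviation.
* **Degenerate inputs and ties.** Flip correction breaks exact two-state
  ties toward the original assignment. Cuboid axis signs are fixed by a
  positive projection of the selection's farthest point, with the third
  axis completing a right-handed frame; collinear selections are
  rejected. Euler extraction near gimbal lock flags the result and
  canonicalizes the degenerate pair. Model-rank ties keep model order.

## What the synthetic fixtures emulate -- and what they do not

All tests run on generated systems; no structure downloads are involved.

* `make_lj_dimer()`: two two-atom rigid units with embedded parameters
  and a single interacting Lennard-Jones pair, so the optimum separation
  (2^(1/6) sigma) and well depth (−epsilon) are closed-form.
* `make_mini_domains()`: two five-residue strands (ALA-ALA-GLN-ALA-ALA),
  built from ideal internal coordinates and posed so the two glutamine
  carboxamides form the parallel, doubly hydrogen-bonded pair of the
  conserved interface at a 2.9 Å donor-acceptor distance. The generator
  then relaxes the construction once, jointly over the Vbeta rigid pose
  and both carboxamide dihedrals, so the shipped default geometry is a
  local minimum of the same objective the pipeline minimizes and serves
  as the recovery reference. Variants ship the Vbeta glutamine rotated
  180° (mispaired) or 90° (bifurcated).
* `make_mini_ternary()` adds a pMHC-like third unit: two four-residue
  alanine strands as a platform carrying an ALA-GLN-ALA peptide whose
  central glutamine points at the receptor face, giving the bound pose a
  directional polar contact rather than shape complementarity alone. Its
  canonical pose is defined as a fixed point of the standard complex-mode
  protocol itself: the generator iterates the single-identity-start
  pipeline pass until two successive passes agree (drift below 0.05 Å),
  so the shipped geometry is a stable attractor of the procedure being
  tested. The platform normal is embedded as the pre-placement
  translation axis.

Jitter uses an explicit seed carried in the generator arguments; no
global random state is consumed. The fixtures are deliberately minimal:
about 60 atoms per variable-domain stand-in against roughly 110 residues
in a real variable domain, a flat two-strand platform instead of the MHC
beta-sheet and helices, no CDR loops, no solvent, and a far smoother
energy landscape than a crystal structure's. Passing tests therefore
demonstrate the correctness of the machinery -- energies against
brute-force oracles, analytic gradients against finite differences,
grid searches against exhaustive enumeration, pose recovery within basins
of attraction -- not prediction accuracy on real TCR structures, which
additionally depends on force-field fidelity and landscape ruggedness at
full scale.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on the fixtures:
nonbonded oracles on one hundred random 20-atom systems, gradient checks
across randomized poses of the 114-atom two-domain fixture, exhaustive
1-degree joint glutamine grids (129,600 evaluations per variant),
twenty to forty seeded recovery runs with Vbeta perturbations up to 16°
about CoR_beta, and full 11-start remodeling of the 177-atom ternary
fixture. These sizes keep a complete run in the minutes range on one CPU
while exercising every code path of the pipeline.

## Known limitations

* The packaged parameter table covers the residue set the generators use
  (GLY, ALA, SER, THR, VAL, LEU, ILE, ASN, GLN); applying the pipeline to
  arbitrary crystal structures requires extending it (the format is
  documented plain text) and externally protonated inputs -- the package
  places only the Asn/Gln amide hydrogens itself.
* Internal flexibility is limited to the carboxamide dihedrals; CDR
  side-chain or backbone adaption is out of scope, as are MHC class II
  systems, constant domains and beta2-microglobulin.
* Binding energies are vacuum force-field scores meant for ranking poses
  of the same system, not transferable affinities.
* Per-entry chain/residue maps for crystal structures are user-supplied
  (a documented template is packaged); automatic domain detection is not
  attempted.
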