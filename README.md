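# tcrdom

Rigid-body energy minimization for predicting protein inter-domain
association angles, specialized to T cell receptors: the packing angle of
the TCR variable domains (Vα/Vβ) and, in complex mode, the orientation of
a class-I peptide–MHC (pMHC) ligand on the receptor.

## Who this is for

Structural immunologists and modelers who need atomistic TCR or TCR–pMHC
models with system-specific inter-domain angles — for remodeling
experiments, as the angle-optimization stage of a homology-modeling
pipeline, or for blind pose selection by force-field energies — and
anyone who needs the standalone asparagine/glutamine carboxamide
flip-correction tool that the pipeline is built from.

## The method

Each modeled unit (Vα, Vβ, pMHC = α1/α2 platform + peptide) is reduced to
an oriented cuboid; the Vα cuboid fixes the coordinate frame. A mobile
unit's placement is a rotation about its center of rotation plus a
translation: CoR\_β sits at the midpoint of the conserved hydrogen-bonded
glutamine pair bridging the two variable domains, CoR\_μ at the center of
the peptide-binding groove. Orientations are measured as three
Euler-angle components in the Vα frame but optimized as exponential-map
rotation vectors **v** (no gimbal singularity, analytic gradients
`∂R/∂v`), with BFGS over the concatenated parameters of all concurrently
mobile bodies.

Poses are scored with an OPLS-style all-atom nonbonded energy
(12-6 Lennard-Jones + Coulomb) and ranked by the binding energy

    E_bind = E_complex − (E_α + E_β + E_μ)

with the unit self-energies computed once per run. Three sub-process
operator families compose the optimization steps: rigid-body motion
(inter-unit energy only), carboxamide rotation (one dihedral; handles the
~20% of crystal-structure Asn/Gln carboxamides deposited in the wrong
flip state, including bifurcated Q–Q pairings two-state flippers cannot
represent), and flat-bottom harmonic position restraints (thresholds
7.5 Å for Vβ, 13.0 Å for pMHC). The standard protocol runs per-domain
flip correction, 11 Vβ starting orientations, pMHC pre-placement and
approach (complex mode), 400-point joint Q–Q sampling at an 18° step, and
concurrent optimization (50 steps, Q–Q resampling, then up to 2950
steps). With a reference structure, success is reported as C\_R (any of
the 11 models within 2 Å all-atom RMSD) and C\_E (the best-energy model
within 2 Å).

Everything is testable offline: deterministic synthetic fixtures (an LJ
dimer with a closed-form optimum, a two-domain mini system with the
conserved Q–Q interface, a ternary mini TCR–pMHC system) exercise the
full pipeline.

## Worked example

Remodel a mini two-domain fixture whose Vβ was rotated 12° about CoR\_β
away from its relaxed reference pose:

```r
library(tcrdom)

ref  <- make_mini_domains()
pert <- make_mini_domains(perturb_rotation = c(12, 0, 0))
all_atom_rmsd(pert, ref)
#> [1] 1.59

models <- run_remodeling(pert, pipeline_config(mode = "TCR"), reference = ref)
rank_models(models)
#> model_set with 11 models
#>    model   E_bind   rmsd
#> 1      1 -14.4116 0.0000
#> 2      2 -14.4116 0.0000
#> ...
#> 9      9 -14.1727 2.8892
evaluate_success(models)
#> C_R: TRUE (best RMSD 0.000 A, model 3)
#> C_E: TRUE (best-energy model 3, RMSD 0.000 A)
```

The run produces one model per starting orientation; here 8 of 11 starts
re-converge to the reference pose (RMSD ≈ 0, E\_bind −14.41 kcal/mol) and
3 fall into a secondary minimum at 2.89 Å with a worse energy, so both
the structural and the energy criterion succeed. Supporting quantities:

```r
locate_cor_beta(ref)$point
#> [1] 1.11 6.29 0.80        # Å, Vα frame
binding_energy(ref)
#> E_complex = -253.4242  E_alpha = -119.4970  E_beta = -119.4970  E_mu = -
#> E_bind    = -14.4302 kcal/mol
```

For real structures, read a PDB file with `read_structure()`, select the
modeled units with `extract_modeling_units()` and a unit map (template in
`inst/extdata/unit_map_template.txt`), place the amide hydrogens, align
with `align_to_va_frame()` and parameterize with `assign_parameters()` —
or use the thin command-line drivers `inst/scripts/remodel.R` and
`inst/scripts/qflip-correct.R`.

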