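# betamep

Backbone torsion parametrization of acyclic β-peptides by minimum energy
path (MEP) matching, in R.

β-peptide foldamers fold into stable non-natural secondary structures (the
14-helix, hairpins), but the extra backbone methylene gives each residue
three backbone torsions — φ (C(O)–N–C<sub>β</sub>–C<sub>α</sub>),
ϑ (N–C<sub>β</sub>–C<sub>α</sub>–C) and ψ (C<sub>β</sub>–C<sub>α</sub>–C–N) —
that general-purpose protein force fields describe poorly.  betamep is for
force-field developers and simulation practitioners who want to derive (or
scrutinize) proper-dihedral parameters for these torsions the standard way:
introduce dedicated backbone atom types on small protected model compounds,
and fit the barrier heights so that the molecular-mechanics torsional MEPs
match reference (typically quantum-chemical) MEPs.

Each fitted term has the periodic CHARMM form

    E(χ) = K_χ [1 + cos(nχ − χ0)],    n ∈ {1, 2, 3, 6},  χ0 ∈ {0°, 180°}

and the package implements the complete surrounding machinery:

* the four protected diamide model compounds (β⁰, β², β³, β²,³) with the
  dedicated atom types CTA1/CTA2/CTB1/CTB2 and HB1/HB2, and enumeration of
  the backbone torsions they introduce (12, 14, 14 and 13 new type
  quadruples);
* the constraint algebra that reduces 318 candidate terms / 636 nominal
  parameters to 96 non-zero terms bound into 38 independent parameters:
  phase restriction to {0°, 180°}, zeroing of aliphatic-hydrogen terms,
  supplementary amide pairs, sp³ triplets, histogram-based multiplicity
  selection, and post-fit correlation merging with sign adjustment;
* a vacuum CHARMM-form energy function with analytic gradients, restrained
  steepest-descent minimization, relaxed 5°-step torsion scans, global MEP
  extraction, and the self-consistent loop that alternates restrained MM
  re-minimization (10⁵ kJ/mol/rad² backbone restraints) with a linear
  least-squares barrier-height fit;
* the trajectory validation statistics: backbone RMSD, greedy
  neighbour-count conformational clustering, two-state folding free
  energies, ⟨r⁻⁶⟩⁻¹ᐟ⁶ NOE violations, Karplus ³J couplings, geometric and
  switching-function hydrogen-bond measures, and circular (von Mises)
  kernel density estimation;
* synthetic reference generators with known ground truth, and CHARMM /
  GROMACS (funct 9) parameter-file output.

## Worked example

Enumerate the torsions, load the published constraint system, and recover
known barrier heights from synthetic reference MEPs carrying 0.1 kcal/mol
of Gaussian noise:

```r
library(betamep)

sys <- published_constraint_system()
print(sys)
#> Constraint system: 96 terms (96 non-zero, 0 fixed to zero), 38 independent parameters

scen <- synthetic_scenario(seed = 7, noise_sd = 0.1)
sy   <- synth_qm_meps(scen, sys)            # 3 x 72-point reference MEPs
fit  <- fit_barrier_heights(sy$meps, sy$meps, rep(list(sy$backend), 3), sys)
print(fit)
#> Barrier-height fit: 8 parameters from 216 matched points, overall RMS 0.0916 kcal/mol

act <- which(fit$active)
data.frame(parameter = sys$groups$label[act],
           K_true = sy$truth_K[act],
           K_fit  = round(fit$K[act], 3),
           se     = round(fit$se[act], 3))
#>       parameter K_true K_fit    se
#>    beta0.phi1.1   0.27 0.282 0.009
#>    beta0.phi1.2   0.16 0.153 0.008
#>    beta0.phi1.3   0.29 0.293 0.006
#>  beta0.theta1.3   0.94 0.957 0.013
#>  beta0.theta1.6   0.07 0.066 0.011
#>    beta0.psi1.1   0.68 0.686 0.006
#>    beta0.psi1.2   0.21 0.202 0.006
#>    beta0.psi1.3   0.13 0.115 0.005
```

The overall RMS of 0.0916 kcal/mol reflects the injected noise, and every
recovered barrier height sits within a couple of standard errors of the
generating value; with `noise_sd = 0` the recovery is exact to machine
precision.  `self_consistent_optimize()` wraps the same fit in the full
iterative loop with restrained MM re-minimization; on this scenario it
converges in 3 iterations.

A thin command-line wrapper ships in `inst/cli/betamep`
(`betamep counts | synth | fit | analyze | write`), e.g.:

```sh
$ Rscript inst/cli/betamep counts
beta0   12 new torsions
beta2   14 new torsions
beta3   14 new torsions
beta23  13 new torsions
non-zero terms: 96 | independent parameters: 38
```

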