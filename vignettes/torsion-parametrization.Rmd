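---
title: "Backbone torsion parametrization of beta-peptides by MEP matching"
author: "betamep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone torsion parametrization of beta-peptides by MEP matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betamep)
```

## The problem

Acyclic beta-amino acids carry an extra backbone methylene, so each residue
has three backbone torsions -- phi (around N--C$_\beta$), theta (around
C$_\beta$--C$_\alpha$) and psi (around C$_\alpha$--C) -- instead of the two
of alpha-peptides.  General-purpose protein force fields describe these
torsions with parameters borrowed from alpha-carbon atom types, which is a
poor approximation: the folds that make beta-peptide foldamers interesting
(the 14-helix, hairpins) live or die on torsional barrier heights of a few
tenths of a kcal/mol.  betamep implements a complete desk-scale version of
the standard remedy: introduce dedicated backbone atom types, and refit the
proper dihedral terms of those types so that the molecular-mechanics (MM)
torsional minimum energy paths (MEPs) of small model compounds reproduce
reference MEPs, typically computed quantum-chemically.

The potential is the conventional CHARMM form: harmonic bonds (with the
CHARMM convention of no 1/2 factor), harmonic angles and Urey-Bradley
terms, periodic proper dihedrals

$$ E_\chi = K_\chi\,[1 + \cos(n\chi - \chi_0)], $$

harmonic impropers, 12-6 Lennard-Jones in the $R_{min}$ form and vacuum
Coulomb electrostatics.  Only the $K_\chi$ of the backbone dihedral terms
are fitted; everything else is held fixed.

## Model compounds, atom types and torsion enumeration

Four protected diamides (acetyl- and N-methylamide-capped beta-alanine
derivatives) span the substitution patterns: unsubstituted (beta0),
alpha-methyl (beta2), beta-methyl (beta3), and both (beta23).  The
substituted/unsubstituted backbone carbons receive atom types CTA1/CTA2
(beta3 pattern) and CTB1/CTB2 (beta2 pattern); their hydrogens are HB1 on
substituted and HB2 on unsubstituted carbons.  Typing is independent of
chirality, so a parameter set derived from the (S) stereoisomers applies
unchanged to the (R) forms.

```{r}
b3 <- build_diamide("beta3")
subset(b3$atoms, name %in% c("CB", "CA", "HB"))[, c("name", "type")]
```

Proper dihedrals are enumerated around the three backbone bonds -- the
bonds whose central atoms include at least one of the new carbon types --
and deduplicated by canonical atom-type quadruple (a quadruple and its
reverse are one torsion).  Torsions around the side-chain and capping
methyl bonds are excluded: those are ordinary aliphatic torsions that the
base force field already parametrizes, and only the backbone terms are
refit here.  Processing the molecules in the order beta0, beta2, beta3,
beta23 while carrying a seen-set of quadruples forward yields 12, 14, 14
and 13 new torsions:

```{r}
seen <- character()
for (nm in c("beta0", "beta2", "beta3", "beta23")) {
  tt <- enumerate_new_torsions(build_diamide(nm), seen)
  cat(nm, ":", nrow(tt), "new torsions\n")
  seen <- c(seen, tt$key)
}
```

## The constraint algebra

With all six multiplicities per torsion the 53 torsions would give 318
terms and 636 nominal parameters ($K_\chi$ and $\chi_0$ each), far too
many to fit stably.  The reduction applies, in order:

1.  **Phase restriction.**  Reversing atom order or mirroring the molecule
    negates a torsion, while the energy must be invariant, so
    $\chi_0 \in \{0^\circ, 180^\circ\}$.  This also guarantees that
    stereoisomers have identical energies.
2.  **Phase elimination.**  Switching $\chi_0$ between 0 and 180 is
    equivalent to negating $K_\chi$, so all phases are set to 0 during
    fitting and $K_\chi$ becomes the only continuous parameter per term.
    After the fit, [sign_adjust()] restores non-negative barriers by
    flipping phases; the energy changes only by the constant $-2K_\chi$.
3.  **Hydrogen zeroing.**  Terms whose quadruple contains HB1 or HB2 are
    fixed to zero -- the positions of these hydrogens are dominated by
    angle terms.
4.  **Multiplicity restriction.**  The sp$^2$/sp$^3$ hybridization states
    admit only $n \in \{1, 2, 3, 6\}$.
5.  **Supplementary amide pairs.**  Planarity of the amide groups makes
    certain torsion pairs sum to $180^\circ$; for equal odd $n$ the pair
    must share $|K_\chi|$ with phases differing by 180, for even $n$ both
    parameters coincide ([supplementary_pair_groups()]).
6.  **sp$^3$ triplets.**  Torsion triplets sharing three atoms around a
    tetrahedral carbon sit $120^\circ$ apart; a common parameter is
    consistent with the $\{0, 180\}$ phase alphabet only when the shift is
    a whole period, i.e. for $n = 3$ and $6$ ([sp3_triplet_groups()]).
7.  **Histogram-based multiplicities.**  The relaxed torsion values
    accumulated over all scan geometries concentrate near the minima of
    the torsional wells, so the minimal multiplicity set is the smallest
    subset of $\{1,2,3,6\}$ whose well minima (one phase per
    multiplicity) cover all histogram modes
    ([multiplicities_from_histogram()]; circular von Mises KDE, default
    bandwidth 5 degrees, mode-to-minimum tolerance 15 degrees -- small
    enough that modes at $\pm 60, \pm 90, \pm 150$ degrees force the
    two-multiplicity set $\{3, 6\}$).

After a fit, remaining parameter pairs with $|r| > 0.9$ are merged:
positively correlated pairs become one parameter, anticorrelated pairs
become one parameter with the phases of one member flipped
([merge_correlated()]; merging is transitive, the lowest-numbered group
survives as representative).

The resulting published term table -- 96 non-zero terms bound into 38
independent parameters -- ships with the package as a fixture
(`published_constraint_system()`), including the cross-molecule groupings
whose selection combined the rules above with fit-time correlation
information that cannot be regenerated without the original reference
data.  One detail of that table is worth noting: in the beta3 molecule the
HB1-CTA1-CTA2-C term is *not* zeroed but tied to its sp$^3$ triplet.  The
shipped table reproduces this choice verbatim; the algorithmic rules
(3 and 6 above) are implemented and tested independently of it.

```{r}
sys <- published_constraint_system()
count_parameters(sys)
head(format_constraint_table(sys), 8)
```

## MEP matching and the self-consistent fit

A relaxed scan drives one torsion in 5-degree steps (72 per turn) with a
stiff harmonic restraint, two full turns in each direction, each point
seeded from the previous one so that hysteresis is representable; the
global MEP takes the lowest-energy conformation per grid angle and may
therefore contain nonadjacent geometries ([run_relaxed_scan()],
[extract_global_mep()]).

Fitting the MM energies *at the reference geometries* would ignore that a
force field relaxes differently than the reference method; instead the MM
MEP is recomputed under the current parameters -- every point minimized
with all three backbone torsions restrained at the reference values with
$10^5$ kJ/mol/rad$^2$ constants, everything else free -- and its energies
are matched to the reference energies ([compute_mm_mep()]).  Because the
dihedral energy is linear in the $K_\chi$, the match is a linear least
squares problem: reference energy $\approx$ non-fitted MM energy $+$
design $\cdot K$ $+$ one additive offset per MEP.  The offsets absorb the
unrelated energy zeroes of the two methods; all matched points carry equal
weight; unconverged scan points are dropped rather than interpolated.  The
fit is unconstrained in sign, with [sign_adjust()] applied afterwards.
[fit_barrier_heights()] returns the parameters, their standard errors and
correlation matrix, and the overall RMS deviation.

Since new parameters change the MM MEP geometries, the procedure iterates:
recompute MM MEPs (warm-started from the previous iteration's geometries),
refit, repeat until both the largest parameter change and the largest MEP
energy change fall below tolerance ([self_consistent_optimize()]; defaults
$10^{-3}$ kcal/mol and $10^{-2}$ kcal/mol, at most 50 iterations).  At
convergence parameters and MEPs are self-consistent, and rerunning from
the converged state is a no-op.  If the loop fails to converge, the
best-RMS iterate is returned, flagged.

## Numerical choices

*   Internal units are kcal/mol and Angstrom (CHARMM convention);
    restraint constants are accepted in kJ/mol/rad$^2$ and converted with
    the exact thermochemical factor 4.184.
*   Angles live on $(-180^\circ, 180^\circ]$ with $0^\circ$ = cis; all
    angular arithmetic wraps circularly.
*   No nonbonded cutoffs, no periodicity, vacuum electrostatics: the model
    compounds are sub-30-atom gas-phase molecules.  1-2 and 1-3 pairs are
    excluded; 1-4 pairs use special Lennard-Jones parameters where defined
    and unscaled Coulomb.
*   Cartesian minimization is steepest descent with a backtracking line
    search, accepting only energy-lowering steps, converged when the
    largest gradient component drops below 0.24 kcal/mol/A (10 kJ/mol/nm).
    Gradients are analytic for every term and are verified against central
    finite differences in the test suite.
*   The torsion-space backend parametrizes the geometry by its torsion
    variables only (idealized bond lengths and angles), and minimizes with
    BFGS; restrained torsions are matched to variables through their atom
    quadruples.  At $10^5$ kJ/mol/rad$^2$ a restrained torsion deviates
    from its target by far less than 0.1 degree.
*   Degenerate inputs are rejected loudly: collinear dihedral quadruples,
    nonbonded contacts below 0.2 A, empty histograms, non-symmetric
    correlation matrices, probabilities outside (0, 1).

## The synthetic reference generator

Reference MEPs of quantum quality cannot be produced at desk scale, so the
package generates them from a known ground truth instead
([synth_qm_meps()]).  The scenario builds a diamide with the torsion-space
backend at a chosen parameter vector (by default the shipped published
values), runs the relaxed scans, and records the resulting energies --
optionally with Gaussian noise -- as the "reference".  Because the
reference geometries come from the same forward model, the generating
parameters are an exact fixed point of the self-consistent loop, noiseless
recovery is exact to machine precision, and the noise response follows the
least-squares covariance.  The default scenario scans the three backbone
torsions of beta0 over the full 72-point grid (216 matched points, 8
active parameters); this size keeps a full loop iteration at a few
seconds while leaving the design comfortably overdetermined.

What the generator deliberately does *not* emulate: electronic-structure
accuracy (its "reference" is the MM model itself), coupling between
torsions and bond/angle relaxation (idealized internal coordinates are
fixed), and scan hysteresis of stiff real molecules.  A passing recovery
test therefore certifies the correctness of the fitting machinery -- the
design matrix, the restraint protocol, the loop -- not the physical
accuracy of any parameter set fitted to real reference data.

Toy trajectories ([synth_trajectory()]) prescribe state populations,
interproton distances, von Mises torsion scatter and donor-H-acceptor
geometries, with the generating truth returned alongside, so every
validation estimator has an exact expected answer; a bundles variant
generates labelled conformational clusters.

## Validation estimators

The trajectory statistics used to judge a parametrization are implemented
exactly as conventionally defined: optimal-superposition backbone RMSD
(unweighted Kabsch); greedy neighbour-count conformational clustering with
a 1 A default cutoff, central representatives (minimum summed RMSD member)
and ties broken toward the lowest frame index; two-state folding free
energy $\Delta G = -k_B T \ln(p/(1-p))$ with $k_B = 0.0019872$ kcal/mol/K
and $T = 300$ K by default, the folded-state RMSD threshold configurable
(1 A for helix-type analyses, 0.8 A for hairpin-type ones) since the
choice is ultimately arbitrary; NOE violations as
$\langle r^{-6} \rangle^{-1/6} - r_0$ with only positive values relevant;
Karplus couplings $\langle a\cos^2\theta + b\cos\theta + c \rangle$ with
the coefficient sets (6.4, -1.4, 1.9) Hz and (9.5, -1.6, 1.8) Hz;
geometric hydrogen bonds (angle strictly greater than 125 degrees,
H-acceptor distance strictly below 2.4 A, boundary ties counting as not
bonded); the rational switching-function count with $r_0 = 2$ A, $n = 6$,
$m = 10$ and the removable singularity at $r_0$ evaluating to $n/m$; and
circular kernel density estimation with a von Mises kernel (default
bandwidth 5 degrees) plus the plain Scott bandwidth
$\hat\sigma N^{-1/5}$.

```{r}
st <- synth_trajectory("two_state", n_frames = 200, seed = 7,
                       p_folded = 0.5)
p <- mean(st$truth$state == "folded")
folding_free_energy(p)
karplus_j(st$traj, st$truth$torsion_quad)
```

## Limitations

*   The published barrier heights, the reference-fit RMS and all
    trajectory observables of the original study require the original
    quantum-chemical scans and microsecond MD trajectories; the package
    ships the published term table as data and validates its machinery on
    synthetic ground truth instead.
*   Partial charges of the shipped topologies are synthetic placeholders
    following the usual amide/aliphatic charge pattern, as are the generic
    bond/angle/Lennard-Jones parameters; they are internally consistent
    and adequate for exercising the pipeline, not a production force
    field.
*   The steepest-descent Cartesian minimizer is faithful to the reference
    protocol but slow to converge tightly on stiff systems; the
    torsion-space backend is the practical choice for scans of the model
    compounds.
*   Improper-dihedral parametrization, CMAP-style grid corrections,
    solvent, and dynamics are out of scope by design.
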