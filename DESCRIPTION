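Package: betamep
Title: Backbone Torsion Parametrization of Beta-Peptides by Minimum
    Energy Path Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving CHARMM-style proper dihedral parameters for
    acyclic beta-amino-acid backbones by matching molecular-mechanics
    torsional minimum energy paths (MEPs) against reference quantum-chemical
    MEPs.  Provides the four protected beta-alanine diamide model compounds
    with the dedicated backbone atom types (CTA1, CTA2, CTB1, CTB2, HB1,
    HB2), enumeration of the backbone torsions they introduce, a constraint
    algebra that reduces the candidate dihedral terms to an independent
    parameter set (phase restriction to 0/180 degrees, zeroing of aliphatic
    hydrogen terms, supplementary amide pairs, sp3 triplets, histogram-based
    multiplicity selection and correlation merging), a vacuum CHARMM-form
    energy function with restrained steepest-descent minimization, relaxed
    torsion scans, global MEP extraction, a self-consistent least-squares
    barrier-height fit, trajectory validation statistics (backbone RMSD,
    Daura conformational clustering, folding free energies, NOE violations,
    Karplus couplings, hydrogen-bond populations and switching-function
    counts, circular kernel density estimation), synthetic reference-data
    generators, and CHARMM/GROMACS parameter file output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
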