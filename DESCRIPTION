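Package: hydrophi
Title: Hydration-Shell Hydrogen Bonding, Native Contacts and Phi-Value
    Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for solvated protein conformational ensembles,
    centred on the water structure around cold- and hot-denatured proteins.
    Provides geometric hydrogen-bond detection with bulk/interface water
    bookkeeping, the water rotational-anisotropy profile and its absolute
    integral, native-contact maps and the fraction of native contacts Q,
    per-residue Phi-values from ensembles or mutational ddG tables, Bronsted
    statistics, a Phi-restrained simulated-annealing sampler of
    transition-state ensembles on a C-alpha Go-type model, dihedral-based
    secondary-structure populations (alpha/beta/polyproline II), and a
    pairwise nonbonded energy decomposition. Includes generators for all
    required synthetic inputs: peptides with prescribed backbone dihedrals,
    TIP4P/2005 water boxes, a rigid-water Monte Carlo sampler for
    equilibrium bulk-water statistics, contact-probability ensembles, and
    ddG tables with prescribed correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
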