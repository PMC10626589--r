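Package: dbmbe
Title: Energy- and Density-Based Many-Body Expansions for Molecular Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fragment-based total energies for molecular clusters via the
    many-body expansion (MBE). Implements the conventional energy-based
    expansion (eb-MBE) with recursive k-mer interaction energies, and the
    density-based expansion (db-MBE) in which an orbital-free-DFT correction,
    evaluated by numerical quadrature over signed combinations of subsystem
    electron densities on a shared supermolecular Becke grid, accounts for
    higher-order inter-fragment effects. Subsystem energies and densities come
    from pluggable backends: a built-in restricted Hartree-Fock engine with
    Gaussian-basis integrals, an analytic Gaussian mock backend for exact
    closed-form testing, or Molden files exported by external quantum-chemistry
    programs (standard and Orca dialects). Includes PW91k (LC94) kinetic and
    PBE exchange-correlation GGA functionals, deterministic water-cluster and
    Gaussian-toy fixture generators, and a cached end-to-end workflow with
    plain-text and JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
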