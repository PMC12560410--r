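Package: quenchbind
Title: Fluorescence Quenching Analysis of Protein-Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for steady-state fluorescence titrations of
    serum albumin (or any single-fluorophore protein) with a small-molecule
    quencher: inner-filter effect correction, Stern-Volmer fitting and
    quenching-mechanism classification from the temperature dependence of
    Ksv, modified (double-logarithmic) Stern-Volmer fitting of the binding
    constant Ka and site number n, van't Hoff decomposition into binding
    enthalpy and entropy with Gibbs energies and Ross-Subramanian force
    classification, synchronous-fluorescence quenching ratios and spectral
    peak-shift quantification, and site-marker / common-ion competition
    analysis.  A seeded synthetic-data generator emulates 1:1
    static-quenching titrations and Gaussian emission bands so every stage
    is testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
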