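Package: cifsmiles
Title: Chemical-Connectivity SMILES from Crystallographic CIF Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives curated chemical-connectivity SMILES strings from
    crystallographic CIF files: entry triage (Z', disorder, cross-unit bonds),
    symmetry expansion to P1, distance-based bond perception with
    organometallic and ionic representation conventions, Hueckel aromaticity,
    tetrahedral stereochemistry with Sohncke-group racemate handling,
    rule-based curation of crude SMILES, haloanion charge redistribution, and
    classification of discrepancies between two SMILES for the same entry.
    Includes an OpenSMILES-dialect parser, writer and canonicalizer and a
    programmatic catalog of synthetic crystal-structure fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
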