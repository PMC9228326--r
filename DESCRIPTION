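Package: dpdcharge
Title: Dissipative Particle Dynamics with Smeared-Charge Electrostatics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A mesoscopic dissipative particle dynamics (DPD) simulator for
    comparing charge-treatment schemes in soft-matter systems: a truncated
    pure Coulomb scheme (C), Coulomb with exponentially smeared charge
    distributions (CD), and smearing combined with an SP3 splitting term
    that approximates periodic mirror charges (CDS). Includes seeded
    builders for ion-pair water boxes and toy membrane/peptide sandwich
    systems, a momentum-conserving pairwise thermostat, cell-list neighbour
    search, radial distribution function analysis with an ion-pairing
    product-law diagnostic, and a lipid-extraction-rate estimator for
    membrane disruption studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
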