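Package: clonemark
Title: Genomic Clonality Analysis for Multiple Squamous Cell Carcinomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminates lung metastases from second primary tumors in
    patients with multiple squamous cell carcinomas using whole-exome
    derived somatic profiles. Implements high-confidence somatic variant
    filtering, trunk/branch/private mutation partitioning with per-patient
    phylogenies, B-allele-frequency comparison, mutation spectra and
    COSMIC-style signature refitting, a GISTIC-like focal copy-number
    analysis (windowed G-scores with a permutation null, five-tier level
    calls and cosine similarity between tumors), and a per-patient
    metastasis-versus-primary verdict. A synthetic multi-tumor cohort
    generator with known ground truth makes every stage testable without
    access-controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    pracma
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
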