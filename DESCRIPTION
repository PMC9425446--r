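Package: polyclave
Title: Multi-Access and Single-Access Identification Keys from Descriptive
    Character Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and using taxonomic identification keys from
    descriptive knowledge bases (characters scored for taxa, with polymorphism,
    unknown and inapplicable values). Provides a multi-access (interactive)
    identification engine with character ranking by discriminatory power,
    a generator for single-access keys with weighting options, an interpreter
    and consistency checker for dichotomous keys, import/export in CSV, JSON
    and an SDD-flavoured XML interchange format, and a synthetic-data module
    for simulation studies of identification accuracy. Ships a worked knowledge
    base for the ground beetle tribe Platynini (Coleoptera, Carabidae) of the
    southern Levant, together with its printed dichotomous key.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
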