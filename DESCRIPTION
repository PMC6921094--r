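Package: drugfunnel
Title: Genome-Based Drug Repurposing Candidate Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for defining the "repurposable drugged genome": staged
    pharmacodynamic attrition of a DrugBank-style drug catalog (drug type,
    approval status, single known mechanism of action, human-target and
    toxicity exclusions), consolidation of surviving drugs into target-action
    pairs, quality control of exome-array variant annotation tables (rsID
    presence, genotyping missingness, minor allele frequency), and a
    gene-level join of drug targets to eligible variants with coverage
    statistics and a prioritized, marketing-annotated shortlist ready for
    phenome-wide association follow-up. Includes deterministic synthetic-data
    generators for both inputs and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
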