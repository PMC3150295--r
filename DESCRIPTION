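Package: coalpheno
Title: Phenotype Simulation on Coalescent Genotypes for GWAS Power Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attaches qualitative (penetrance-model) or quantitative
    (multi-QTN additive, dominant and epistatic) phenotypes to haplotypes
    produced by coalescent simulators such as ms, msHOT and msms. Causal
    sites can be restricted to an allele-frequency range or to a common
    haploblock defined by the four-gamete test; populations can be
    subsampled by markers and individuals with case/control ascertainment
    and optional removal of the causal markers; datasets are exported in
    the input formats of common association tools (PLINK PED/MAP and
    TPED/TFAM, EMMA matrices, generic TSV). A seeded fixture generator
    replaces external simulators in tests and examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
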