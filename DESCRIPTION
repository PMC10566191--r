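Package: coreselect
Title: Two-Phase Core Collection Selection from SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects germplasm core collections from markers-by-accessions
    SNP genotype matrices using a deterministic two-phase algorithm: a
    covering phase that greedily maximizes allele-class coverage (CV) with
    two acceleration operations, and a thickening phase that enriches the
    core with carriers of rare alleles ranked by a per-accession rarity
    score. Includes the standard evaluation metrics for core collections
    (coverage, base-c Shannon diversity, modified Rogers distance), readers
    and writers for delimited genotype tables and VCF, a seeded simulator
    of biallelic SNP panels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
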