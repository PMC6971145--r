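Package: bfbl
Title: Sequence-Based Allele Nomenclature for the Chicken MHC (BF-BL Region)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A curation engine for naming classical MHC alleles and haplotypes of
    the chicken BF-BL region from sequence rather than from serological haplotype.
    Reads BLB exon 2 and BF exon 2+3 sequences with a tab-separated metadata
    sidecar, validates sequences by independent-amplification evidence, computes
    amino-acid and nucleotide difference matrices over the peptide-binding
    domains, builds neighbour-joining trees with bootstrap support, clusters
    validated sequences into allele groups with per-domain difference cutoffs,
    assigns multi-field allele names in haplotype order, renders haplotype
    strings and Bfbl haplotype names, detects gene-level mosaic haplotypes, and
    maintains an append-only registry with an audit log. Includes a synthetic
    sequence generator with planted locus, group and variant structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    phangorn,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
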