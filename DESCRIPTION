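Package: scimprint
Title: Loss-of-Imprinting Detection from Single-Cell and Bulk RNA-Seq Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects loss of imprinting (LOI) at heterozygous SNPs by combining
    full-length single-cell RNA-seq with patient-matched bulk RNA-seq. Converts
    samtools-mpileup text into base-quality-filtered per-SNP allele counts,
    computes the lesser allele fraction (LAF), calls biallelic expression per
    cell or bulk sample with a one-sided binomial test against a sequencing-error
    null and Benjamini-Hochberg FDR control, and integrates per-cell calls with
    cell-type annotations and a bulk-derived imprinted-SNP reference to
    discriminate cancer LOI from transcript-specific imprinting and random
    monoallelic expression (RME). Includes a synthetic-data generator producing
    sparse per-cell and admixed bulk allele counts with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
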