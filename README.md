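# scimprint

Loss-of-imprinting (LOI) detection from single-cell and bulk RNA-seq allele
counts.

Imprinted genes express a single, parent-of-origin-determined allele. In
cancer the silenced allele is frequently re-expressed, and at a heterozygous
SNP that loss of imprinting shows up as biallelic expression: the lesser
allele fraction, LAF = min(n_ref, n_alt) / (n_ref + n_alt), rises from the
sequencing-error floor toward 0.5. Bulk RNA-seq alone cannot tell whether a
biallelic signal comes from tumor cells (genuine cancer LOI), from normal
cells admixed in the tumor, from transcript-specific imprinting (reciprocally
imprinted transcripts sharing exons), or from random monoallelic expression
(RME). `scimprint` is for analysts integrating full-length (SMART-seq)
single-cell RNA-seq with patient-matched bulk data and a bulk-derived
imprinted-SNP reference to make that attribution.

The core statistic: for each cell (or bulk sample) and SNP with `total`
ref+alt reads and `minor` reads on the lesser allele, a one-sided exact
binomial test of

> minor ~ Binomial(total, e), e = 0.005

against over-representation of the minor allele, evaluated only when
`total >= 4`, Benjamini–Hochberg-adjusted across all covered tests at
reference-imprinted SNPs, and accepted as biallelic expression only with
`q < 0.05` and at least 2 reads on both alleles. Per-cell verdicts are then
integrated with cell-type annotations and the imprinting reference to
classify each (patient, SNP) as `cancer_LOI`, `RME_candidate`,
`transcript_specific_or_not_imprinted`, `imprinted_no_LOI`, or
`uninformative`.

## What's inside

- `parse_pileup_line()`, `count_alleles()`, `count_alleles_stream()` —
  samtools-mpileup text to base-quality-filtered (phred >= 25) per-SNP
  ref/alt/other counts.
- `laf()`, `binom_loi_pvalue()`, `bh_adjust()`, `call_unit()`,
  `call_dataset()` — the biallelic-expression caller.
- `classify_snp()`, `classify_dataset()`, `loi_fraction()`,
  `mean_laf_loi_cells()`, `pseudobulk()`, `summarize_classifications()` —
  single-cell/bulk integration and the per-locus report.
- `scenario()`, `snp_spec()`, `generate_dataset()`, `scenario_reference()`,
  `write_synthetic_pileup()` — a synthetic-data generator with ground truth
  (imprinted, LOI, RME, transcript-specific and homozygous regimes; sparse
  zero-inflated negative-binomial depths; admixed bulk).
- `run_all()` — end-to-end driver writing TSVs and a JSON run manifest;
  `inst/cli/scimprint` is a thin command-line wrapper
  (`simulate | count | test | classify | run-all`).

## Worked example

Two tumor cells from one patient at an imprinted PEG10 SNP, with the minor
allele seen 4 of 23 and 19 of 72 times:

```r
library(scimprint)

counts <- data.frame(unit_id = c("cell1", "cell2"), rsid = "rs13073",
                     ref_count = c(19L, 53L), alt_count = c(4L, 19L),
                     other_count = 0L)
cells <- data.frame(cell_id = counts$unit_id, patient_id = "BC06",
                    cell_type = "tumor", is_tumor = TRUE)
ref <- data.frame(rsid = "rs13073", gene = "PEG10", imprinted_in_normal = TRUE)

calls <- call_dataset(counts, ref)
calls[, c("unit_id", "total", "minor_count", "laf", "p_value", "q_value", "biallelic")]
#>   unit_id total minor_count       laf      p_value      q_value biallelic
#> 1   cell1    23           4 0.1739130 5.129159e-06 5.129159e-06      TRUE
#> 2   cell2    72          19 0.2638889 1.745209e-27 3.490417e-27      TRUE

classify_dataset(calls, cells, ref)[, c("category", "n_loi_cells",
                                        "n_eligible_tumor_cells",
                                        "loi_fraction", "mean_laf_loi_cells")]
#>     category n_loi_cells n_eligible_tumor_cells loi_fraction mean_laf_loi_cells
#> 1 cancer_LOI           2                      2            1           0.218901
```

Both cells reject the sequencing-error null decisively (4 error reads out of
23 would occur with probability 5.1e-06), both carry >= 2 reads per allele,
so the locus is called cancer LOI in 2 of 2 eligible tumor cells (LOI
fraction 100%) with a mean LAF of 0.219 over the LOI cells. Had the same
biallelic calls appeared only in, say, B cells, the category would have been
`RME_candidate`; had the SNP not been flagged imprinted-in-normal in the
reference, `transcript_specific_or_not_imprinted`.

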