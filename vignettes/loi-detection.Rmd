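---
title: "Detecting loss of imprinting from single-cell and bulk allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting loss of imprinting from single-cell and bulk allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scimprint)
```

## The problem

Imprinted genes express one parent-of-origin-determined allele. In cancer the
normally silenced allele is frequently re-activated — loss of imprinting
(LOI). At a heterozygous SNP inside an imprinted transcript, LOI manifests as
biallelic expression: the lesser allele fraction

$$\mathrm{LAF} = \frac{\min(n_\mathrm{ref}, n_\mathrm{alt})}{n_\mathrm{ref} + n_\mathrm{alt}}$$

rises from the sequencing-error floor (~0) toward 0.5. Bulk RNA-seq alone
cannot attribute that signal: it may come from tumor cells (genuine cancer
LOI), from normal cells admixed in the tumor mass, from *transcript-specific
imprinting* — reciprocally imprinted transcripts of one gene sharing exons,
so a SNP in a shared exon looks biallelic even though every transcript is
monoallelic — or from *random monoallelic expression* (RME), where each cell
picks an allele at random and the population pools to a biallelic signal.
Full-length (SMART-seq) single-cell data resolve the cell of origin; a
bulk-derived reference of which SNPs are imprinted in normal tissue resolves
the transcript-level ambiguity. This package implements that integration.

## The statistical model

For each (unit, SNP) — a unit being a single cell or a bulk sample — with
`total` = ref + alt reads and `minor` reads on the lesser allele, we test

* H0: the locus is monoallelic and every minor read is a sequencing error,
  so `minor ~ Binomial(total, e)`;
* H1: the minor allele is over-represented relative to errors.

The one-sided exact p-value is $P(X \ge \mathrm{minor})$ with
$X \sim \mathrm{Binomial}(\mathrm{total}, e)$. The error rate defaults to
$e = 0.005$, a conservative bound for HiSeq-class instruments (median error
below 0.2%). Only units with `total >= 4` are evaluated; p-values are
adjusted by Benjamini–Hochberg over the family of all covered tests at SNPs
flagged imprinted-in-normal in the reference, across all cells; and
significant calls additionally require at least 2 reads on *both* alleles.
The per-allele filter is applied after FDR adjustment, so it prunes the
discovery set without re-shaping the family. Bulk samples run through the
identical test, per patient rather than per cell.

The FDR family matters: q-values change when the family changes. The default
(`fdr_family = "imprinted_covered"`) pools all cells and all
reference-imprinted covered SNPs into one family — in a realistic dataset
that family is large and signal-sparse, which is exactly what makes
borderline two-minor-read outcomes non-significant. `"all_covered"` and a
per-group variant are exposed for sensitivity analyses; single-cell and bulk
tests are always kept in separate families, since pooling them would let the
(deep, many-test) bulk data reshape single-cell q-values.

Non-imprinted SNPs get descriptive LAF and p-values but no FDR-adjusted
verdict — they are outside the family by design. Where the classifier needs
to count biallelic *evidence* at such SNPs (the transcript-specific rows of
the report) it applies the same components descriptively: covered, nominal
p < alpha, both alleles >= 2 reads.

## Classification logic

Per (patient, SNP), with per-cell verdicts, cell annotations, the imprinting
reference, and optionally the same-patient bulk call:

1. SNP not imprinted in normal tissue → `transcript_specific_or_not_imprinted`.
2. No covered cell → `uninformative`.
3. ≥1 biallelic *tumor* cell → `cancer_LOI`, with the LOI fraction estimated
   over eligible (covered) tumor cells and the mean LAF over LOI cells.
4. No tumor biallelic call but ≥1 biallelic call in a known non-tumor
   lineage → `RME_candidate`: the biallelic signal lives in normal cells,
   which argues against cancer LOI and for lineage-restricted RME.
5. Eligible tumor cells but no biallelic call anywhere → `imprinted_no_LOI`.

Two deliberate edge rules. Cells annotated `unknown` count as non-tumor but
are excluded from the RME lineage argument — a biallelic call in an
unannotated cell cannot assign the signal to a lineage, so it never creates
an RME candidate on its own. And when tumor *and* non-tumor cells both carry
biallelic calls, the verdict is `cancer_LOI` with
`nontumor_biallelic_evidence = TRUE`: one reading of the evidence is that
non-cancer biallelic expression disproves LOI, the other that the tumor
signal is genuine and the non-tumor signal is a second phenomenon; we
surface the conflict in the output rather than resolve it silently. Bulk
corroboration is annotative only (a column), never a veto — a bulk sample
can miss LOI confined to a small tumor subpopulation.

A single biallelic tumor cell suffices for `cancer_LOI`; rare single-cell
LOI events are real observations, and `n_loi_cells` is carried in the report
so users can apply stricter cutoffs. One documented arithmetic note: for the
two-cell worked example with counts (4,19) and (19,53), the mean LAF over
LOI cells under the stated averaging rule is (4/23 + 19/72)/2 = 0.219;
published summaries of the same counts sometimes round or recompute this
differently (0.24), and we keep the formula, not the rounded figure.

## Pileup parsing choices

Allele counts come from samtools-mpileup text. Coordinates are 1-based
everywhere. Read-start (`^` + mapping quality), read-end (`$`) and indel runs
produce no calls; `.`/`,` are the reference base; letter case (strand) is
ignored; deletion placeholders and `N`/reference skips consume a quality
character but are dropped entirely — they carry no allele information.
Bases that are neither the SNP's ref nor alt are tallied as `other_count`
and excluded from the test total: the test contrasts the two known alleles
of a biallelic dbSNP site. Base quality is filtered at phred >= 25 (the
recalibrated-quality threshold used upstream of counting), with the
threshold and the ASCII offset (default 33) exposed. Mapping-quality
filtering is assumed done at the BAM level upstream and is not re-applied.

## The synthetic-data generator

The generator produces the full input bundle — SNP table, cell annotations,
sparse cell counts, bulk counts, truth tables — under the same statistical
structure the caller assumes, so every stage is testable without downloads.

* **Depth**: zero-inflated negative binomial. A cell covers a SNP with
  probability `1 - dropout_prob` (default 0.3), then draws depth from
  NB(mean `depth_mean` = 20, size `depth_dispersion` = 2). The strong
  overdispersion and dropout reproduce the sparsity of SMART-seq per-SNP
  coverage, where a 26-cell patient can have only 4 cells with usable
  expression at a locus.
* **Errors**: a misread reports the opposite known allele with probability
  `error_rate` (default 0.005, matching the caller's null); third/fourth
  bases are not simulated by default (the parser routes them to
  `other_count`, which the test ignores).
* **Regimes**: `imprinted` — every cell monoallelic on a per-patient fixed
  allele; `imprinted_with_loi` — tumor cells become biallelic with
  probability `loi_fraction`; `transcript_specific_biallelic` — every cell
  biallelic at ratio 0.5; `homozygous` — single-allele truth everywhere;
  `rme` — cells of the configured lineage are biallelic with a per-cell
  random dominant allele at minor fraction `rme_minor_fraction` (default
  0.3), all other lineages monoallelic on a per-patient fixed allele. The
  RME model is skewed-biallelic rather than strictly monoallelic-per-cell
  because that is how lineage-restricted RME presents in per-cell
  significance calls (FDR-significant biallelic expression confined to
  B cells, with LAFs around 0.27–0.38); a strictly cell-fixed-allele model
  would be invisible to a per-cell biallelic test and undetectable by any
  single-cell classifier.
* **Bulk**: exact sums of the patient's cell counts, plus an admixed
  *biallelic* normal component whose read mass is
  `bulk_admix_normal / (1 - bulk_admix_normal)` times the cell mass
  (default weight 0.3 — tumor purity in resected specimens commonly sits
  near 60–80%, and the value is arbitrary within that range; results that
  depend on it should report it). The admixed component is biallelic by
  construction because it exists to model the confounder under study —
  normal-cell biallelic expression creating perceived LOI in bulk; with
  `bulk_admix_normal = 0` bulk equals the cell sums exactly.
* **Seeding**: one master seed, with per-(patient, SNP) substreams derived
  deterministically, so identical scenarios are bit-identical and subsets
  reproduce.

What the generator does *not* emulate: transcript structure and isoform
switching, PCR-duplicate and alignment artifacts, copy-number alterations,
allele-specific expression gradients within a lineage, and beta-binomial
bursting (available as an optional stress knob, off by default, and never
part of the caller). Passing recovery tests therefore demonstrate that the
statistics and integration logic are correct under the assumed model — not
that the model captures every failure mode of real tumor data.

## Validation problem sizes

The shipped checks use deliberately desk-scale simulations: a null
calibration with ~10^4 covered monoallelic tests (the empirical false
biallelic-verdict proportion stays at or below the FDR level, in practice
near zero because the discrete null and the per-allele filter make the
procedure conservative); LOI-fraction recovery with 200 tumor cells at depth
20 over 20 seeds (planted 75%, recovered ~71–72% — the small downward bias
is the finite-depth probability that a truly biallelic cell shows fewer than
two minor reads, and the estimate stays within the exact binomial 95% band
around 75%); and a 100-seed category-recovery study on a three-SNP scenario.

That scenario is worth describing, because its composition is a design
choice: one patient, 150 cells, 6% tumor cells, B cells ~8% of the non-tumor
compartment. It emulates an immune-dominated metastatic lymph-node specimen —
the setting in which lineage-restricted RME is actually observed and hardest
to separate from LOI — and it gives the BH family the large, signal-sparse
shape of a real screen (hundreds of covered null tests, a dozen true
signals). In small signal-dense families the BH threshold rises high enough
to admit two-minor-read chance outcomes in monoallelic cells, which would
occasionally flip an RME locus to `cancer_LOI` via a single false tumor-cell
verdict; the realistic family shape is what keeps those marginal outcomes
non-significant, and recovery then succeeds on ≈98/100 seeds.

## Limitations

Only heterozygous SNPs are informative; the package trusts the supplied SNP
table and cannot detect that a patient is homozygous (such loci surface as
`imprinted_no_LOI` or `uninformative`). The imprinting reference is taken as
ground truth, so SNPs missing from it are never called LOI. The RME/LOI
boundary is evidential, not quantitative: the package reports lineage
composition rather than imposing a threshold that no available data would
calibrate. And q-values are family-relative: re-running on a subset of cells
or SNPs legitimately changes them.
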