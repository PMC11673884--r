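#' Tumor-cell LOI fraction for one (patient, SNP)
#'
#' Among tumor cells with sufficient coverage (the eligible cells), the
#' fraction carrying a biallelic-expression verdict — the per-patient estimate
#' of how widespread the loss of imprinting is within the tumor.
#'
#' @param calls Per-cell biallelic calls for one patient and SNP
#'   ([call_dataset()] rows).
#' @param cells Cell annotation (`cell_id`, `patient_id`, `cell_type`,
#'   `is_tumor`).
#' @return List with `n_loi`, `n_eligible`, and `fraction` (`NA` when no
#'   eligible tumor cell exists — undefined, not zero).
#' @export
loi_fraction <- function(calls, cells) {
  m <- match(calls$unit_id, cells$cell_id)
  if (anyNA(m)) stop("loi_fraction: calls contain unit_ids absent from cells",
                     call. = FALSE)
  tumor <- cells$is_tumor[m]
  eligible <- tumor & calls$covered
  n_eligible <- sum(eligible)
  n_loi <- sum(eligible & calls$biallelic %in% TRUE)
  list(n_loi = n_loi, n_eligible = n_eligible,
       fraction = if (n_eligible > 0) n_loi / n_eligible else NA_real_)
}

#' Mean LAF over cells with a biallelic verdict
#'
#' The summary printed per locus in the integrated report: after computing the
#' LAF for each cell, the unweighted arithmetic mean over the cells exhibiting
#' biallelic expression (LOI).
#'
#' @param calls Per-cell biallelic calls.
#' @return Mean LAF, or `NA` when no cell has a biallelic verdict.
#' @export
mean_laf_loi_cells <- function(calls) {
  sel <- calls$biallelic %in% TRUE
  if (!any(sel)) return(NA_real_)
  mean(calls$laf[sel])
}

#' Sum one patient's tumor-cell counts into a pseudobulk record
#'
#' Merges all cancer cells of a patient into a single synthetic bulk
#' measurement, trading cell-level resolution for detection power at sparsely
#' covered SNPs.
#'
#' @param counts Allele-count records for one patient's tumor cells at one or
#'   more SNPs.
#' @param patient_id Patient identifier; the output `unit_id` is
#'   `"<patient_id>:pseudobulk"`.
#' @return One allele-count record per SNP with element-wise summed counts.
#' @export
pseudobulk <- function(counts, patient_id) {
  if (!nrow(counts)) stop("pseudobulk: no cells to merge", call. = FALSE)
  agg <- stats::aggregate(counts[c("ref_count", "alt_count", "other_count")],
                          by = list(rsid = counts$rsid), FUN = sum)
  data.frame(unit_id = paste0(patient_id, ":pseudobulk"), rsid = agg$rsid,
             ref_count = agg$ref_count, alt_count = agg$alt_count,
             other_count = agg$other_count, stringsAsFactors = FALSE)
}

#' Classify one (patient, SNP) from integrated evidence
#'
#' Applies the integration strategy: biallelic expression at a SNP not
#' imprinted in normal tissue reflects transcript-specific imprinting (or an
#' unimprinted transcript), not LOI; biallelic expression in at least one
#' tumor cell of an imprinted SNP is cancer LOI; biallelic expression
#' restricted to a non-tumor lineage marks a random-monoallelic-expression
#' (RME) candidate — the bulk signal came from normal cells, disproving
#' cancer LOI; imprinted SNPs with eligible tumor cells but no biallelic call
#' retain normal imprinting; and SNPs with no covered cell are uninformative.
#'
#' Cells of type `"unknown"` count as non-tumor but are excluded from the RME
#' lineage argument (a biallelic call in an unannotated cell cannot assign the
#' signal to a lineage). When both tumor and non-tumor cells carry biallelic
#' calls the verdict is `cancer_LOI`, but `nontumor_biallelic_evidence` is set
#' so the conflict with the non-tumor evidence is surfaced rather than
#' silently resolved.
#'
#' @param calls Per-cell biallelic calls for one patient and SNP.
#' @param cells Cell annotation table.
#' @param reference_entry One imprinting-reference row (`rsid`, `gene`,
#'   `imprinted_in_normal`, optionally `subtype_loi`), or `NULL` (treated as
#'   not imprinted, with a warning).
#' @param bulk_call Optional same-patient bulk biallelic call (one row);
#'   annotative only — it never overrides the single-cell category.
#' @param config A [test_config()]; at non-imprinted SNPs (which carry no
#'   FDR-adjusted verdict because the family is restricted to imprinted SNPs)
#'   biallelic *evidence* is counted descriptively with the same components —
#'   covered, `min_per_allele` reads on both alleles, nominal
#'   `p_value < fdr_alpha`.
#' @return One-row data frame (`snp_classification`): `patient_id`, `rsid`,
#'   `gene`, `category`, `n_loi_cells`, `n_eligible_tumor_cells`,
#'   `loi_fraction`, `mean_laf_loi_cells`, `n_biallelic_cells`,
#'   `nontumor_biallelic_evidence`, `rme_lineages`,
#'   `bulk_same_patient_biallelic`, `bulk_same_patient_laf`,
#'   `reference_subtype_loi`.
#' @export
classify_snp <- function(calls, cells, reference_entry, bulk_call = NULL,
                         config = test_config()) {
  patient_id <- unique(cells$patient_id[match(calls$unit_id, cells$cell_id)])
  patient_id <- patient_id[!is.na(patient_id)]
  if (length(patient_id) > 1L)
    stop("classify_snp: calls span more than one patient", call. = FALSE)
  if (length(patient_id) == 0L) patient_id <- NA_character_
  rsid <- unique(calls$rsid)
  if (length(rsid) != 1L)
    stop("classify_snp: calls must concern exactly one SNP", call. = FALSE)

  if (is.null(reference_entry)) {
    warning("classify_snp: SNP ", rsid,
            " missing from the imprinting reference; treated as not imprinted",
            call. = FALSE)
    reference_entry <- list(rsid = rsid, gene = NA_character_,
                            imprinted_in_normal = FALSE, subtype_loi = NA)
  }

  m <- match(calls$unit_id, cells$cell_id)
  tumor <- cells$is_tumor[m]
  ctype <- cells$cell_type[m]
  imprinted <- isTRUE(reference_entry$imprinted_in_normal)
  bi <- if (imprinted) calls$biallelic %in% TRUE else
    calls$covered & calls$minor_count >= config$min_per_allele &
      !is.na(calls$p_value) & calls$p_value < config$fdr_alpha

  lf <- loi_fraction(calls, cells)
  nontumor_bi <- !tumor & bi
  nontumor_bi_known <- nontumor_bi & ctype != "unknown"

  category <- if (!isTRUE(reference_entry$imprinted_in_normal)) {
    "transcript_specific_or_not_imprinted"
  } else if (!any(calls$covered)) {
    "uninformative"
  } else if (lf$n_loi > 0L) {
    "cancer_LOI"
  } else if (any(nontumor_bi_known)) {
    "RME_candidate"
  } else if (lf$n_eligible > 0L) {
    "imprinted_no_LOI"
  } else {
    "uninformative"
  }

  gene <- if (!is.null(reference_entry$gene) && !is.na(reference_entry$gene))
    reference_entry$gene else
      if (length(stats::na.omit(unique(calls$gene)))) stats::na.omit(unique(calls$gene))[1]
      else NA_character_

  data.frame(
    patient_id = patient_id, rsid = rsid, gene = gene, category = category,
    n_loi_cells = lf$n_loi, n_eligible_tumor_cells = lf$n_eligible,
    loi_fraction = lf$fraction,
    mean_laf_loi_cells = if (any(bi)) mean(calls$laf[bi]) else NA_real_,
    n_biallelic_cells = sum(bi),
    nontumor_biallelic_evidence = any(nontumor_bi),
    rme_lineages = if (any(nontumor_bi_known))
      paste(sort(unique(ctype[nontumor_bi_known])), collapse = ";") else NA_character_,
    bulk_same_patient_biallelic = if (is.null(bulk_call)) NA else
      isTRUE(bulk_call$biallelic),
    bulk_same_patient_laf = if (is.null(bulk_call)) NA_real_ else bulk_call$laf,
    reference_subtype_loi = if (!is.null(reference_entry$subtype_loi))
      isTRUE(reference_entry$subtype_loi) else NA,
    stringsAsFactors = FALSE)
}

#' Classify every (patient, SNP) in a call table
#'
#' Groups per-cell calls by patient and SNP, attaches the matching reference
#' entry and (when supplied) the same-patient bulk call, and runs
#' [classify_snp()] on each group.
#'
#' @param calls Per-cell biallelic calls ([call_dataset()] output).
#' @param cells Cell annotation table.
#' @param reference Imprinting reference table.
#' @param bulk_calls Optional bulk biallelic calls whose `unit_id` is the
#'   patient id.
#' @param config A [test_config()], forwarded to [classify_snp()].
#' @return Data frame of classifications, one row per (patient, SNP).
#' @export
classify_dataset <- function(calls, cells, reference, bulk_calls = NULL,
                             config = test_config()) {
  if (!nrow(calls)) {
    return(data.frame(patient_id = character(), rsid = character(),
                      gene = character(), category = character(),
                      n_loi_cells = integer(), n_eligible_tumor_cells = integer(),
                      loi_fraction = numeric(), mean_laf_loi_cells = numeric(),
                      n_biallelic_cells = integer(),
                      nontumor_biallelic_evidence = logical(),
                      rme_lineages = character(),
                      bulk_same_patient_biallelic = logical(),
                      bulk_same_patient_laf = numeric(),
                      reference_subtype_loi = logical(),
                      stringsAsFactors = FALSE))
  }
  m <- match(calls$unit_id, cells$cell_id)
  if (anyNA(m))
    stop("classify_dataset: calls contain unit_ids absent from cells", call. = FALSE)
  patient <- cells$patient_id[m]
  groups <- split(seq_len(nrow(calls)), list(patient, calls$rsid), drop = TRUE)
  rows <- lapply(groups, function(idx) {
    grp_calls <- calls[idx, , drop = FALSE]
    pid <- patient[idx[1L]]
    rsid <- grp_calls$rsid[1L]
    ref_hit <- which(reference$rsid == rsid)
    ref_entry <- if (length(ref_hit)) as.list(reference[ref_hit[1L], ]) else NULL
    bulk <- NULL
    if (!is.null(bulk_calls)) {
      bh <- which(bulk_calls$unit_id == pid & bulk_calls$rsid == rsid)
      if (length(bh)) bulk <- bulk_calls[bh[1L], ]
    }
    classify_snp(grp_calls, cells, ref_entry, bulk, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$rsid, out$patient_id), , drop = FALSE]
}

#' Report loci with integrated biallelic-expression evidence
#'
#' The integrated summary table: one row per (patient, SNP) with a category
#' other than uninformative and at least one cell carrying a biallelic
#' verdict, sorted by rsid. Mirrors the per-locus columns of the integrated
#' single-cell/bulk report (mean LAF over LOI cells, cell counts, LOI
#' fraction, same-patient bulk corroboration, prior subtype evidence).
#'
#' @param classifications Output of [classify_dataset()].
#' @return Filtered, rsid-sorted data frame.
#' @export
summarize_classifications <- function(classifications) {
  keep <- classifications$category != "uninformative" &
    classifications$n_biallelic_cells >= 1L
  out <- classifications[keep, , drop = FALSE]
  out <- out[order(out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
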