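#' Specify one simulated SNP
#'
#' Describes the allelic regime of a single heterozygous-candidate SNP in a
#' simulated dataset. Regimes mirror the biological situations the caller must
#' distinguish: genomic imprinting (monoallelic in every cell), imprinting with
#' loss of imprinting (LOI) in a fraction of tumor cells, random monoallelic
#' expression (RME) restricted to one lineage, transcript-specific biallelic
#' expression, and homozygosity (a single allele in truth, uninformative for
#' imprinting).
#'
#' @param rsid SNP identifier (unique within a scenario).
#' @param gene Gene label carried through to all output tables.
#' @param regime One of `"imprinted"`, `"imprinted_with_loi"`, `"rme"`,
#'   `"transcript_specific_biallelic"`, `"homozygous"`.
#' @param loi_fraction Fraction of tumor cells rendered biallelic; only used
#'   when `regime = "imprinted_with_loi"`.
#' @param rme_cell_type Lineage label whose cells express both alleles with a
#'   per-cell random dominant allele; only used when `regime = "rme"`.
#' @param heterozygous Logical; `FALSE` is equivalent to `regime = "homozygous"`.
#' @param chrom,pos,ref,alt Optional genomic annotation. When omitted,
#'   [generate_dataset()] assigns deterministic placeholder coordinates and a
#'   seeded ref/alt pair.
#' @return An object of class `snp_spec`.
#' @seealso [scenario()], [generate_dataset()]
#' @export
snp_spec <- function(rsid, gene, regime = c("imprinted", "imprinted_with_loi",
                                            "rme", "transcript_specific_biallelic",
                                            "homozygous"),
                     loi_fraction = 0, rme_cell_type = NULL,
                     heterozygous = TRUE,
                     chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  regime <- match.arg(regime)
  if (!heterozygous) regime <- "homozygous"
  if (regime != "imprinted_with_loi" && loi_fraction != 0) {
    stop("snp_spec: 'loi_fraction' is only meaningful for regime = 'imprinted_with_loi' (rsid ",
         rsid, ")", call. = FALSE)
  }
  if (loi_fraction < 0 || loi_fraction > 1) {
    stop("snp_spec: 'loi_fraction' must lie in [0, 1] (rsid ", rsid, ")", call. = FALSE)
  }
  if (regime == "rme" && is.null(rme_cell_type)) {
    stop("snp_spec: regime 'rme' requires 'rme_cell_type' (rsid ", rsid, ")", call. = FALSE)
  }
  structure(list(rsid = as.character(rsid), gene = as.character(gene),
                 regime = regime, loi_fraction = loi_fraction,
                 rme_cell_type = rme_cell_type,
                 heterozygous = regime != "homozygous",
                 chrom = chrom, pos = pos, ref = ref, alt = alt),
            class = "snp_spec")
}

#' Define a simulation scenario
#'
#' A scenario bundles every knob of the synthetic allele-count generator:
#' cohort structure, sequencing depth model, dropout, per-read error rate, and
#' bulk normal-cell admixture. Defaults emulate a SMART-seq breast-tumor
#' dataset: negative-binomial per-SNP depth around 20 reads with strong
#' overdispersion, frequent dropout, a 0.5% per-read error rate, and a tumor
#' specimen containing infiltrating immune and stromal cells.
#'
#' @param snps List of [snp_spec()] objects.
#' @param n_patients Number of patients.
#' @param cells_per_patient Cells per patient.
#' @param tumor_fraction Fraction of each patient's cells that are tumor cells.
#' @param cell_types Named numeric vector of non-tumor lineage proportions
#'   (must sum to 1). The label `"unknown"` marks cells of ambiguous type.
#' @param depth_mean Mean reads per expressed SNP per cell (negative binomial).
#' @param depth_dispersion Negative-binomial size (shape); smaller values give
#'   more overdispersed depths.
#' @param dropout_prob Probability that a cell has zero coverage at a SNP.
#' @param error_rate Per-read probability that a read reports the allele that
#'   was not transcribed.
#' @param bulk_admix_normal Fraction of the bulk library derived from admixed
#'   normal cells; the admixed component is biallelic at heterozygous SNPs
#'   (the tissue-specific-imprinting confounder), monoallelic at homozygous
#'   ones. `0` makes bulk counts exact sums of the patient's cell counts.
#' @param rme_minor_fraction Expected minor-allele fraction in RME-lineage
#'   cells (the per-cell dominant allele is random).
#' @param biallelic_dispersion Optional beta-binomial overdispersion
#'   (rho in (0,1)) for biallelic draws; `NULL` (default) uses a plain
#'   binomial. A stress-test knob, not part of the caller's model.
#' @param seed Master seed; per-patient and per-SNP substreams are derived
#'   deterministically from it, so subsets of a scenario reproduce.
#' @return An object of class `loi_scenario`.
#' @export
scenario <- function(snps,
                     n_patients = 1L,
                     cells_per_patient = 50L,
                     tumor_fraction = 0.65,
                     cell_types = c(T_cell = 0.40, B_cell = 0.20,
                                    myeloid = 0.20, unknown = 0.20),
                     depth_mean = 20,
                     depth_dispersion = 2,
                     dropout_prob = 0.3,
                     error_rate = 0.005,
                     bulk_admix_normal = 0.3,
                     rme_minor_fraction = 0.3,
                     biallelic_dispersion = NULL,
                     seed = 1L) {
  sc <- structure(list(snps = snps, n_patients = as.integer(n_patients),
                       cells_per_patient = as.integer(cells_per_patient),
                       tumor_fraction = tumor_fraction, cell_types = cell_types,
                       depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                       dropout_prob = dropout_prob, error_rate = error_rate,
                       bulk_admix_normal = bulk_admix_normal,
                       rme_minor_fraction = rme_minor_fraction,
                       biallelic_dispersion = biallelic_dispersion,
                       seed = as.integer(seed)),
                  class = "loi_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("scenario: '", nm, "' must be a fraction in [0, 1]", call. = FALSE)
  }
  chk_frac(sc$tumor_fraction, "tumor_fraction")
  chk_frac(sc$dropout_prob, "dropout_prob")
  chk_frac(sc$error_rate, "error_rate")
  chk_frac(sc$bulk_admix_normal, "bulk_admix_normal")
  chk_frac(sc$rme_minor_fraction, "rme_minor_fraction")
  if (sc$bulk_admix_normal >= 1)
    stop("scenario: 'bulk_admix_normal' must be < 1", call. = FALSE)
  if (!is.numeric(sc$depth_mean) || sc$depth_mean <= 0)
    stop("scenario: 'depth_mean' must be > 0", call. = FALSE)
  if (!is.numeric(sc$depth_dispersion) || sc$depth_dispersion <= 0)
    stop("scenario: 'depth_dispersion' must be > 0", call. = FALSE)
  if (sc$n_patients < 1L) stop("scenario: 'n_patients' must be >= 1", call. = FALSE)
  if (sc$cells_per_patient < 1L)
    stop("scenario: 'cells_per_patient' must be >= 1", call. = FALSE)
  if (is.null(names(sc$cell_types)) || any(!nzchar(names(sc$cell_types))))
    stop("scenario: 'cell_types' must be a named vector of proportions", call. = FALSE)
  if (any(sc$cell_types < 0) || abs(sum(sc$cell_types) - 1) > 1e-8)
    stop("scenario: 'cell_types' proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (!length(sc$snps) || !all(vapply(sc$snps, inherits, logical(1), "snp_spec")))
    stop("scenario: 'snps' must be a non-empty list of snp_spec objects", call. = FALSE)
  rsids <- vapply(sc$snps, `[[`, character(1), "rsid")
  if (anyDuplicated(rsids))
    stop("scenario: duplicate rsid in 'snps': ",
         paste(unique(rsids[duplicated(rsids)]), collapse = ", "), call. = FALSE)
  if (!is.null(sc$biallelic_dispersion)) {
    rho <- sc$biallelic_dispersion
    if (!is.numeric(rho) || rho <= 0 || rho >= 1)
      stop("scenario: 'biallelic_dispersion' must be in (0, 1) or NULL", call. = FALSE)
  }
  invisible(sc)
}

# Deterministic substream seed for (patient, snp) blocks; keeps every derived
# seed inside the 32-bit integer range.
substream_seed <- function(master, patient_i, snp_j = 0L) {
  ((as.double(master) %% 2147483647) * 31 + patient_i * 1000003 + snp_j * 7919) %%
    2147483647
}

#' Draw ref/alt read counts for one cell at one SNP
#'
#' The elementary sampling step of the generator. Monoallelic modes draw
#' minor-allele reads from Binomial(depth, error_rate) — the same null the
#' biallelic-expression caller tests against. Biallelic modes draw reference
#' reads from Binomial(depth, p_ref), optionally beta-binomial when an
#' overdispersion is supplied.
#'
#' @param mode `"mono_ref"`, `"mono_alt"`, `"biallelic"`, or `"silent"`.
#' @param depth Total reads to distribute (>= 0).
#' @param error_rate Per-read misread probability.
#' @param p_ref Expected reference-allele fraction for biallelic draws.
#' @param biallelic_dispersion Optional beta-binomial rho in (0,1).
#' @return Integer vector `c(ref_count, alt_count)` summing to `depth`.
#' @export
sample_cell_counts <- function(mode, depth, error_rate, p_ref = 0.5,
                               biallelic_dispersion = NULL) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 0) stop("sample_cell_counts: depth must be >= 0")
  if (depth == 0L || mode == "silent") return(c(ref_count = 0L, alt_count = 0L))
  if (mode == "mono_ref") {
    alt <- stats::rbinom(1L, depth, error_rate)
    ref <- depth - alt
  } else if (mode == "mono_alt") {
    ref <- stats::rbinom(1L, depth, error_rate)
    alt <- depth - ref
  } else if (mode == "biallelic") {
    p <- if (is.null(biallelic_dispersion)) p_ref else {
      rho <- biallelic_dispersion
      stats::rbeta(1L, p_ref * (1 - rho) / rho, (1 - p_ref) * (1 - rho) / rho)
    }
    ref <- stats::rbinom(1L, depth, p)
    alt <- depth - ref
  } else {
    stop("sample_cell_counts: unknown mode '", mode, "'")
  }
  c(ref_count = as.integer(ref), alt_count = as.integer(alt))
}

#' Generate a synthetic allele-count dataset with ground truth
#'
#' Produces every table the downstream pipeline consumes: a SNP annotation
#' table, cell annotations, sparse per-cell allele counts (only records with at
#' least one read are emitted), per-patient bulk counts (cell sums plus an
#' optional admixed biallelic normal component), and a truth table at both the
#' (cell, SNP) and (patient, SNP) level. Identical scenarios (including the
#' seed) yield bit-identical output.
#'
#' @param sc A [scenario()].
#' @return A list with elements `snp_table`, `cells`, `cell_counts`,
#'   `bulk_counts`, `truth_cells`, `truth_snps`.
#' @examples
#' sc <- scenario(list(snp_spec("rs1", "GENE1", "imprinted")),
#'                cells_per_patient = 10, seed = 42)
#' d <- generate_dataset(sc)
#' head(d$cell_counts)
#' @export
generate_dataset <- function(sc) {
  validate_scenario(sc)
  n_snp <- length(sc$snps)

  # -- SNP annotation table (placeholder coordinates unless supplied) --------
  set.seed(substream_seed(sc$seed, 0L, 0L))
  bases <- c("A", "C", "G", "T")
  snp_table <- do.call(rbind, lapply(seq_len(n_snp), function(j) {
    sp <- sc$snps[[j]]
    ra <- if (is.null(sp$ref) || is.null(sp$alt)) sample(bases, 2L) else c(sp$ref, sp$alt)
    data.frame(rsid = sp$rsid,
               chrom = if (is.null(sp$chrom)) paste0("chr", ((j - 1L) %% 22L) + 1L) else sp$chrom,
               pos = if (is.null(sp$pos)) 1000000L + j * 1000L else as.integer(sp$pos),
               ref = ra[1], alt = ra[2], gene = sp$gene,
               stringsAsFactors = FALSE)
  }))

  # -- cells -----------------------------------------------------------------
  cells <- do.call(rbind, lapply(seq_len(sc$n_patients), function(p) {
    set.seed(substream_seed(sc$seed, p, 0L))
    n <- sc$cells_per_patient
    n_tumor <- round(n * sc$tumor_fraction)
    type <- c(rep("tumor", n_tumor),
              sample(names(sc$cell_types), n - n_tumor, replace = TRUE,
                     prob = sc$cell_types))
    data.frame(cell_id = sprintf("P%02d_C%03d", p, seq_len(n)),
               patient_id = sprintf("P%02d", p),
               cell_type = type,
               is_tumor = type == "tumor",
               stringsAsFactors = FALSE)
  }))

  cc_list <- list(); tc_list <- list(); ts_list <- list(); bk_list <- list()

  for (p in seq_len(sc$n_patients)) {
    pid <- sprintf("P%02d", p)
    pcells <- cells[cells$patient_id == pid, ]
    nc <- nrow(pcells)
    for (j in seq_len(n_snp)) {
      sp <- sc$snps[[j]]
      set.seed(substream_seed(sc$seed, p, j))

      # per-patient fixed expressed allele for monoallelic regimes
      fixed_mode <- sample(c("mono_ref", "mono_alt"), 1L)

      mode <- rep(fixed_mode, nc)
      p_ref <- rep(0.5, nc)
      if (sp$regime == "homozygous") {
        mode[] <- "mono_ref"
      } else if (sp$regime == "imprinted_with_loi") {
        loi <- pcells$is_tumor & stats::runif(nc) < sp$loi_fraction
        mode[loi] <- "biallelic"
      } else if (sp$regime == "transcript_specific_biallelic") {
        mode[] <- "biallelic"
      } else if (sp$regime == "rme") {
        in_lineage <- pcells$cell_type == sp$rme_cell_type
        mode[in_lineage] <- "biallelic"
        # per-cell random dominant allele at the configured skew
        dom_ref <- stats::runif(nc) < 0.5
        p_ref[in_lineage] <- ifelse(dom_ref[in_lineage],
                                    1 - sc$rme_minor_fraction,
                                    sc$rme_minor_fraction)
      }

      depth <- ifelse(stats::runif(nc) < sc$dropout_prob, 0L,
                      stats::rnbinom(nc, size = sc$depth_dispersion,
                                     mu = sc$depth_mean))
      counts <- t(vapply(seq_len(nc), function(i) {
        sample_cell_counts(mode[i], depth[i], sc$error_rate, p_ref[i],
                           sc$biallelic_dispersion)
      }, integer(2)))

      true_mode <- ifelse(depth == 0L, "silent", mode)
      tc_list[[length(tc_list) + 1L]] <- data.frame(
        cell_id = pcells$cell_id, rsid = sp$rsid, true_mode = true_mode,
        stringsAsFactors = FALSE)

      keep <- (counts[, 1L] + counts[, 2L]) > 0L
      if (any(keep)) {
        cc_list[[length(cc_list) + 1L]] <- data.frame(
          unit_id = pcells$cell_id[keep], rsid = sp$rsid,
          ref_count = counts[keep, 1L], alt_count = counts[keep, 2L],
          other_count = 0L, stringsAsFactors = FALSE)
      }

      # bulk: exact cell sums plus admixed biallelic normal component
      ref_sum <- sum(counts[, 1L]); alt_sum <- sum(counts[, 2L])
      if (sc$bulk_admix_normal > 0) {
        n_admix <- round(sc$bulk_admix_normal / (1 - sc$bulk_admix_normal) *
                           (ref_sum + alt_sum))
        if (n_admix > 0) {
          if (sp$regime == "homozygous") {
            ref_sum <- ref_sum + n_admix
          } else {
            a_ref <- stats::rbinom(1L, n_admix, 0.5)
            ref_sum <- ref_sum + a_ref
            alt_sum <- alt_sum + (n_admix - a_ref)
          }
        }
      }
      bk_list[[length(bk_list) + 1L]] <- data.frame(
        unit_id = pid, rsid = sp$rsid, ref_count = ref_sum,
        alt_count = alt_sum, other_count = 0L, stringsAsFactors = FALSE)

      ts_list[[length(ts_list) + 1L]] <- data.frame(
        patient_id = pid, rsid = sp$rsid,
        true_category = switch(sp$regime,
                               imprinted = "imprinted_no_LOI",
                               imprinted_with_loi = "cancer_LOI",
                               rme = "RME",
                               transcript_specific_biallelic = "transcript_specific",
                               homozygous = "uninformative"),
        stringsAsFactors = FALSE)
    }
  }

  empty_counts <- data.frame(unit_id = character(), rsid = character(),
                             ref_count = integer(), alt_count = integer(),
                             other_count = integer(), stringsAsFactors = FALSE)
  cell_counts <- if (length(cc_list)) do.call(rbind, cc_list) else empty_counts
  rownames(cell_counts) <- NULL
  bulk_counts <- do.call(rbind, bk_list); rownames(bulk_counts) <- NULL
  truth_cells <- do.call(rbind, tc_list); rownames(truth_cells) <- NULL
  truth_snps <- do.call(rbind, ts_list); rownames(truth_snps) <- NULL

  list(snp_table = snp_table, cells = cells, cell_counts = cell_counts,
       bulk_counts = bulk_counts, truth_cells = truth_cells,
       truth_snps = truth_snps)
}

#' Build the imprinting reference table implied by a scenario
#'
#' Downstream classification consumes a bulk-RNA-derived reference of which
#' SNPs are imprinted in normal tissue. For synthetic data that reference is
#' implied by the regimes: imprinted, imprinted-with-LOI, and RME SNPs were
#' all reported as imprinted by the (simulated) bulk study — RME genes are
#' precisely the ones bulk data misreport as imprinted — while
#' transcript-specific-biallelic and homozygous SNPs were not.
#'
#' @param sc A [scenario()].
#' @param subtype_loi Optional named logical vector (by rsid) of prior
#'   subtype-level LOI evidence; defaults to `FALSE`.
#' @return Data frame with columns `rsid`, `gene`, `imprinted_in_normal`,
#'   `subtype_loi`.
#' @export
scenario_reference <- function(sc, subtype_loi = NULL) {
  rs <- vapply(sc$snps, `[[`, character(1), "rsid")
  df <- data.frame(
    rsid = rs,
    gene = vapply(sc$snps, `[[`, character(1), "gene"),
    imprinted_in_normal = vapply(sc$snps, function(s)
      s$regime %in% c("imprinted", "imprinted_with_loi", "rme"), logical(1)),
    subtype_loi = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(subtype_loi)) {
    hit <- match(df$rsid, names(subtype_loi))
    df$subtype_loi[!is.na(hit)] <- unname(subtype_loi[hit[!is.na(hit)]])
  }
  df
}

#' Write a synthetic mpileup file for one unit's counts
#'
#' Emits minimal valid mpileup lines (ref reads as `.`/`,`, alt and other
#' reads as base letters, constant base quality) so the pileup parser can be
#' exercised end to end against a known count table.
#'
#' @param counts Count records for one unit (`rsid`, `ref_count`, `alt_count`,
#'   `other_count`).
#' @param snp_table SNP annotation as produced by [generate_dataset()].
#' @param path Output file path (plain text).
#' @param base_quality Phred quality written for every read.
#' @param quality_offset ASCII offset of the quality encoding.
#' @return `path`, invisibly.
#' @export
write_synthetic_pileup <- function(counts, snp_table, path, base_quality = 40L,
                                   quality_offset = 33L) {
  idx <- match(counts$rsid, snp_table$rsid)
  if (anyNA(idx)) stop("write_synthetic_pileup: counts contain rsids absent from snp_table")
  other_base <- function(ref, alt) setdiff(c("A", "C", "G", "T"), c(ref, alt))[1]
  lines <- vapply(seq_len(nrow(counts)), function(i) {
    sn <- snp_table[idx[i], ]
    n_ref <- counts$ref_count[i]; n_alt <- counts$alt_count[i]
    n_oth <- if ("other_count" %in% names(counts)) counts$other_count[i] else 0L
    # alternate '.' and ',' so both strands of the dialect are exercised
    ref_calls <- rep_len(c(".", ","), n_ref)
    calls <- paste0(paste(ref_calls, collapse = ""),
                    strrep(sn$alt, n_alt),
                    strrep(other_base(sn$ref, sn$alt), n_oth))
    depth <- n_ref + n_alt + n_oth
    quals <- strrep(intToUtf8(base_quality + quality_offset), depth)
    paste(sn$chrom, sn$pos, sn$ref, depth, calls, quals, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
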