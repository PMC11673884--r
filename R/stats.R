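#' Configure the biallelic-expression test
#'
#' Holds every threshold of the caller. Defaults follow the published
#' detection settings for HiSeq-class data: a conservative 0.5% per-read
#' sequencing-error null, statistical evaluation only of SNPs with total count
#' >= 4 in the unit under study, Benjamini-Hochberg FDR at 0.05, and a
#' post-FDR requirement of at least two reads on both alleles.
#'
#' @param error_rate Expected per-read sequencing error rate (null minor-allele
#'   probability), in (0, 0.5).
#' @param min_total Minimum ref+alt total for a (unit, SNP) to be statistically
#'   evaluated.
#' @param min_per_allele Minimum reads required on *both* alleles for a
#'   significant test to be accepted as biallelic expression; applied after
#'   FDR adjustment.
#' @param fdr_alpha FDR significance level.
#' @param fdr_family Which tests form the BH family: `"imprinted_covered"`
#'   (default; all covered tests at reference-imprinted SNPs, across all
#'   units), `"all_covered"` (all covered tests regardless of imprinting
#'   status), or `"imprinted_covered_by_group"` (covered imprinted tests
#'   within each unit group, e.g. per patient; requires `unit_groups` in
#'   [call_dataset()]).
#' @return An object of class `loi_test_config`.
#' @export
test_config <- function(error_rate = 0.005, min_total = 4L, min_per_allele = 2L,
                        fdr_alpha = 0.05,
                        fdr_family = c("imprinted_covered", "all_covered",
                                       "imprinted_covered_by_group")) {
  fdr_family <- match.arg(fdr_family)
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 0.5)
    stop("test_config: 'error_rate' must lie in (0, 0.5)", call. = FALSE)
  if (min_total < 1L) stop("test_config: 'min_total' must be >= 1", call. = FALSE)
  if (min_per_allele < 0L) stop("test_config: 'min_per_allele' must be >= 0", call. = FALSE)
  if (fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("test_config: 'fdr_alpha' must lie in (0, 1)", call. = FALSE)
  structure(list(error_rate = error_rate, min_total = as.integer(min_total),
                 min_per_allele = as.integer(min_per_allele),
                 fdr_alpha = fdr_alpha, fdr_family = fdr_family),
            class = "loi_test_config")
}

#' Lesser allele fraction
#'
#' LAF = min(ref, alt) / (ref + alt): 0 for pure monoallelic expression, 0.5
#' for perfectly balanced biallelic expression. Vectorized.
#'
#' @param ref_count,alt_count Non-negative read counts; each pair must sum to
#'   at least 1.
#' @return Numeric vector in \[0, 0.5\].
#' @examples
#' laf(4, 19)   # 0.1739
#' @export
laf <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  if (any(total <= 0))
    stop("laf: undefined for zero total count; exclude uncovered records first",
         call. = FALSE)
  pmin(ref_count, alt_count) / total
}

#' One-sided binomial p-value against the sequencing-error null
#'
#' P(X >= minor_count) for X ~ Binomial(total, error_rate): the probability of
#' seeing at least this many minor-allele reads if the locus were truly
#' monoallelic and every minor read were a sequencing error. Computed with the
#' exact binomial survival function; returns 1 when `minor_count` = 0.
#' Vectorized over counts.
#'
#' @param minor_count Reads supporting the lesser-expressed allele.
#' @param total Total ref+alt reads (>= 1).
#' @param error_rate Null per-read error probability, in (0, 1).
#' @return Numeric vector of p-values.
#' @examples
#' binom_loi_pvalue(4, 23, 0.005)   # ~5.1e-06
#' @export
binom_loi_pvalue <- function(minor_count, total, error_rate = 0.005) {
  if (!is.numeric(error_rate) || any(error_rate <= 0) || any(error_rate >= 1))
    stop("binom_loi_pvalue: 'error_rate' must lie in (0, 1)", call. = FALSE)
  if (any(total < 1L)) stop("binom_loi_pvalue: 'total' must be >= 1", call. = FALSE)
  if (any(minor_count < 0L) || any(minor_count > total))
    stop("binom_loi_pvalue: need 0 <= minor_count <= total", call. = FALSE)
  stats::pbinom(minor_count - 1, total, error_rate, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values with the usual cumulative-minimum monotonicity
#' correction; output order matches input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Evaluate one (unit, SNP) allele-count record
#'
#' Builds a single biallelic-expression call (without FDR adjustment, which is
#' a family-level quantity): total = ref + alt (other bases are excluded from
#' the test), coverage flag, LAF, minor count, and the one-sided binomial
#' p-value when covered.
#'
#' @param ref_count,alt_count Read counts for the two known alleles.
#' @param config A [test_config()].
#' @param unit_id,rsid Identifiers carried into the record.
#' @return One-row data frame with columns `unit_id`, `rsid`, `ref_count`,
#'   `alt_count`, `total`, `minor_count`, `laf`, `p_value`, `covered`.
#' @export
call_unit <- function(ref_count, alt_count, config = test_config(),
                      unit_id = NA_character_, rsid = NA_character_) {
  ref_count <- as.integer(ref_count)
  alt_count <- as.integer(alt_count)
  total <- ref_count + alt_count
  covered <- total >= config$min_total
  data.frame(unit_id = unit_id, rsid = rsid,
             ref_count = ref_count, alt_count = alt_count, total = total,
             minor_count = if (total > 0) min(ref_count, alt_count) else NA_integer_,
             laf = if (total > 0) laf(ref_count, alt_count) else NA_real_,
             p_value = if (covered)
               binom_loi_pvalue(min(ref_count, alt_count), total, config$error_rate)
             else NA_real_,
             covered = covered, stringsAsFactors = FALSE)
}

#' Call biallelic expression across a dataset
#'
#' The full per-unit caller: computes LAF and the one-sided binomial test for
#' every (unit, SNP) allele-count record, adjusts p-values by
#' Benjamini-Hochberg over the configured family (by default all covered tests
#' at SNPs flagged imprinted-in-normal in the reference, across all units),
#' and issues the final biallelic verdict for imprinted SNPs: covered, q <
#' `fdr_alpha`, and at least `min_per_allele` reads on both alleles.
#' Non-imprinted SNPs receive descriptive LAF and p-values but an `NA`
#' verdict; SNPs absent from the reference are treated as non-imprinted with a
#' warning.
#'
#' @param counts Allele-count records (`unit_id`, `rsid`, `ref_count`,
#'   `alt_count`, optionally `other_count`, which is ignored by the test).
#' @param reference Imprinting reference (`rsid`, `gene`,
#'   `imprinted_in_normal`).
#' @param config A [test_config()].
#' @param unit_groups Optional named vector mapping `unit_id` to a family
#'   group (e.g. patient); required for
#'   `fdr_family = "imprinted_covered_by_group"`.
#' @return Data frame with columns `unit_id`, `rsid`, `gene`, `ref_count`,
#'   `alt_count`, `total`, `minor_count`, `laf`, `p_value`, `q_value`,
#'   `covered`, `biallelic`.
#' @export
call_dataset <- function(counts, reference, config = test_config(),
                         unit_groups = NULL) {
  required <- c("unit_id", "rsid", "ref_count", "alt_count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols))
    stop("call_dataset: counts lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  hit <- match(counts$rsid, reference$rsid)
  if (anyNA(hit)) {
    warning("call_dataset: ", sum(is.na(hit)),
            " record(s) at SNPs absent from the reference; treated as non-imprinted",
            call. = FALSE)
  }
  gene <- ifelse(is.na(hit), NA_character_, reference$gene[hit])
  imprinted <- !is.na(hit) & reference$imprinted_in_normal[hit]

  total <- counts$ref_count + counts$alt_count
  minor <- pmin(counts$ref_count, counts$alt_count)
  covered <- total >= config$min_total
  lafv <- ifelse(total > 0, minor / total, NA_real_)
  p <- rep(NA_real_, nrow(counts))
  p[covered] <- binom_loi_pvalue(minor[covered], total[covered], config$error_rate)

  in_family <- switch(config$fdr_family,
                      imprinted_covered = covered & imprinted,
                      all_covered = covered,
                      imprinted_covered_by_group = covered & imprinted)
  q <- rep(NA_real_, nrow(counts))
  if (config$fdr_family == "imprinted_covered_by_group") {
    if (is.null(unit_groups))
      stop("call_dataset: fdr_family 'imprinted_covered_by_group' requires 'unit_groups'",
           call. = FALSE)
    grp <- unname(unit_groups[counts$unit_id])
    if (anyNA(grp[in_family]))
      stop("call_dataset: 'unit_groups' lacks entries for some units", call. = FALSE)
    for (g in unique(grp[in_family])) {
      sel <- in_family & grp == g
      q[sel] <- bh_adjust(p[sel])
    }
  } else if (any(in_family)) {
    q[in_family] <- bh_adjust(p[in_family])
  }

  biallelic <- rep(NA, nrow(counts))
  biallelic[imprinted] <- covered[imprinted] &
    !is.na(q[imprinted]) & q[imprinted] < config$fdr_alpha &
    minor[imprinted] >= config$min_per_allele
  out <- data.frame(unit_id = counts$unit_id, rsid = counts$rsid, gene = gene,
                    ref_count = counts$ref_count, alt_count = counts$alt_count,
                    total = total, minor_count = minor, laf = lafv,
                    p_value = p, q_value = q, covered = covered,
                    biallelic = biallelic, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
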