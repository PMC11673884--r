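# Independent oracles and fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation, kept free of any package
# internals, so the implementation is checked against an independent route.

# Definitional Benjamini-Hochberg step-up: sort ascending, q_(i) =
# min_{k >= i} m * p_(k) / k (capped at 1), mapped back to input order.
naive_bh <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Naive exact binomial upper tail by term-wise summation.
naive_binom_tail <- function(minor, total, e) {
  if (minor == 0) return(1)
  sum(vapply(minor:total, function(k) choose(total, k) * e^k * (1 - e)^(total - k),
             numeric(1)))
}

# Naive quality-filtered allele tally from a calls data frame.
naive_count <- function(calls, ref, alt, min_q) {
  keep <- calls$qual >= min_q & !(calls$base %in% c("del", "N"))
  b <- calls$base[keep]
  c(ref = sum(b == ref), alt = sum(b == alt), other = sum(b != ref & b != alt))
}

# Random mpileup line generator with constructive ground truth: assembles the
# base string token by token (enumerating marker placements), so the expected
# call sequence is known by construction rather than by parsing.
build_random_pileup_line <- function(chrom = "chr1", pos = 1000L, ref = "A") {
  n_tok <- sample(1:12, 1)
  bases <- character(0)
  truth <- character(0)
  push_call <- function(token, base) {
    bases <<- c(bases, token)
    truth <<- c(truth, base)
  }
  for (i in seq_len(n_tok)) {
    kind <- sample(c("refmatch", "mismatch", "lower", "start", "end", "ins",
                     "del_run", "delbase", "refskip"), 1)
    if (kind == "refmatch") {
      push_call(sample(c(".", ","), 1), ref)
    } else if (kind == "mismatch") {
      b <- sample(setdiff(c("A", "C", "G", "T", "N"), ref), 1)
      push_call(b, b)
    } else if (kind == "lower") {
      b <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      push_call(tolower(b), b)
    } else if (kind == "start") {
      # '^' + mapping quality char, then the first base of that read
      bases <- c(bases, paste0("^", intToUtf8(sample(33:90, 1))))
      push_call(sample(c(".", ","), 1), ref)
    } else if (kind == "end") {
      push_call(sample(c(".", ","), 1), ref)
      bases <- c(bases, "$")
    } else if (kind == "ins") {
      push_call(sample(c(".", ","), 1), ref)
      len <- sample(c(1:3, 10:12), 1)  # exercise multi-digit lengths
      bases <- c(bases, paste0(sample(c("+", "-"), 1), len,
                               paste(sample(c("A", "C", "G", "T"), len,
                                            replace = TRUE), collapse = "")))
    } else if (kind == "del_run") {
      len <- sample(1:3, 1)
      bases <- c(bases, paste0("-", len,
                               paste(sample(c("A", "C", "G", "T"), len,
                                            replace = TRUE), collapse = "")))
      # the deletion run annotates the *previous* read; emits no call itself
    } else if (kind == "delbase") {
      push_call("*", "del")
    } else if (kind == "refskip") {
      push_call(sample(c(">", "<"), 1), "N")
    }
  }
  if (!length(truth)) push_call(".", ref)
  quals <- sample(0:41, length(truth), replace = TRUE)
  list(line = paste(chrom, pos, ref, length(truth),
                    paste(bases, collapse = ""),
                    intToUtf8(quals + 33L, multiple = FALSE),
                    sep = "\t"),
       truth_base = truth, truth_qual = quals)
}

# Small reference table for hand-built call fixtures.
make_reference <- function(rsids, genes = rsids, imprinted = TRUE) {
  data.frame(rsid = rsids, gene = genes,
             imprinted_in_normal = rep_len(imprinted, length(rsids)),
             subtype_loi = FALSE, stringsAsFactors = FALSE)
}

# Hand-built per-cell call rows for classification tests.
make_call <- function(unit_id, rsid, ref, alt, biallelic, covered = TRUE,
                      gene = "G") {
  total <- ref + alt
  data.frame(unit_id = unit_id, rsid = rsid, gene = gene, ref_count = ref,
             alt_count = alt, total = total, minor_count = min(ref, alt),
             laf = if (total > 0) min(ref, alt) / total else NA_real_,
             p_value = NA_real_, q_value = NA_real_, covered = covered,
             biallelic = biallelic, stringsAsFactors = FALSE)
}

make_cells <- function(cell_ids, patient = "P01", cell_type = "tumor") {
  data.frame(cell_id = cell_ids, patient_id = patient,
             cell_type = rep_len(cell_type, length(cell_ids)),
             is_tumor = rep_len(cell_type, length(cell_ids)) == "tumor",
             stringsAsFactors = FALSE)
}

# The immune-rich specimen used for classification-recovery checks: few tumor
# cells, a B-cell minority carrying the RME signal, and a large sparse-signal
# BH family, emulating a metastatic lymph-node sample.
recovery_scenario <- function(seed) {
  scenario(
    snps = list(
      snp_spec("rs_loi", "GENE_LOI", "imprinted_with_loi", loi_fraction = 0.75),
      snp_spec("rs_rme", "GENE_RME", "rme", rme_cell_type = "B_cell"),
      snp_spec("rs_tsb", "GENE_TSB", "transcript_specific_biallelic")),
    n_patients = 1L, cells_per_patient = 150L, tumor_fraction = 0.06,
    cell_types = c(T_cell = 0.62, myeloid = 0.20, B_cell = 0.08, unknown = 0.10),
    depth_mean = 20, depth_dispersion = 2, dropout_prob = 0.2,
    error_rate = 0.005, bulk_admix_normal = 0, seed = seed)
}

# One classification-recovery replicate: TRUE iff every (patient, SNP) truth
# category is recovered exactly.
run_recovery_replicate <- function(seed) {
  sc <- recovery_scenario(seed)
  d <- generate_dataset(sc)
  ref <- scenario_reference(sc)
  calls <- call_dataset(d$cell_counts, ref)
  cl <- classify_dataset(calls, d$cells, ref)
  truth_map <- c(cancer_LOI = "cancer_LOI", RME = "RME_candidate",
                 transcript_specific = "transcript_specific_or_not_imprinted",
                 imprinted_no_LOI = "imprinted_no_LOI",
                 uninformative = "uninformative")
  key <- paste(cl$patient_id, cl$rsid)
  tkey <- paste(d$truth_snps$patient_id, d$truth_snps$rsid)
  expected <- truth_map[d$truth_snps$true_category[match(key, tkey)]]
  nrow(cl) == nrow(d$truth_snps) && all(cl$category == unname(expected))
}
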