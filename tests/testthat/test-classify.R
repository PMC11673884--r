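ref1 <- make_reference("rs1", "GENE1")

test_that("loi_fraction counts eligible tumor cells and leaves 0/0 undefined", {
  cells <- make_cells(sprintf("c%02d", 1:14),
                      cell_type = c(rep("tumor", 13), "T_cell"))
  calls <- rbind(
    do.call(rbind, lapply(1:9, function(i)
      make_call(sprintf("c%02d", i), "rs1", 10, 8, TRUE))),
    do.call(rbind, lapply(10:12, function(i)
      make_call(sprintf("c%02d", i), "rs1", 10, 0, FALSE))),
    make_call("c13", "rs1", 2, 0, FALSE, covered = FALSE),   # below coverage
    make_call("c14", "rs1", 10, 8, TRUE))                    # non-tumor
  lf <- loi_fraction(calls, cells)
  expect_identical(lf$n_loi, 9L)
  expect_identical(lf$n_eligible, 12L)
  expect_equal(lf$fraction, 0.75)

  lf2 <- loi_fraction(make_call("c13", "rs1", 2, 0, FALSE, covered = FALSE), cells)
  expect_identical(lf2$n_eligible, 0L)
  expect_true(is.na(lf2$fraction))
})

test_that("mean LAF over LOI cells follows the per-locus averaging rule", {
  expect_equal(mean_laf_loi_cells(make_call("c1", "rs1", 10, 6, TRUE)),
               6 / 16)
  two <- rbind(make_call("c1", "rs1", 19, 4, TRUE),
               make_call("c2", "rs1", 53, 19, TRUE))
  expect_equal(mean_laf_loi_cells(two), mean(c(4 / 23, 19 / 72)), tolerance = 1e-12)
  expect_equal(mean_laf_loi_cells(two), 0.2189, tolerance = 1e-4)
  # non-biallelic cells are excluded
  expect_true(is.na(mean_laf_loi_cells(make_call("c1", "rs1", 10, 0, FALSE))))
  # brute-force mean on random call sets
  set.seed(201)
  for (i in 1:100) {
    n <- sample(1:20, 1)
    cs <- do.call(rbind, lapply(seq_len(n), function(j)
      make_call(paste0("c", j), "rs1", sample(2:30, 1), sample(2:30, 1),
                runif(1) < 0.5)))
    sel <- cs$biallelic
    expected <- if (any(sel)) sum(cs$laf[sel]) / sum(sel) else NA_real_
    expect_equal(mean_laf_loi_cells(cs), expected, tolerance = 1e-12)
  }
})

test_that("pseudobulk sums counts element-wise per SNP", {
  one <- data.frame(unit_id = "c1", rsid = "rs1", ref_count = 4L, alt_count = 19L,
                    other_count = 0L, stringsAsFactors = FALSE)
  pb1 <- pseudobulk(one, "BC06")
  expect_identical(pb1$ref_count, 4L)
  expect_identical(pb1$alt_count, 19L)
  expect_identical(pb1$unit_id, "BC06:pseudobulk")

  two <- rbind(one, data.frame(unit_id = "c2", rsid = "rs1", ref_count = 19L,
                               alt_count = 53L, other_count = 0L))
  pb2 <- pseudobulk(two, "BC06")
  expect_identical(pb2$ref_count, 23L)
  expect_identical(pb2$alt_count, 72L)

  # conservation: pseudobulk of all synthetic cells equals the generator's
  # bulk output when no normal admixture is simulated
  sc <- scenario(list(snp_spec("rs1", "G1", "imprinted_with_loi", loi_fraction = 0.5)),
                 cells_per_patient = 25, tumor_fraction = 1,
                 bulk_admix_normal = 0, seed = 77)
  d <- generate_dataset(sc)
  pb <- pseudobulk(d$cell_counts, "P01")
  expect_identical(pb$ref_count, d$bulk_counts$ref_count)
  expect_identical(pb$alt_count, d$bulk_counts$alt_count)
})

test_that("classification follows the integration strategy", {
  cells <- make_cells(sprintf("c%02d", 1:15),
                      cell_type = c(rep("tumor", 12), "B_cell", "B_cell", "unknown"))

  # imprinted SNP, 9 of 12 eligible tumor cells biallelic -> cancer LOI at 75%
  calls_loi <- do.call(rbind, lapply(1:12, function(i)
    make_call(sprintf("c%02d", i), "rs1", 10, if (i <= 9) 8 else 0, i <= 9)))
  cl <- classify_snp(calls_loi, cells, as.list(ref1[1, ]))
  expect_identical(cl$category, "cancer_LOI")
  expect_equal(cl$loi_fraction, 0.75)
  expect_identical(cl$n_loi_cells, 9L)
  expect_false(cl$nontumor_biallelic_evidence)

  # biallelic calls only in B cells -> RME candidate
  calls_rme <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      make_call(sprintf("c%02d", i), "rs1", 10, 0, FALSE))),
    make_call("c13", "rs1", 10, 7, TRUE),
    make_call("c14", "rs1", 12, 6, TRUE))
  cl2 <- classify_snp(calls_rme, cells, as.list(ref1[1, ]))
  expect_identical(cl2$category, "RME_candidate")
  expect_identical(cl2$rme_lineages, "B_cell")
  expect_identical(cl2$n_loi_cells, 0L)

  # biallelic only in an unknown-type cell: excluded from the RME argument
  calls_unk <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      make_call(sprintf("c%02d", i), "rs1", 10, 0, FALSE))),
    make_call("c15", "rs1", 10, 7, TRUE))
  cl3 <- classify_snp(calls_unk, cells, as.list(ref1[1, ]))
  expect_identical(cl3$category, "imprinted_no_LOI")
  expect_true(cl3$nontumor_biallelic_evidence)

  # non-imprinted SNP wins over everything else
  ref_bi <- list(rsid = "rs1", gene = "GENE1", imprinted_in_normal = FALSE,
                 subtype_loi = FALSE)
  cl4 <- classify_snp(calls_loi, cells, ref_bi)
  expect_identical(cl4$category, "transcript_specific_or_not_imprinted")

  # zero covered cells -> uninformative
  calls_none <- make_call("c01", "rs1", 1, 0, FALSE, covered = FALSE)
  cl5 <- classify_snp(calls_none, cells, as.list(ref1[1, ]))
  expect_identical(cl5$category, "uninformative")

  # tumor and non-tumor biallelic together: cancer_LOI with the conflict flagged
  calls_mix <- rbind(calls_loi, make_call("c13", "rs1", 10, 7, TRUE))
  cl6 <- classify_snp(calls_mix, cells, as.list(ref1[1, ]))
  expect_identical(cl6$category, "cancer_LOI")
  expect_true(cl6$nontumor_biallelic_evidence)

  # missing reference entry: warned, treated as non-imprinted
  expect_warning(cl7 <- classify_snp(calls_loi, cells, NULL), "missing from")
  expect_identical(cl7$category, "transcript_specific_or_not_imprinted")
})

test_that("classification is invariant to cell ordering", {
  cells <- make_cells(sprintf("c%02d", 1:10),
                      cell_type = c(rep("tumor", 7), rep("B_cell", 3)))
  calls <- rbind(
    do.call(rbind, lapply(1:7, function(i)
      make_call(sprintf("c%02d", i), "rs1", 12, if (i <= 3) 9 else 0, i <= 3))),
    make_call("c08", "rs1", 10, 6, TRUE))
  base <- classify_snp(calls, cells, as.list(ref1[1, ]))
  set.seed(202)
  for (i in 1:10) {
    shuffled <- calls[sample(nrow(calls)), ]
    expect_equal(classify_snp(shuffled, cells, as.list(ref1[1, ])), base)
  }
})

test_that("bulk corroboration is annotative and never changes the category", {
  cells <- make_cells(c("c1", "c2"))
  calls <- rbind(make_call("c1", "rs1", 10, 8, TRUE),
                 make_call("c2", "rs1", 10, 0, FALSE))
  bulk_yes <- make_call("P01", "rs1", 100, 27, TRUE)
  bulk_no <- make_call("P01", "rs1", 120, 1, FALSE)
  with_bulk <- classify_snp(calls, cells, as.list(ref1[1, ]), bulk_yes)
  without <- classify_snp(calls, cells, as.list(ref1[1, ]), bulk_no)
  expect_identical(with_bulk$category, without$category)
  expect_true(with_bulk$bulk_same_patient_biallelic)
  expect_equal(with_bulk$bulk_same_patient_laf, 27 / 127)
  expect_false(without$bulk_same_patient_biallelic)
})

test_that("summarize_classifications reports informative loci sorted by rsid", {
  empty_calls <- make_call("x", "rs1", 1, 1, TRUE)[0, ]
  expect_identical(nrow(summarize_classifications(
    classify_dataset(empty_calls, make_cells("c1"), ref1))), 0L)

  sc <- scenario(
    snps = list(snp_spec("rs_b_loi", "G1", "imprinted_with_loi", loi_fraction = 0.75),
                snp_spec("rs_a_rme", "G2", "rme", rme_cell_type = "B_cell"),
                snp_spec("rs_c_tsb", "G3", "transcript_specific_biallelic")),
    cells_per_patient = 60, tumor_fraction = 0.3,
    cell_types = c(B_cell = 0.4, T_cell = 0.6),
    depth_mean = 25, dropout_prob = 0.1, seed = 205)
  d <- generate_dataset(sc)
  ref <- scenario_reference(sc)
  calls <- call_dataset(d$cell_counts, ref)
  cl <- classify_dataset(calls, d$cells, ref)
  report <- summarize_classifications(cl)
  expect_identical(report$rsid, sort(report$rsid))
  expect_lte(nrow(report), nrow(cl))
  expect_setequal(report$category,
                  c("cancer_LOI", "RME_candidate",
                    "transcript_specific_or_not_imprinted"))
})

test_that("planted categories are recovered on a well-powered seed", {
  expect_true(run_recovery_replicate(990001))
})
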