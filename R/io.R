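#' Read a SNP annotation table (TSV or VCF)
#'
#' Loads heterozygous-candidate SNPs into the standard annotation layout:
#' `rsid`, `chrom`, `pos` (1-based), `ref`, `alt`, `gene`. TSV input must
#' carry those columns (gene may be absent; filled with `NA`). VCF input maps
#' CHROM/POS/ID/REF/ALT; a `GENE=` INFO tag supplies the gene label when
#' present. Multi-allelic VCF rows, invalid alleles, `ref == alt` rows, and
#' duplicated rsIDs are rejected with row-numbered errors.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"vcf"`.
#' @return Validated SNP annotation data frame.
#' @export
read_snp_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_snp_table: no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    # colClasses: a lone "T"/"F" allele must not be parsed as a logical
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("rsid", "chrom", "pos", "ref", "alt")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
      stop("read_snp_table: missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (!"gene" %in% names(df)) df$gene <- NA_character_
    df <- df[c("rsid", "chrom", "pos", "ref", "alt", "gene")]
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix  # CHROM POS ID REF ALT QUAL FILTER INFO
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      stop("read_snp_table: multi-allelic VCF record(s) at row(s) ",
           paste(which(multi), collapse = ", "),
           "; split or filter them upstream", call. = FALSE)
    info <- fix[, "INFO"]
    gene <- ifelse(grepl("(^|;)GENE=", info),
                   sub(".*(?:^|;)GENE=([^;]*).*", "\\1", info), NA_character_)
    df <- data.frame(rsid = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                     alt = fix[, "ALT"], gene = gene, stringsAsFactors = FALSE)
  }
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  bad_allele <- !(df$ref %in% c("A", "C", "G", "T")) |
    !(df$alt %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    stop("read_snp_table: invalid ref/alt allele at row(s) ",
         paste(which(bad_allele), collapse = ", "), call. = FALSE)
  same <- df$ref == df$alt
  if (any(same))
    stop("read_snp_table: ref equals alt at row(s) ",
         paste(which(same), collapse = ", "), call. = FALSE)
  if (any(is.na(df$pos) | df$pos < 1L))
    stop("read_snp_table: positions must be 1-based positive integers", call. = FALSE)
  dup <- duplicated(df$rsid)
  if (any(dup))
    stop("read_snp_table: duplicated rsID(s): ",
         paste(unique(df$rsid[dup]), collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Read an imprinting reference table
#'
#' TSV with columns `rsid`, `gene`, `imprinted_in_normal` (logical or 0/1) and
#' optionally `subtype_loi` or per-subtype logical columns prefixed `loi_`.
#'
#' @param path File path.
#' @return Validated reference data frame.
#' @export
read_reference <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "gene", "imprinted_in_normal")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_reference: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$imprinted_in_normal <- as.logical(df$imprinted_in_normal)
  if (anyNA(df$imprinted_in_normal))
    stop("read_reference: 'imprinted_in_normal' must be logical or 0/1", call. = FALSE)
  if (anyDuplicated(df$rsid))
    stop("read_reference: duplicated rsID(s)", call. = FALSE)
  if ("subtype_loi" %in% names(df)) df$subtype_loi <- as.logical(df$subtype_loi)
  df
}

#' Read a cell annotation table
#'
#' TSV with columns `cell_id`, `patient_id`, `cell_type`, `is_tumor`.
#'
#' @param path File path.
#' @return Validated cell annotation data frame.
#' @export
read_cells <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "patient_id", "cell_type", "is_tumor")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_cells: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$is_tumor <- as.logical(df$is_tumor)
  if (anyDuplicated(df$cell_id))
    stop("read_cells: duplicated cell_id(s)", call. = FALSE)
  df
}

#' Read an allele-count table
#'
#' TSV with columns `unit_id`, `rsid`, `ref_count`, `alt_count`,
#' `other_count`.
#'
#' @param path File path.
#' @return Allele-count data frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "rsid", "ref_count", "alt_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_counts: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"other_count" %in% names(df)) df$other_count <- 0L
  if (any(df$ref_count < 0 | df$alt_count < 0 | df$other_count < 0))
    stop("read_counts: counts must be non-negative", call. = FALSE)
  df
}

#' Write a table as TSV with a fixed column order
#'
#' The package's interchange writer: tab-separated, header, no quoting, no row
#' names, `NA` written as empty string. Re-reading with [read_counts()] and
#' friends reproduces the in-memory table.
#'
#' @param df Data frame.
#' @param path Output path (a `.gz` suffix writes gzip).
#' @param columns Optional explicit column order.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, columns = NULL) {
  if (!is.null(columns)) df <- df[columns]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the full detection pipeline
#'
#' Chains allele counting (when pileups rather than count tables are given),
#' per-cell and per-patient-bulk biallelic-expression testing, integration,
#' and summary, writing every intermediate TSV plus a JSON run manifest
#' (package version, thresholds, seed, per-stage record counts, configuration
#' hash). Deterministic given fixed inputs.
#'
#' @param snp_table SNP annotation data frame or path ([read_snp_table()]).
#' @param cells Cell annotation data frame or path.
#' @param reference Imprinting reference data frame or path.
#' @param cell_counts Per-cell allele counts (data frame or path), or `NULL`
#'   when `pileups` is given.
#' @param pileups Optional named character vector of per-cell mpileup paths
#'   (names are cell ids).
#' @param bulk_counts Optional per-patient bulk allele counts (data frame or
#'   path).
#' @param config A [test_config()].
#' @param min_base_quality Minimum phred base quality for pileup counting.
#' @param outdir Output directory (created if missing).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @param verbose Emit per-stage record counts via `message()`.
#' @return Invisibly, a list with `cell_calls`, `bulk_calls`,
#'   `classifications`, `report`, `manifest`.
#' @export
run_all <- function(snp_table, cells, reference, cell_counts = NULL,
                    pileups = NULL, bulk_counts = NULL,
                    config = test_config(), min_base_quality = 25L,
                    outdir = ".", seed = NA_integer_, verbose = TRUE) {
  say <- function(...) if (verbose) message("[scimprint] ", ...)
  load_df <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

  snp_table <- load_df(snp_table, read_snp_table)
  cells <- load_df(cells, read_cells)
  reference <- load_df(reference, read_reference)
  bulk_counts <- load_df(bulk_counts, read_counts)

  if (is.null(cell_counts)) {
    if (is.null(pileups))
      stop("run_all: supply either 'cell_counts' or 'pileups'", call. = FALSE)
    say("counting alleles from ", length(pileups), " pileup file(s)")
    cell_counts <- do.call(rbind, lapply(names(pileups), function(id) {
      count_alleles_stream(pileups[[id]], snp_table, min_base_quality, id)
    }))
  } else {
    cell_counts <- load_df(cell_counts, read_counts)
  }
  say(nrow(cell_counts), " cell-level allele-count record(s) across ",
      length(unique(cell_counts$unit_id)), " cell(s)")

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  cell_calls <- call_dataset(cell_counts, reference, config)
  say(sum(cell_calls$covered), " covered cell-level test(s); ",
      sum(cell_calls$biallelic %in% TRUE), " biallelic verdict(s)")

  bulk_calls <- NULL
  if (!is.null(bulk_counts) && nrow(bulk_counts)) {
    bulk_calls <- call_dataset(bulk_counts, reference, config)
    say(sum(bulk_calls$covered), " covered bulk test(s); ",
        sum(bulk_calls$biallelic %in% TRUE), " biallelic verdict(s)")
  }

  classifications <- classify_dataset(cell_calls, cells, reference, bulk_calls,
                                      config)
  report <- summarize_classifications(classifications)
  say(nrow(classifications), " (patient, SNP) classification(s); ",
      nrow(report), " reported locus/loci")

  call_cols <- c("unit_id", "rsid", "gene", "ref_count", "alt_count", "total",
                 "minor_count", "laf", "p_value", "q_value", "covered", "biallelic")
  write_tsv(cell_calls, file.path(outdir, "cell_calls.tsv"), call_cols)
  if (!is.null(bulk_calls))
    write_tsv(bulk_calls, file.path(outdir, "bulk_calls.tsv"), call_cols)
  write_tsv(classifications, file.path(outdir, "classifications.tsv"))
  write_tsv(report, file.path(outdir, "report.tsv"))

  cfg_flat <- list(error_rate = config$error_rate, min_total = config$min_total,
                   min_per_allele = config$min_per_allele,
                   fdr_alpha = config$fdr_alpha, fdr_family = config$fdr_family,
                   min_base_quality = min_base_quality)
  manifest <- list(
    package = "scimprint",
    version = as.character(utils::packageVersion("scimprint")),
    seed = seed,
    config = cfg_flat,
    config_hash = config_hash(cfg_flat),
    counts = list(cells = nrow(cell_counts),
                  bulk = if (is.null(bulk_counts)) 0L else nrow(bulk_counts),
                  covered_cell_tests = sum(cell_calls$covered),
                  biallelic_cells = sum(cell_calls$biallelic %in% TRUE),
                  classifications = nrow(classifications),
                  reported = nrow(report)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cell_calls = cell_calls, bulk_calls = bulk_calls,
                 classifications = classifications, report = report,
                 manifest = manifest))
}

# djb2 string hash over the serialized configuration, reported in the manifest
# so two runs with identical thresholds are recognizably comparable.
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
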