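#' Parse one samtools-mpileup line into per-read base calls
#'
#' Tokenizes the base-call column of an mpileup record, pairing each surviving
#' call with its base quality. Read-start markers (`^` plus the following
#' mapping-quality character), read-end markers (`$`), and indel runs (`+`/`-`
#' followed by a length and that many sequence characters) are consumed
#' without producing calls; `.`/`,` resolve to the reference base; letters
#' resolve to themselves uppercased (case encodes strand, which carries no
#' allele information); `*`/`#` resolve to a deletion placeholder and `<`/`>`
#' (reference skips) to `N` — both consume a quality character but are never
#' counted as alleles downstream.
#'
#' @param line One mpileup text line (>= 6 tab-separated fields: chrom, pos,
#'   ref, depth, bases, qualities).
#' @param quality_offset ASCII offset of the quality string (33 for
#'   Sanger/Illumina 1.8+).
#' @param line_number Optional line number used in error messages.
#' @return A `pileup_site`: list with `chrom`, `pos` (1-based), `ref_base`,
#'   `depth`, and `calls` (data frame with columns `base`, `qual`).
#' @examples
#' site <- parse_pileup_line("chr7\t130505748\tA\t5\t..,,G\tIIIII")
#' site$calls
#' @export
parse_pileup_line <- function(line, quality_offset = 33L, line_number = NA_integer_) {
  where <- if (is.na(line_number)) "" else paste0(" at line ", line_number)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 6L) {
    stop("malformed mpileup record", where, ": expected >= 6 tab-separated fields, got ",
         length(fields), call. = FALSE)
  }
  ref_base <- toupper(fields[3L])
  base <- tokenize_pileup_bases(fields[5L], ref_base)
  qual <- utf8ToInt(fields[6L]) - quality_offset
  if (length(base) != length(qual)) {
    stop("malformed mpileup record", where, ": ", length(base),
         " base calls but ", length(qual), " quality characters", call. = FALSE)
  }
  structure(list(chrom = fields[1L], pos = as.integer(fields[2L]),
                 ref_base = ref_base, depth = length(base),
                 calls = data.frame(base = base, qual = qual,
                                    stringsAsFactors = FALSE)),
            class = "pileup_site")
}

# Walks the base string once; indel lengths are multi-digit.
tokenize_pileup_bases <- function(bases, ref_base) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L                       # marker + mapping-quality char
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && ch[j] >= "0" && ch[j] <= "9") j <- j + 1L
      if (j == i + 1L)
        stop("malformed mpileup bases: indel marker '", c0,
             "' not followed by a length", call. = FALSE)
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else {
      k <- k + 1L
      out[k] <- if (c0 == "." || c0 == ",") ref_base
                else if (c0 == "*" || c0 == "#") "del"
                else if (c0 == "<" || c0 == ">") "N"
                else toupper(c0)
      i <- i + 1L
    }
  }
  out[seq_len(k)]
}

#' Count quality-filtered ref/alt/other alleles at one site
#'
#' Applies the base-quality filter (default phred >= 25, matching
#' recalibrated-quality filtering upstream) and tallies calls against the
#' SNP's known alleles. Deletion placeholders and `N` carry no allele
#' information and are excluded from all three tallies.
#'
#' @param site A `pileup_site` from [parse_pileup_line()].
#' @param snp One SNP record (list or one-row data frame with `rsid`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param min_base_quality Minimum phred base quality for a call to count.
#' @param unit_id Identifier of the cell or bulk sample, carried into the record.
#' @return One-row data frame: `unit_id`, `rsid`, `ref_count`, `alt_count`,
#'   `other_count`.
#' @export
count_alleles <- function(site, snp, min_base_quality = 25L, unit_id = NA_character_) {
  if (site$chrom != snp$chrom || site$pos != snp$pos) {
    stop("count_alleles: site ", site$chrom, ":", site$pos,
         " does not match SNP ", snp$rsid, " at ", snp$chrom, ":", snp$pos,
         call. = FALSE)
  }
  calls <- site$calls[site$calls$qual >= min_base_quality, , drop = FALSE]
  informative <- !(calls$base %in% c("del", "N"))
  b <- calls$base[informative]
  data.frame(unit_id = unit_id, rsid = snp$rsid,
             ref_count = sum(b == snp$ref),
             alt_count = sum(b == snp$alt),
             other_count = sum(b != snp$ref & b != snp$alt),
             stringsAsFactors = FALSE)
}

#' Stream an mpileup file into per-SNP allele counts
#'
#' Reads mpileup text (plain or gzip) for one unit (cell or bulk sample),
#' matches each site against the SNP annotation by (chrom, pos), and emits one
#' allele-count record per SNP with at least one quality-passing informative
#' call. SNPs absent from the pileup are omitted. Duplicate positions are
#' resolved last-wins with a warning.
#'
#' @param path Path to an mpileup file, or a character vector of lines.
#' @param snp_table SNP annotation (`rsid`, `chrom`, `pos`, `ref`, `alt`, ...).
#' @param min_base_quality Minimum phred base quality (default 25).
#' @param unit_id Identifier recorded on every output row.
#' @param quality_offset ASCII offset of the quality encoding.
#' @return Data frame of allele-count records (`unit_id`, `rsid`, `ref_count`,
#'   `alt_count`, `other_count`).
#' @export
count_alleles_stream <- function(path, snp_table, min_base_quality = 25L,
                                 unit_id = NA_character_, quality_offset = 33L) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  key <- paste(snp_table$chrom, snp_table$pos, sep = ":")
  if (anyDuplicated(key))
    stop("count_alleles_stream: snp_table has duplicated (chrom, pos)", call. = FALSE)
  recs <- vector("list", nrow(snp_table))
  seen <- character(0)
  for (ln in seq_along(lines)) {
    if (!nzchar(lines[ln])) next
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop("malformed mpileup record at line ", ln, ": fewer than 2 fields",
           call. = FALSE)
    }
    k <- paste(f[1L], f[2L], sep = ":")
    hit <- match(k, key)
    if (is.na(hit)) next
    if (k %in% seen) {
      warning("count_alleles_stream: duplicate pileup position ", k,
              " (line ", ln, "); last occurrence wins", call. = FALSE)
    }
    seen <- c(seen, k)
    site <- parse_pileup_line(lines[ln], quality_offset, ln)
    recs[[hit]] <- count_alleles(site, snp_table[hit, ], min_base_quality, unit_id)
  }
  recs <- Filter(Negate(is.null), recs)
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(unit_id = character(), rsid = character(), ref_count = integer(),
               alt_count = integer(), other_count = integer(),
               stringsAsFactors = FALSE)
  out <- out[(out$ref_count + out$alt_count + out$other_count) > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
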