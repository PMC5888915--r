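#' Per-pool variant calls
#'
#' Throughout the package a pool's variant evidence is a tibble of *pool
#' calls*, one row per alternate allele per site, with columns:
#'
#' * `chrom`, `pos` — 1-based coordinates of the site,
#' * `class` — one of `SNV`, `MNV`, `insertion`, `deletion`, `replacement`,
#' * `ref`, `alt` — reference and variant alleles,
#' * `pool` — `"mutant"` or `"wildtype"`,
#' * `variant_reads`, `coverage` — reads supporting the variant and total reads,
#' * `frequency` — percent, `100 * variant_reads / coverage`,
#' * `forward_reads`, `reverse_reads` — strand split of the variant reads
#'   (`NA` when the caller did not report it),
#' * `unique_starts` — number of distinct read start positions among the
#'   variant reads (`NA` when not reported).
#'
#' Multi-allelic records are always split into one row per alternate allele
#' before any downstream step, so the cross-pool join is well defined.
#'
#' @name pool-calls
NULL

pool_call_cols <- c(
  "chrom", "pos", "class", "ref", "alt", "pool",
  "variant_reads", "coverage", "frequency",
  "forward_reads", "reverse_reads", "unique_starts"
)

new_pool_calls <- function(df) {
  df <- tibble::as_tibble(df)[, pool_call_cols]
  df$pos <- as.integer(df$pos)
  for (col in c("variant_reads", "coverage", "forward_reads", "reverse_reads", "unique_starts")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$frequency <- as.numeric(df$frequency)
  df
}

classify_variant <- function(ref, alt) {
  dplyr::case_when(
    ref == "-" ~ "insertion",
    alt == "-" ~ "deletion",
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNV",
    nchar(ref) == nchar(alt) ~ "MNV",
    nchar(ref) < nchar(alt) ~ "insertion",
    nchar(ref) > nchar(alt) ~ "deletion",
    TRUE ~ "replacement"
  )
}

#' Read one pool's variant calls from a VCF
#'
#' Reads a VCF 4.2 file with per-sample `DP` and `AD` FORMAT fields (and
#' optionally `ADF`/`ADR` for strand counts and the non-standard `USP` tag for
#' unique read start positions) into the pool-call table described in
#' [pool-calls]. Multi-allelic records are split into one call per alternate
#' allele; the variant frequency is recomputed as `100 * AD_alt / DP`.
#' Annotations absent from the file yield `NA` fields, never fabricated zeros.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param pool_label `"mutant"` or `"wildtype"`.
#' @param layout Optional genome layout; when given, records on contigs not in
#'   the layout raise an error naming the contig.
#' @return A pool-call tibble.
#' @export
read_pool_vcf <- function(path, pool_label = c("mutant", "wildtype"), layout = NULL) {
  pool_label <- match.arg(pool_label)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcf@fix
  if (nrow(fx) == 0) {
    return(new_pool_calls(tibble::tibble(
      chrom = character(), pos = integer(), class = character(),
      ref = character(), alt = character(), pool = character(),
      variant_reads = integer(), coverage = integer(), frequency = double(),
      forward_reads = integer(), reverse_reads = integer(), unique_starts = integer()
    )))
  }
  fmt_has <- function(tag) any(grepl(paste0("(^|:)", tag, "(:|$)"), vcf@gt[, "FORMAT"]))
  get_fmt <- function(tag) {
    if (!fmt_has(tag)) return(NULL)
    vcfR::extract.gt(vcf, element = tag)[, 1]
  }
  dp <- get_fmt("DP")
  ad <- get_fmt("AD")
  if (is.null(dp) || is.null(ad)) {
    rlang::abort("VCF lacks the required DP and AD FORMAT fields")
  }
  missing_rec <- which(is.na(dp) | is.na(ad))
  if (length(missing_rec) > 0) {
    rlang::abort(sprintf(
      "VCF record %d (%s:%s) is missing DP or AD",
      missing_rec[1], fx[missing_rec[1], "CHROM"], fx[missing_rec[1], "POS"]
    ))
  }
  adf <- get_fmt("ADF")
  adr <- get_fmt("ADR")
  usp <- get_fmt("USP")

  if (!is.null(layout)) {
    check_on_layout(fx[, "CHROM"], as.integer(fx[, "POS"]), layout, what = "VCF record")
  }

  # split multi-allelic ALT (and the matching AD/ADF/ADR fields, which carry
  # ref followed by one count per alt allele)
  split_counts <- function(x, i, k) {
    if (is.null(x) || is.na(x[i])) return(NA_integer_)
    parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < k + 1) return(NA_integer_)
    as.integer(parts[k + 1])
  }
  rows <- vector("list", nrow(fx))
  for (i in seq_len(nrow(fx))) {
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1]]
    cov <- as.integer(dp[i])
    rows[[i]] <- tibble::tibble(
      chrom = unname(fx[i, "CHROM"]),
      pos = as.integer(fx[i, "POS"]),
      ref = unname(fx[i, "REF"]),
      alt = alts,
      coverage = cov,
      variant_reads = vapply(seq_along(alts), function(k) split_counts(ad, i, k), integer(1)),
      forward_reads = vapply(seq_along(alts), function(k) split_counts(adf, i, k), integer(1)),
      reverse_reads = vapply(seq_along(alts), function(k) split_counts(adr, i, k), integer(1)),
      unique_starts = if (is.null(usp)) NA_integer_ else
        vapply(seq_along(alts), function(k) split_counts(usp, i, k), integer(1))
    )
  }
  calls <- dplyr::bind_rows(rows)
  if (anyNA(calls$variant_reads)) {
    bad <- which(is.na(calls$variant_reads))[1]
    rlang::abort(sprintf(
      "AD field at %s:%d has fewer entries than ALT alleles",
      calls$chrom[bad], calls$pos[bad]
    ))
  }
  calls$class <- classify_variant(calls$ref, calls$alt)
  calls$pool <- pool_label
  calls$frequency <- 100 * calls$variant_reads / calls$coverage
  new_pool_calls(calls)
}

#' Read one pool's variant calls from a tabular variant export
#'
#' Reads the documented TSV dialect emulating a variant-caller table export.
#' Required columns: `chromosome`, `position`, `type`, `reference`, `allele`,
#' `count`, `coverage`, `frequency`; optional: `forward_reads`,
#' `reverse_reads`, `unique_starts`. Lines starting with `#` are ignored.
#' The declared frequency is cross-checked against `100 * count / coverage`;
#' a discrepancy above 0.5 percentage points triggers a warning and the
#' recomputed value wins.
#'
#' @inheritParams read_pool_vcf
#' @return A pool-call tibble.
#' @export
read_pool_table <- function(path, pool_label = c("mutant", "wildtype"), layout = NULL) {
  pool_label <- match.arg(pool_label)
  tab <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("chromosome", "position", "type", "reference", "allele",
                "count", "coverage", "frequency")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("variant table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  num <- function(col) suppressWarnings(as.numeric(tab[[col]]))
  opt <- function(col) if (col %in% names(tab)) suppressWarnings(as.integer(tab[[col]])) else NA_integer_
  calls <- tibble::tibble(
    chrom = tab$chromosome,
    pos = num("position"),
    class = tab$type,
    ref = tab$reference,
    alt = tab$allele,
    pool = pool_label,
    variant_reads = num("count"),
    coverage = num("coverage"),
    frequency = num("frequency"),
    forward_reads = opt("forward_reads"),
    reverse_reads = opt("reverse_reads"),
    unique_starts = opt("unique_starts")
  )
  bad <- which(is.na(calls$pos) | is.na(calls$variant_reads) |
                 is.na(calls$coverage) | is.na(calls$ref) | is.na(calls$alt) |
                 calls$coverage <= 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed variant-table row %d in %s", bad[1], path))
  }
  if (!is.null(layout)) {
    check_on_layout(calls$chrom, calls$pos, layout, what = "variant-table row")
  }
  recomputed <- 100 * calls$variant_reads / calls$coverage
  off <- which(is.na(calls$frequency) | abs(calls$frequency - recomputed) > 0.5)
  if (length(off) > 0) {
    rlang::warn(sprintf(
      "%d row(s) with declared frequency off by > 0.5 points (first: row %d, declared %s, recomputed %.1f); recomputed values used",
      length(off), off[1], format(calls$frequency[off[1]]), recomputed[off[1]]
    ))
    calls$frequency[off] <- recomputed[off]
  }
  new_pool_calls(calls)
}

#' Write a pool-call table in the tabular variant dialect
#'
#' Writes the TSV dialect read by [read_pool_table()], preceded by a `#`
#' comment header carrying the package version. Reading the file back yields
#' a field-identical pool-call table.
#'
#' @param calls A pool-call tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pool_table <- function(calls, path) {
  out <- tibble::tibble(
    chromosome = calls$chrom, position = calls$pos, type = calls$class,
    reference = calls$ref, allele = calls$alt, count = calls$variant_reads,
    coverage = calls$coverage, frequency = sprintf("%.6f", calls$frequency),
    forward_reads = calls$forward_reads, reverse_reads = calls$reverse_reads,
    unique_starts = calls$unique_starts
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(list(format = "variant-table")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Match variant calls across the two pools
#'
#' Joins the mutant and wildtype pool-call tables on the exact variant key
#' `(chrom, pos, class, ref, alt)` and labels each variant `mutant_specific`,
#' `wildtype_specific`, or `common`. The same position with different
#' alternate alleles yields two pool-specific records, not a common one.
#'
#' @param mutant,wildtype Pool-call tibbles (see [pool-calls]).
#' @return A tibble with the key columns, per-pool evidence columns suffixed
#'   `_mutant` / `_wildtype`, and a `membership` column. The partition
#'   satisfies `mutant_specific + common == nrow(mutant)` and symmetrically.
#' @export
match_pools <- function(mutant, wildtype) {
  key <- c("chrom", "pos", "class", "ref", "alt")
  for (side in list(mutant, wildtype)) {
    dup <- duplicated(side[, key])
    if (any(dup)) {
      d <- side[which(dup)[1], ]
      rlang::abort(sprintf(
        "duplicate variant key within one pool at %s:%d %s>%s (upstream multi-allelic splitting bug?)",
        d$chrom, d$pos, d$ref, d$alt
      ))
    }
  }
  ev <- c("variant_reads", "coverage", "frequency", "forward_reads",
          "reverse_reads", "unique_starts")
  m <- mutant[, c(key, ev)]
  w <- wildtype[, c(key, ev)]
  joined <- dplyr::full_join(m, w, by = key, suffix = c("_mutant", "_wildtype"))
  joined$membership <- dplyr::case_when(
    !is.na(joined$coverage_mutant) & !is.na(joined$coverage_wildtype) ~ "common",
    !is.na(joined$coverage_mutant) ~ "mutant_specific",
    TRUE ~ "wildtype_specific"
  )
  dplyr::arrange(joined, .data$chrom, .data$pos, .data$alt)
}

#' Write mapped regions as BED6
#'
#' Converts 1-based inclusive region intervals to 0-based half-open BED
#' coordinates. The score column is the region's peak z-score scaled by 100
#' and clamped to `[0, 1000]`; the name column is the locus label.
#'
#' @param regions Tibble with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `name`, and `peak_z`.
#' @param path Output file path.
#' @param layout Optional genome layout; intervals outside a chromosome raise
#'   an error.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, layout = NULL) {
  if (!is.null(layout) && nrow(regions) > 0) {
    check_on_layout(regions$chrom, regions$start, layout, what = "region start")
    check_on_layout(regions$chrom, regions$end, layout, what = "region end")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(list(format = "BED6", score = "z*100 clamped [0,1000]")), con)
  if (nrow(regions) > 0) {
    score <- pmin(pmax(round(regions$peak_z * 100), 0), 1000)
    bed <- data.frame(
      chrom = regions$chrom,
      start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
      end = format(regions$end, scientific = FALSE, trim = TRUE),
      name = regions$name,
      score = score,
      strand = "."
    )
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
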