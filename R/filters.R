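#' Filter configuration
#'
#' Thresholds for the two-stage variant filter cascade. The primary stage is
#' applied per pool right after variant calling; the confidence stage is
#' applied before mapping to minimise false positives.
#'
#' @param min_coverage_primary Minimum read coverage at the primary stage.
#' @param min_variant_reads Minimum reads supporting the variant allele.
#' @param min_coverage_confidence Minimum coverage at the confidence stage.
#' @param balance_min,balance_max Inclusive bounds on the forward/reverse
#'   balance of variant reads, `min(forward, reverse) / variant_reads`, so
#'   0.5 is perfect balance.
#' @param min_unique_starts Minimum number of variant reads with unique start
#'   positions.
#' @param ambiguous_ref_codes IUPAC codes; calls whose reference base is one
#'   of these are removed.
#' @param homopolymer_min_run Minimum reference homopolymer run length for the
#'   indel homopolymer filter.
#' @param hyperallelic_min_alts Sites with at least this many distinct
#'   alternate alleles (within a pool) are removed entirely.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_coverage_primary = 10,
                          min_variant_reads = 2,
                          min_coverage_confidence = 20,
                          balance_min = 0.25,
                          balance_max = 0.5,
                          min_unique_starts = 5,
                          ambiguous_ref_codes = c("M", "R", "W", "S", "Y", "K"),
                          homopolymer_min_run = 4,
                          hyperallelic_min_alts = 3) {
  stopifnot(
    balance_min >= 0, balance_min <= balance_max, balance_max <= 0.5,
    min_coverage_primary >= 0, min_variant_reads >= 0,
    min_coverage_confidence >= 0, min_unique_starts >= 0,
    homopolymer_min_run >= 1, hyperallelic_min_alts >= 2
  )
  structure(
    list(
      min_coverage_primary = min_coverage_primary,
      min_variant_reads = min_variant_reads,
      min_coverage_confidence = min_coverage_confidence,
      balance_min = balance_min,
      balance_max = balance_max,
      min_unique_starts = min_unique_starts,
      ambiguous_ref_codes = ambiguous_ref_codes,
      homopolymer_min_run = homopolymer_min_run,
      hyperallelic_min_alts = hyperallelic_min_alts
    ),
    class = "filter_config"
  )
}

new_filter_report <- function(stage, removed, n_input, n_surviving, notes = character()) {
  structure(
    list(
      stage = stage,
      removed = removed,           # named integer vector, cascade order
      n_input = n_input,
      n_surviving = n_surviving,
      notes = notes
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report (%s stage): %d in, %d out\n", x$stage, x$n_input, x$n_surviving))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %-22s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report A `filter_report` from [filter_primary()] or
#'   [filter_confidence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(list(stage = report$stage)), con)
  df <- data.frame(
    filter = c("input", names(report$removed), "surviving"),
    records = c(report$n_input, unname(report$removed), report$n_surviving)
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# longest homopolymer run in `context` that covers the centre base
centre_run_length <- function(context) {
  if (is.na(context) || !nzchar(context)) return(0L)
  n <- nchar(context)
  centre <- (n + 1L) %/% 2L
  chars <- strsplit(toupper(context), "")[[1]]
  b <- chars[centre]
  left <- centre
  while (left > 1 && chars[left - 1] == b) left <- left - 1
  right <- centre
  while (right < n && chars[right + 1] == b) right <- right + 1
  as.integer(right - left + 1L)
}

#' Primary variant filter cascade
#'
#' Removes, in fixed cascade order: (1) calls whose alternate allele equals
#' the reference allele; (2) all calls at hyperallelic sites (at least
#' `hyperallelic_min_alts` distinct alternate alleles at one position);
#' (3) insertion/deletion calls lying within a reference homopolymer run of
#' at least `homopolymer_min_run` bases (skipped with a warning when
#' `reference_context` is absent); (4) calls at sites whose reference base is
#' an ambiguous IUPAC code; (5) calls below the primary coverage or
#' variant-read minimums. Each removed record is attributed to the first
#' failing filter, so the report counts are conserved.
#'
#' @param calls A pool-call tibble.
#' @param reference_context Optional tibble with columns `chrom`, `pos`,
#'   `context`: the local reference sequence with the variant position at the
#'   centre of the string, used only by the homopolymer filter.
#' @param config A [filter_config()].
#' @return A list with elements `calls` (survivors) and `report`
#'   (a `filter_report`).
#' @export
filter_primary <- function(calls, reference_context = NULL, config = filter_config()) {
  n_in <- nrow(calls)
  removed <- c(reference_allele = 0L, hyperallelic = 0L, homopolymer = 0L,
               ambiguous_reference = 0L, low_evidence = 0L)
  notes <- character()
  fail <- rep(NA_character_, n_in)

  mark <- function(fail, idx, label) {
    idx <- idx[is.na(fail[idx])]
    fail[idx] <- label
    fail
  }

  fail <- mark(fail, which(calls$alt == calls$ref), "reference_allele")

  site <- paste(calls$chrom, calls$pos)
  n_alts <- stats::ave(calls$alt, site, FUN = function(a) length(unique(a)))
  fail <- mark(fail, which(as.integer(n_alts) >= config$hyperallelic_min_alts), "hyperallelic")

  is_indel <- calls$class %in% c("insertion", "deletion")
  if (is.null(reference_context)) {
    if (any(is_indel & is.na(fail))) {
      rlang::warn("no reference context supplied; homopolymer filter skipped")
      notes <- c(notes, "homopolymer filter skipped (no reference context)")
    }
  } else {
    ctx <- reference_context$context[match(
      paste(calls$chrom, calls$pos),
      paste(reference_context$chrom, reference_context$pos)
    )]
    run <- vapply(ctx, centre_run_length, integer(1), USE.NAMES = FALSE)
    fail <- mark(fail, which(is_indel & !is.na(ctx) & run >= config$homopolymer_min_run),
                 "homopolymer")
  }

  ref_first <- toupper(substr(calls$ref, 1, 1))
  fail <- mark(fail, which(ref_first %in% toupper(config$ambiguous_ref_codes)),
               "ambiguous_reference")

  fail <- mark(fail, which(calls$coverage < config$min_coverage_primary |
                             calls$variant_reads < config$min_variant_reads),
               "low_evidence")

  keep <- is.na(fail)
  tab <- table(factor(fail[!keep], levels = names(removed)))
  removed[names(tab)] <- as.integer(tab)
  list(
    calls = calls[keep, , drop = FALSE],
    report = new_filter_report("primary", removed, n_in, sum(keep), notes)
  )
}

#' Confidence variant filter
#'
#' Keeps calls with coverage at or above `min_coverage_confidence`, a
#' forward/reverse balance of variant reads within
#' `[balance_min, balance_max]` inclusive, and at least `min_unique_starts`
#' variant reads with unique start positions. When a call lacks the evidence
#' for a metric (strand counts or unique starts not reported), that metric's
#' filter is skipped for the call and the skip is counted in the report.
#'
#' @inheritParams filter_primary
#' @return A list with elements `calls` and `report`.
#' @export
filter_confidence <- function(calls, config = filter_config()) {
  n_in <- nrow(calls)
  counts <- calls[, c("variant_reads", "coverage", "forward_reads",
                      "reverse_reads", "unique_starts")]
  if (any(unlist(counts) < 0, na.rm = TRUE)) {
    rlang::abort("negative read counts in input")
  }
  removed <- c(low_coverage = 0L, strand_imbalance = 0L, few_unique_starts = 0L)
  fail <- rep(NA_character_, n_in)
  mark <- function(fail, idx, label) {
    idx <- idx[is.na(fail[idx])]
    fail[idx] <- label
    fail
  }

  fail <- mark(fail, which(calls$coverage < config$min_coverage_confidence), "low_coverage")

  total_strand <- calls$forward_reads + calls$reverse_reads
  balance <- ifelse(total_strand > 0,
                    pmin(calls$forward_reads, calls$reverse_reads) / total_strand,
                    NA_real_)
  has_balance <- !is.na(balance)
  fail <- mark(fail, which(has_balance &
                             (balance < config$balance_min | balance > config$balance_max)),
               "strand_imbalance")

  has_usp <- !is.na(calls$unique_starts)
  fail <- mark(fail, which(has_usp & calls$unique_starts < config$min_unique_starts),
               "few_unique_starts")

  keep <- is.na(fail)
  tab <- table(factor(fail[!keep], levels = names(removed)))
  removed[names(tab)] <- as.integer(tab)
  notes <- character()
  if (any(!has_balance)) {
    notes <- c(notes, sprintf("balance filter skipped for %d call(s) without strand counts",
                              sum(!has_balance)))
  }
  if (any(!has_usp)) {
    notes <- c(notes, sprintf("unique-start filter skipped for %d call(s) without USP",
                              sum(!has_usp)))
  }
  list(
    calls = calls[keep, , drop = FALSE],
    report = new_filter_report("confidence", removed, n_in, sum(keep), notes)
  )
}
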