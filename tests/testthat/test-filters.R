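test_that("primary cascade removes records in documented order", {
  calls <- dplyr::bind_rows(
    toy_calls(1, pos = 100),                               # clean, survives
    {x <- toy_calls(1, pos = 150); x$alt <- x$ref; x},     # alt == ref
    {x <- toy_calls(3, pos = c(200, 200, 200)); x$ref <- "A"
     x$alt <- c("G", "T", "C"); x},                        # hyperallelic site
    {x <- toy_calls(1, pos = 300); x$ref <- "R"; x},       # ambiguous ref
    {x <- toy_calls(1, pos = 400, coverage = 9); x},       # coverage 9 < 10
    {x <- toy_calls(1, pos = 500); x$variant_reads <- 1L
     x$frequency <- 100 / x$coverage; x}                   # 1 variant read < 2
  )
  res <- suppressWarnings(filter_primary(calls))
  expect_equal(res$report$n_input, 8)
  expect_equal(res$report$n_surviving, 1)
  expect_equal(unname(res$report$removed["reference_allele"]), 1L)
  expect_equal(unname(res$report$removed["hyperallelic"]), 3L)
  expect_equal(unname(res$report$removed["ambiguous_reference"]), 1L)
  expect_equal(unname(res$report$removed["low_evidence"]), 2L)
  # conservation: removed + surviving = input
  expect_equal(sum(res$report$removed) + res$report$n_surviving, res$report$n_input)
  expect_equal(res$calls$pos, 100L)
})

test_that("homopolymer filter removes indels inside reference runs", {
  calls <- toy_calls(2, pos = c(100, 200))
  calls$class <- "deletion"
  calls$ref <- c("AA", "AT"); calls$alt <- "A"
  ctx <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L),
    context = c("CCAAAAACC", "GGCATGGCC")  # run of 5 A covers centre / no run
  )
  res <- filter_primary(calls, reference_context = ctx)
  expect_equal(unname(res$report$removed["homopolymer"]), 1L)
  expect_equal(res$calls$pos, 200L)

  # absent context: filter skipped with a warning, nothing removed by it
  expect_warning(res2 <- filter_primary(calls), "homopolymer")
  expect_equal(unname(res2$report$removed["homopolymer"]), 0L)
})

test_that("confidence filter applies coverage, balance and start thresholds", {
  calls <- dplyr::bind_rows(
    toy_calls(1, pos = 100, coverage = 25, frequency = 100),  # 25 reads
    toy_calls(1, pos = 200, coverage = 20, frequency = 100),
    toy_calls(1, pos = 300, coverage = 19, frequency = 100)
  )
  # kept: coverage 25, forward 10 / reverse 15 (balance 0.4), usp 6
  calls$variant_reads <- c(25L, 20L, 19L)
  calls$forward_reads <- c(10L, 4L, 9L)
  calls$reverse_reads <- c(15L, 16L, 10L)
  calls$unique_starts <- c(6L, 5L, 10L)
  res <- filter_confidence(calls)
  expect_equal(res$calls$pos, 100L)                # balance 0.2 and cov 19 removed
  expect_equal(unname(res$report$removed["strand_imbalance"]), 1L)
  expect_equal(unname(res$report$removed["low_coverage"]), 1L)

  # inclusive boundaries: balance exactly 0.25 and 0.5, usp exactly 5 survive
  edge <- toy_calls(2, pos = c(10, 20), coverage = 24, frequency = 100)
  edge$variant_reads <- c(24L, 24L)
  edge$forward_reads <- c(6L, 12L)
  edge$reverse_reads <- c(18L, 12L)
  edge$unique_starts <- c(5L, 5L)
  expect_equal(nrow(filter_confidence(edge)$calls), 2)

  # absent strand evidence: balance filter skipped, noted in report
  noev <- toy_calls(1, pos = 700, coverage = 30, frequency = 100)
  noev$forward_reads <- NA_integer_; noev$reverse_reads <- NA_integer_
  noev$variant_reads <- 30L
  res3 <- filter_confidence(noev)
  expect_equal(nrow(res3$calls), 1)
  expect_match(res3$report$notes, "strand", all = FALSE)

  neg <- noev; neg$coverage <- -1L
  expect_error(filter_confidence(neg), "negative")
})

test_that("filtering is idempotent and monotone in thresholds", {
  set.seed(31)
  n <- 200
  calls <- toy_calls(
    n, pos = sample.int(1e6, n),
    frequency = runif(n, 5, 100), coverage = sample(5:60, n, replace = TRUE),
    usp = sample(0:15, n, replace = TRUE)
  )
  calls$forward_reads <- vapply(calls$variant_reads, function(v) rbinom(1, v, 0.5), integer(1))
  calls$reverse_reads <- calls$variant_reads - calls$forward_reads
  calls <- dplyr::arrange(calls, pos)
  calls <- calls[!duplicated(calls$pos), ]

  once <- filter_confidence(filter_primary(calls)$calls)$calls
  again <- filter_confidence(filter_primary(once)$calls)$calls
  expect_identical(once, again)

  tighter <- filter_config(min_coverage_confidence = 30, min_unique_starts = 8,
                           min_coverage_primary = 15, min_variant_reads = 4)
  strict <- filter_confidence(filter_primary(calls, config = tighter)$calls,
                              config = tighter)$calls
  expect_lte(nrow(strict), nrow(once))
  expect_true(all(paste(strict$chrom, strict$pos) %in% paste(once$chrom, once$pos)))
})
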