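test_that("VCF records parse into pool calls with recomputed frequencies", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_record("chr13", 7923460, "C", "T", "DP:AD", "40:22,18"),
    vcf_record("chr1", 500, "A", "T,G", "DP:AD", "30:15,10,5"),
    vcf_record("chr1", 900, "G", "C", "DP:AD:ADF:ADR:USP", "50:30,20:14,12:16,8:22,9")
  ))
  calls <- read_pool_vcf(path, "mutant")
  expect_equal(nrow(calls), 4)

  snv <- calls[calls$pos == 7923460, ]
  expect_equal(snv$frequency, 45.0)
  expect_equal(snv$ref, "C")
  expect_equal(snv$alt, "T")
  expect_true(is.na(snv$forward_reads))
  expect_true(is.na(snv$unique_starts))

  multi <- calls[calls$pos == 500, ]
  expect_equal(sort(multi$alt), c("G", "T"))
  expect_equal(multi$frequency[multi$alt == "T"], 100 * 10 / 30)
  expect_equal(multi$frequency[multi$alt == "G"], 100 * 5 / 30)
  expect_equal(multi$pos, c(500L, 500L))

  annotated <- calls[calls$pos == 900, ]
  expect_equal(annotated$forward_reads, 12L)
  expect_equal(annotated$reverse_reads, 8L)
  expect_equal(annotated$unique_starts, 9L)
})

test_that("VCF reading errors on missing evidence and unknown contigs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, vcf_record("chr1", 100, "A", "G", "DP:AD", "25:13,12"))
  layout <- genome_layout(c(chrX = 1e6))
  expect_error(read_pool_vcf(path, "mutant", layout), "chr1")

  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "pool1", sep = "\t"),
    vcf_record("chr1", 100, "A", "G", "GT", "0/1")
  ), path2)
  expect_error(suppressWarnings(read_pool_vcf(path2, "mutant")), "DP and AD")
})

test_that("variant tables read, cross-check frequencies, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chromosome\tposition\ttype\treference\tallele\tcount\tcoverage\tfrequency\tforward_reads\treverse_reads\tunique_starts",
    "chr1\t100\tSNV\tA\tG\t12\t24\t50.0\t7\t5\t6",
    "chr1\t200\tSNV\tC\tT\t10\t30\t50\t\t\t",
    "chr2\t300\tdeletion\tAT\tA\t8\t20\t40.0\t4\t4\t5"
  ), path)
  expect_warning(calls <- read_pool_table(path, "wildtype"), "recomputed")
  expect_equal(nrow(calls), 3)
  expect_equal(calls$frequency[calls$pos == 200], 100 * 10 / 30)
  expect_equal(calls$frequency[calls$pos == 100], 50)
  # empty optional columns stay absent, not zero
  expect_true(is.na(calls$forward_reads[calls$pos == 200]))
  expect_true(is.na(calls$unique_starts[calls$pos == 200]))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_pool_table(calls, out)
  back <- read_pool_table(out, "wildtype")
  expect_equal(as.data.frame(back), as.data.frame(calls), tolerance = 1e-6)
})

test_that("malformed table rows are reported by row number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chromosome\tposition\ttype\treference\tallele\tcount\tcoverage\tfrequency",
    "chr1\t100\tSNV\tA\tG\t12\t24\t50.0",
    "chr1\tnot_a_number\tSNV\tC\tT\t5\t20\t25.0"
  ), path)
  expect_error(read_pool_table(path, "mutant"), "row 2")
})

test_that("match_pools joins on the exact allele key and partitions inputs", {
  mut <- toy_calls(3, pool = "mutant", pos = c(100, 200, 300))
  wt <- toy_calls(3, pool = "wildtype", pos = c(100, 200, 400))
  # same position, different alt allele: pool-specific, not common
  wt$alt[wt$pos == 200] <- "C"
  wt$ref[wt$pos == 200] <- mut$ref[mut$pos == 200]

  m <- match_pools(mut, wt)
  memb <- table(m$membership)
  expect_equal(unname(memb[["common"]]), 1)
  expect_equal(unname(memb[["mutant_specific"]]), 2)
  expect_equal(unname(memb[["wildtype_specific"]]), 2)
  expect_equal(m$membership[m$pos == 100], "common")
  expect_equal(sum(m$pos == 200), 2)

  # partition identity: specific + common = pool input size
  expect_equal(sum(m$membership != "wildtype_specific"), nrow(mut))
  expect_equal(sum(m$membership != "mutant_specific"), nrow(wt))

  # symmetry: swapping roles swaps labels, preserves sizes
  m2 <- match_pools(wt, mut)
  expect_equal(sum(m2$membership == "common"), sum(m$membership == "common"))
  expect_equal(sum(m2$membership == "mutant_specific"),
               sum(m$membership == "wildtype_specific"))
})

test_that("duplicate keys within one pool are rejected", {
  mut <- toy_calls(2, pos = c(100, 100))
  mut$ref <- "A"; mut$alt <- "G"
  expect_error(match_pools(mut, toy_calls(1)), "duplicate")
})

test_that("BED export converts coordinates and scales scores", {
  regions <- tibble::tibble(
    chrom = "chr13", start = 5000001, end = 12000000,
    name = "W", peak_z = 5.1
  )
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# mafdd")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[1:3], c("chr13", "5000000", "12000000"))
  expect_equal(fields[5], "510")

  # clamping and empty set
  big <- regions; big$peak_z <- 99
  write_regions_bed(big, path)
  expect_equal(strsplit(readLines(path)[2], "\t")[[1]][5], "1000")
  write_regions_bed(regions[0, ], path)
  expect_equal(length(readLines(path)), 1)  # header only

  layout <- genome_layout(c(chr13 = 10e6))
  expect_error(write_regions_bed(regions, path, layout), "beyond")
})
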