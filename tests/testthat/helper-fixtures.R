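# programmatic fixtures shared across test files

toy_calls <- function(n = 5, pool = "mutant", chrom = "chr1",
                      pos = seq(100, by = 100, length.out = n),
                      frequency = rep(50, n), coverage = rep(30L, n),
                      forward = NULL, usp = rep(8L, n)) {
  vr <- as.integer(round(frequency / 100 * coverage))
  fwd <- if (is.null(forward)) as.integer(vr %/% 2L) else as.integer(forward)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), class = "SNV",
    ref = rep(c("A", "C", "G", "T"), length.out = n),
    alt = rep(c("G", "T", "A", "C"), length.out = n),
    pool = pool,
    variant_reads = vr, coverage = as.integer(coverage),
    frequency = 100 * vr / coverage,
    forward_reads = fwd, reverse_reads = vr - fwd,
    unique_starts = as.integer(usp)
  )
}

# minimal VCF written in code (text fixture, no binary files)
write_test_vcf <- function(path, records,
                           contigs = c(chr1 = 1000000, chr13 = 20000000),
                           format = "DP:AD") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Forward depths">',
    '##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Reverse depths">',
    '##FORMAT=<ID=USP,Number=R,Type=Integer,Description="Unique starts">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "pool1", sep = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, fmt, gt) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", fmt, gt, sep = "\t")
}

# a fast small simulated cross reused by several files
small_sim <- function(seed = 42, ...) {
  simulate_cross(cross_config(
    layout = genome_layout(c(chr1 = 10e6, chr2 = 10e6, chr3 = 10e6)),
    causal_chrom = "chr2", causal_pos = 5e6, seed = seed, ...
  ))
}
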