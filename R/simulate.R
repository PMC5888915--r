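#' Configuration of a simulated F1 cross and pooled sequencing design
#'
#' Describes an F1 cross between a heterozygous seed parent carrying one copy
#' of a dominant causal allele and a non-carrier parent, the selection of
#' progeny into a mutant and a wildtype pool, and binomial read sampling of
#' each pool. Variants of the modelled segregation types are placed uniformly
#' along each chromosome at the configured densities; each heterozygous-seed
#' variant gets a random phase relative to the causal haplotype.
#'
#' @param layout Genome layout; default 5 chromosomes of 30 Mb.
#' @param causal_chrom,causal_pos Location of the dominant causal locus.
#' @param n_mutant_pool,n_wildtype_pool Progeny per pool (defaults 17 and 16).
#' @param type_densities Named numeric, variants per Mb for `type_I`
#'   (`<lmxmm>`), `type_II` (`<lmxll>`), `type_III` (`<hkxhk>`) and
#'   `non_informative` (an equal mix of `<nnxnp>` and `<qqxqq>`).
#' @param cM_per_Mb Recombination rate; map distance is converted to a
#'   recombination fraction with Haldane's map function
#'   `r = (1 - exp(-2 d / 100)) / 2` for `d` in cM. Variants on other
#'   chromosomes segregate independently (`r = 0.5`).
#' @param depth_mean Mean per-pool coverage per site (Poisson, minimum 1).
#' @param misclassification_rate Probability that a progeny's phenotype is
#'   scored opposite to its causal genotype (models incomplete
#'   penetrance/expressivity).
#' @param coupling_fraction Probability that a variant's non-reference allele
#'   is the one in coupling phase with the causal allele (0.5 = random
#'   phase).
#' @param usp_mean Mean of the Poisson start-diversity model for unique read
#'   start positions (capped at the variant read count).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `cross_config` list.
#' @export
cross_config <- function(layout = default_layout(),
                         causal_chrom = "chr3",
                         causal_pos = 15.5e6,
                         n_mutant_pool = 17,
                         n_wildtype_pool = 16,
                         type_densities = c(type_I = 40, type_II = 40,
                                            type_III = 40, non_informative = 40),
                         cM_per_Mb = 2.0,
                         depth_mean = 25,
                         misclassification_rate = 0,
                         coupling_fraction = 0.5,
                         usp_mean = 10,
                         seed = 1L) {
  stopifnot(
    n_mutant_pool > 0, n_wildtype_pool > 0,
    all(type_densities >= 0),
    cM_per_Mb >= 0, depth_mean > 0,
    misclassification_rate >= 0, misclassification_rate < 0.5,
    coupling_fraction >= 0, coupling_fraction <= 1
  )
  if (!causal_chrom %in% layout$chrom) {
    rlang::abort(sprintf("causal chromosome %s is not in the layout", causal_chrom))
  }
  td <- c(type_I = 0, type_II = 0, type_III = 0, non_informative = 0)
  td[names(type_densities)] <- type_densities
  structure(
    list(layout = layout, causal_chrom = causal_chrom, causal_pos = causal_pos,
         n_mutant_pool = n_mutant_pool, n_wildtype_pool = n_wildtype_pool,
         type_densities = td, cM_per_Mb = cM_per_Mb, depth_mean = depth_mean,
         misclassification_rate = misclassification_rate,
         coupling_fraction = coupling_fraction, usp_mean = usp_mean,
         seed = as.integer(seed)),
    class = "cross_config"
  )
}

haldane_r <- function(d_cM) {
  (1 - exp(-2 * d_cM / 100)) / 2
}

# variant-allele transmission probabilities per gamete, given the gamete's
# causal allele: seed parent depends on phase and r; other parent is constant
seg_sim_model <- function(type) {
  switch(type,
    "<lmxmm>" = list(seed_het = TRUE, other_p = 0),
    "<lmxll>" = list(seed_het = TRUE, other_p = 1),
    "<hkxhk>" = list(seed_het = TRUE, other_p = 0.5),
    "<nnxnp>" = list(seed_het = FALSE, seed_p = 0, other_p = 0.5),
    "<qqxqq>" = list(seed_het = FALSE, seed_p = 1, other_p = 1),
    rlang::abort(sprintf("unknown simulated segregation type %s", type))
  )
}

#' Simulate an F1 cross with pooled sequencing
#'
#' Generates the two pools' variant-call tables plus a ground-truth table.
#' The generative model: (1) variants are placed uniformly per chromosome at
#' the configured per-type densities, each with a random phase; (2) progeny
#' are drawn by independent Mendelian transmission — the seed parent's gamete
#' carries the causal allele with probability 1/2, and each variant allele is
#' co-transmitted with crossover probability given by Haldane's map function;
#' (3) a progeny's phenotype is mutant iff it carries the causal allele,
#' flipped with the misclassification rate; progeny are drawn until both
#' pools are full; (4) per variant and pool, the true pooled allele fraction
#' is the variant allele count over `2 * pool size`; coverage is Poisson,
#' variant reads binomial at the true fraction, forward reads binomial 1/2 of
#' the variant reads, and unique start positions a capped Poisson;
#' (5) calls with zero variant reads are suppressed, which naturally
#' produces pool-specific versus common membership.
#'
#' @param config A [cross_config()].
#' @return A list with pool-call tibbles `mutant` and `wildtype` (see
#'   [pool-calls]), the ground-truth tibble `truth` (columns `chrom`, `pos`,
#'   `ref`, `alt`, `seg_type`, `phase`, `r`, `true_freq_mutant`,
#'   `true_freq_wildtype`), and `config`. Re-running with the same config is
#'   byte-identical.
#' @export
simulate_cross <- function(config = cross_config()) {
  withr::with_seed(config$seed, simulate_cross_impl(config))
}

simulate_cross_impl <- function(config) {
  lay <- config$layout
  type_names <- c(type_I = "<lmxmm>", type_II = "<lmxll>", type_III = "<hkxhk>")

  # --- 1. place variants ----------------------------------------------------
  place <- list()
  for (i in seq_len(nrow(lay))) {
    mb <- lay$length[i] / 1e6
    for (td in names(config$type_densities)) {
      n <- stats::rpois(1, config$type_densities[[td]] * mb)
      if (n == 0) next
      types <- if (td == "non_informative") {
        sample(c("<nnxnp>", "<qqxqq>"), n, replace = TRUE)
      } else rep(type_names[[td]], n)
      place[[length(place) + 1]] <- tibble::tibble(
        chrom = lay$chrom[i],
        pos = sample.int(lay$length[i], n, replace = FALSE),
        seg_type = types
      )
    }
  }
  if (length(place) == 0) {
    empty <- new_pool_calls(tibble::tibble(
      chrom = character(), pos = integer(), class = character(), ref = character(),
      alt = character(), pool = character(), variant_reads = integer(),
      coverage = integer(), frequency = double(), forward_reads = integer(),
      reverse_reads = integer(), unique_starts = integer()
    ))
    truth0 <- tibble::tibble(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      seg_type = character(), phase = character(), r = double(),
      true_freq_mutant = double(), true_freq_wildtype = double()
    )
    return(list(mutant = empty, wildtype = empty, truth = truth0, config = config))
  }
  v <- dplyr::arrange(dplyr::bind_rows(place), .data$chrom, .data$pos)
  # one variant per site: collisions across type draws are dropped
  v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
  nv <- nrow(v)
  v$phase <- ifelse(stats::runif(nv) < config$coupling_fraction, "coupling", "repulsion")
  bases <- c("A", "C", "G", "T")
  v$ref <- sample(bases, nv, replace = TRUE)
  v$alt <- vapply(v$ref, function(b) sample(setdiff(bases, b), 1), character(1))

  # recombination fraction to the causal locus
  d_cM <- ifelse(
    v$chrom == config$causal_chrom,
    config$cM_per_Mb * abs(v$pos - config$causal_pos) / 1e6,
    Inf
  )
  v$r <- ifelse(is.finite(d_cM), haldane_r(d_cM), 0.5)

  # --- 2-3. progeny until both pools are full -------------------------------
  n_m <- config$n_mutant_pool
  n_w <- config$n_wildtype_pool
  carrier_m <- logical(0)
  carrier_w <- logical(0)
  while (length(carrier_m) < n_m || length(carrier_w) < n_w) {
    batch <- 4 * (n_m + n_w)
    carries <- stats::runif(batch) < 0.5
    flipped <- stats::runif(batch) < config$misclassification_rate
    pheno_mut <- xor(carries, flipped)
    carrier_m <- c(carrier_m, carries[pheno_mut])[seq_len(min(n_m, length(carrier_m) + sum(pheno_mut)))]
    carrier_w <- c(carrier_w, carries[!pheno_mut])[seq_len(min(n_w, length(carrier_w) + sum(!pheno_mut)))]
  }
  carriers <- c(carrier_m, carrier_w)
  n_prog <- n_m + n_w

  # --- 4. transmission: variants x progeny ----------------------------------
  # seed parent: P(transmit coupling-linked allele | gamete causal status)
  p_linked <- outer(1 - v$r, as.numeric(carriers)) + outer(v$r, 1 - as.numeric(carriers))
  seed_het <- vapply(v$seg_type, function(t) seg_sim_model(t)$seed_het, logical(1))
  seed_hom_p <- vapply(v$seg_type, function(t) seg_sim_model(t)$seed_p %||% NA_real_, double(1))
  other_p <- vapply(v$seg_type, function(t) seg_sim_model(t)$other_p, double(1))

  # variant allele from the seed parent
  linked_transmitted <- matrix(stats::runif(nv * n_prog), nv, n_prog) < p_linked
  coupling <- v$phase == "coupling"
  seed_variant <- linked_transmitted
  seed_variant[!coupling, ] <- !seed_variant[!coupling, , drop = FALSE]
  # homozygous seed types ignore linkage
  hom <- !seed_het
  if (any(hom)) {
    seed_variant[hom, ] <- matrix(stats::runif(sum(hom) * n_prog), sum(hom), n_prog) <
      seed_hom_p[hom]
  }
  # variant allele from the other parent (unlinked to the causal locus)
  other_variant <- matrix(stats::runif(nv * n_prog), nv, n_prog) <
    matrix(other_p, nv, n_prog)

  alleles <- seed_variant + other_variant
  idx_m <- seq_len(n_m)
  idx_w <- n_m + seq_len(n_w)
  q_m <- rowSums(alleles[, idx_m, drop = FALSE]) / (2 * n_m)
  q_w <- rowSums(alleles[, idx_w, drop = FALSE]) / (2 * n_w)

  truth <- tibble::tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    seg_type = v$seg_type, phase = v$phase, r = v$r,
    true_freq_mutant = 100 * q_m, true_freq_wildtype = 100 * q_w
  )

  # --- 5. read sampling per pool --------------------------------------------
  sample_pool <- function(q, pool_label) {
    cov <- pmax(1L, stats::rpois(nv, config$depth_mean))
    vr <- stats::rbinom(nv, cov, q)
    fwd <- stats::rbinom(nv, vr, 0.5)
    usp <- pmin(vr, stats::rpois(nv, config$usp_mean))
    keep <- vr > 0
    new_pool_calls(tibble::tibble(
      chrom = v$chrom[keep], pos = v$pos[keep], class = "SNV",
      ref = v$ref[keep], alt = v$alt[keep], pool = pool_label,
      variant_reads = vr[keep], coverage = cov[keep],
      frequency = 100 * vr[keep] / cov[keep],
      forward_reads = fwd[keep], reverse_reads = vr[keep] - fwd[keep],
      unique_starts = usp[keep]
    ))
  }
  list(
    mutant = sample_pool(q_m, "mutant"),
    wildtype = sample_pool(q_w, "wildtype"),
    truth = truth,
    config = config
  )
}

#' Write a simulated cross to disk
#'
#' Emits, per pool, both the tabular variant dialect (read by
#' [read_pool_table()]) and a minimal valid VCF 4.2 (read by
#' [read_pool_vcf()]) with FORMAT fields `DP:AD:ADF:ADR:USP`, plus the
#' ground-truth TSV.
#'
#' @param sim Output of [simulate_cross()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    mutant_table = file.path(out_dir, "mutant.tsv"),
    wildtype_table = file.path(out_dir, "wildtype.tsv"),
    mutant_vcf = file.path(out_dir, "mutant.vcf"),
    wildtype_vcf = file.path(out_dir, "wildtype.vcf"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_pool_table(sim$mutant, files[["mutant_table"]])
  write_pool_table(sim$wildtype, files[["wildtype_table"]])
  write_sim_vcf(sim$mutant, sim$config$layout, files[["mutant_vcf"]], "mutant_pool")
  write_sim_vcf(sim$wildtype, sim$config$layout, files[["wildtype_vcf"]], "wildtype_pool")
  con <- file(files[["truth"]], "w")
  writeLines(output_header(list(table = "simulation-truth")), con)
  utils::write.table(sim$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(files)
}

write_sim_vcf <- function(calls, layout, path, sample_name) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=mafdd %s", utils::packageVersion("mafdd")),
    sprintf("##contig=<ID=%s,length=%d>", layout$chrom, as.integer(layout$length)),
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Allelic depths, forward strand">',
    '##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Allelic depths, reverse strand">',
    '##FORMAT=<ID=USP,Number=R,Type=Integer,Description="Reads with unique start positions">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
          sample_name, sep = "\t")
  ), con)
  if (nrow(calls) == 0) return(invisible(path))
  calls <- dplyr::arrange(calls, match(.data$chrom, layout$chrom), .data$pos)
  ref_reads <- calls$coverage - calls$variant_reads
  ref_fwd <- pmax(ref_reads %/% 2L, 0L)
  gt <- sprintf(
    "%d:%d,%d:%d,%d:%d,%d:%d,%d",
    calls$coverage, ref_reads, calls$variant_reads,
    ref_fwd, calls$forward_reads,
    ref_reads - ref_fwd, calls$reverse_reads,
    pmin(ref_reads, calls$unique_starts), calls$unique_starts
  )
  lines <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
                 ".", "DP:AD:ADF:ADR:USP", gt, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
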