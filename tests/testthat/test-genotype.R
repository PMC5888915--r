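test_that("zygosity bands classify with inclusive 15-80 heterozygous range", {
  expect_equal(
    classify_zygosity(c(45, 15, 80, 80.1, 10, 0, 100)),
    c("heterozygous", "heterozygous", "heterozygous", "homozygous",
      "low_frequency", "low_frequency", "homozygous")
  )
  expect_error(classify_zygosity(101), "\\[0, 100\\]")
  expect_error(classify_zygosity(-1), "\\[0, 100\\]")
})

make_common <- function(fm, fw, ref = "A", alt = "G", pos = seq_along(fm) * 100) {
  tibble::tibble(
    chrom = "chr1", pos = as.integer(pos), class = "SNV", ref = ref, alt = alt,
    variant_reads_mutant = 10L, coverage_mutant = 20L, frequency_mutant = fm,
    forward_reads_mutant = 5L, reverse_reads_mutant = 5L, unique_starts_mutant = 5L,
    variant_reads_wildtype = 10L, coverage_wildtype = 20L, frequency_wildtype = fw,
    forward_reads_wildtype = 5L, reverse_reads_wildtype = 5L, unique_starts_wildtype = 5L,
    membership = "common"
  )
}

test_that("genotype groups follow the two-pool zygosity grid", {
  m <- make_common(
    fm = c(52, 97, 45, 95, 10),
    fw = c(48, 50, 92, 99, 50)
  )
  g <- assign_genotype_groups(m)
  expect_equal(g$group, c("G1", "G2", "G3", "G4", "excluded"))

  # three distinct bases at one site across pools: complex (G5)
  tri <- dplyr::bind_rows(
    make_common(52, 48, ref = "A", alt = "G", pos = 100),
    make_common(30, 20, ref = "A", alt = "T", pos = 100)
  )
  expect_equal(assign_genotype_groups(tri)$group, c("G5", "G5"))

  # group assignment partitions the input
  set.seed(8)
  big <- make_common(fm = runif(300, 0, 100), fw = runif(300, 0, 100))
  summ <- summarise_genotype_groups(assign_genotype_groups(big))
  expect_equal(sum(summ$n), 300)

  ps <- make_common(50, 50)
  ps$membership <- "mutant_specific"
  expect_error(assign_genotype_groups(ps), "common")
})

test_that("expected pool frequencies reproduce the segregation-type model", {
  # full linkage: (50,0), (100,50), (75,25) and a 50-point AFDD for all three
  expect_equal(expected_pool_frequency("<lmxmm>", 0, "mutant"), 50)
  expect_equal(expected_pool_frequency("<lmxmm>", 0, "wildtype"), 0)
  expect_equal(expected_pool_frequency("<lmxll>", 0, "mutant"), 100)
  expect_equal(expected_pool_frequency("<lmxll>", 0, "wildtype"), 50)
  expect_equal(expected_pool_frequency("<hkxhk>", 0, "mutant"), 75)
  expect_equal(expected_pool_frequency("<hkxhk>", 0, "wildtype"), 25)
  for (ty in c("<lmxmm>", "<lmxll>", "<hkxhk>")) {
    expect_equal(
      expected_pool_frequency(ty, 0, "mutant") - expected_pool_frequency(ty, 0, "wildtype"),
      50
    )
  }

  # no linkage: both pools at the unlinked expectation
  expect_equal(expected_pool_frequency("<hkxhk>", 0.5, "mutant"), 50)
  expect_equal(expected_pool_frequency("<hkxhk>", 0.5, "wildtype"), 50)
  expect_equal(expected_pool_frequency("<lmxmm>", 0.5, "mutant"), 25)
  expect_equal(expected_pool_frequency("<lmxll>", 0.5, "wildtype"), 75)

  expect_error(expected_pool_frequency("<hkxhk>", 0.6, "mutant"), "0.5")
  expect_error(expected_pool_frequency("<abxcd>", 0, "mutant"), "multi-allelic")
})

test_that("partial linkage matches a brute-force gamete enumeration", {
  # independent oracle: enumerate the 4 ordered seed gamete classes x 2 other
  # parent gametes with their weights, conditioned on the causal allele
  oracle <- function(seed_var, other_var, r, pool) {
    w <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
    causal <- c(1, 1, 0, 0)
    varal <- c(seed_var[1], seed_var[2], seed_var[1], seed_var[2])
    keep <- causal == (pool == "mutant")
    ws <- w[keep] / sum(w[keep])
    seed_mean <- sum(ws * varal[keep])
    100 * (seed_mean + mean(other_var)) / 2
  }
  cases <- expand.grid(
    r = c(0, 0.1, 0.25, 0.4, 0.5), pool = c("mutant", "wildtype"),
    stringsAsFactors = FALSE
  )
  types <- list(
    "<lmxmm>" = list(seed = c(1, 0), other = c(0, 0)),
    "<lmxll>" = list(seed = c(1, 0), other = c(1, 1)),
    "<hkxhk>" = list(seed = c(1, 0), other = c(1, 0))
  )
  for (nm in names(types)) {
    for (i in seq_len(nrow(cases))) {
      expect_equal(
        expected_pool_frequency(nm, cases$r[i], cases$pool[i]),
        oracle(types[[nm]]$seed, types[[nm]]$other, cases$r[i], cases$pool[i]),
        info = paste(nm, cases$r[i], cases$pool[i])
      )
    }
  }
  # spot value: type I at r = 0.25 in the mutant pool is 37.5%
  expect_equal(expected_pool_frequency("<lmxmm>", 0.25, "mutant"), 37.5)

  # monotone approach to the unlinked value over [0, 0.5]
  rs <- seq(0, 0.5, by = 0.05)
  f <- vapply(rs, function(r) expected_pool_frequency("<hkxhk>", r, "mutant"), double(1))
  expect_true(all(diff(f) < 0))
  expect_equal(f[length(f)], 50)
})

test_that("candidate segregation types cover the group map with phase", {
  g3 <- infer_candidate_types("G3")
  expect_true("<lmxmm>" %in% g3$seg_type)
  expect_true(g3$informative[g3$seg_type == "<lmxmm>"])
  g2 <- infer_candidate_types("G2")
  expect_true(all(g2$seg_type == "<lmxll>") && all(g2$informative))
  g1 <- infer_candidate_types("G1")
  expect_true(any(g1$seg_type == "<hkxhk>" & g1$informative))
  expect_true(any(!g1$informative))  # G1 also admits non-informative types
  g5 <- infer_candidate_types("G5")
  expect_setequal(g5$seg_type, c("<abxcd>", "<efxeg>"))
  expect_error(infer_candidate_types("G9"), "unknown")
})

test_that("frequency-band selection shows the expected wildtype-pool response", {
  lay <- genome_layout(c(chr1 = 30e6))
  base <- list(layout = lay, causal_chrom = "chr1", causal_pos = 15e6,
               cM_per_Mb = 0, depth_mean = 400, coupling_fraction = 1)
  sim2 <- simulate_cross(do.call(cross_config, c(base, list(
    type_densities = c(type_II = 20), seed = 21))))
  sim3 <- simulate_cross(do.call(cross_config, c(base, list(
    type_densities = c(type_III = 20), seed = 22))))
  matched2 <- match_pools(sim2$mutant, sim2$wildtype)
  matched3 <- match_pools(sim3$mutant, sim3$wildtype)

  resp2 <- evaluate_type_response(matched2, c(95, 100))
  expect_gt(resp2$n_selected, 100)
  mode2 <- resp2$wildtype_hist$bin_mid[which.max(resp2$wildtype_hist$n)]
  expect_lt(abs(mode2 - 50), 5)

  resp3 <- evaluate_type_response(matched3, c(70, 80))
  expect_gt(resp3$n_selected, 100)
  mode3 <- resp3$wildtype_hist$bin_mid[which.max(resp3$wildtype_hist$n)]
  expect_lt(abs(mode3 - 25), 5)

  empty <- evaluate_type_response(matched2, c(0, 0))
  expect_equal(empty$n_selected, 0L)
  expect_equal(nrow(empty$per_chromosome), 0)
})
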