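#' Zygosity classification bands
#'
#' Variant allele frequencies from 15% to 80% (inclusive) are classed
#' heterozygous; frequencies above 80% homozygous; frequencies below 15% are
#' classed `low_frequency` and excluded from genotype-group assignment
#' (their counts are always reported).
#'
#' @param het_min,het_max Inclusive heterozygous band bounds in percent.
#' @return A `zygosity_bands` list.
#' @export
zygosity_bands <- function(het_min = 15, het_max = 80) {
  stopifnot(het_min > 0, het_min < het_max, het_max < 100)
  structure(list(het_min = het_min, het_max = het_max), class = "zygosity_bands")
}

#' Classify zygosity from a pooled allele frequency
#'
#' @param frequency Numeric vector of allele frequencies in percent.
#' @param bands A [zygosity_bands()].
#' @return Character vector: `"heterozygous"`, `"homozygous"`, or
#'   `"low_frequency"`.
#' @examples
#' classify_zygosity(c(45, 80, 80.1, 10))
#' @export
classify_zygosity <- function(frequency, bands = zygosity_bands()) {
  if (any(!is.finite(frequency) | frequency < 0 | frequency > 100)) {
    rlang::abort("frequencies must lie in [0, 100]")
  }
  dplyr::case_when(
    frequency < bands$het_min ~ "low_frequency",
    frequency <= bands$het_max ~ "heterozygous",
    TRUE ~ "homozygous"
  )
}

#' The six F1 segregation types
#'
#' JoinMap-style codes for the allele configurations of the two parents of an
#' F1 cross between heterozygous out-crossing parents. By convention the
#' first-listed allele of the seed (mutant) parent is the one linked, in
#' coupling phase, to the dominant causal allele, and the *variant* allele is
#' the non-reference one. Three configurations are informative for mapping a
#' dominant trait: `<lm x mm>` (type I, mutant-pool-specific), `<lm x ll>`
#' (type II) and `<hk x hk>` (type III). At full linkage their expected
#' variant allele frequencies are (50, 0), (100, 50) and (75, 25) percent in
#' the mutant and wildtype pools respectively — a 50-percentage-point
#' directional difference for all three.
#'
#' @return A tibble with columns `name`, `type_label` (`I`/`II`/`III` or
#'   `NA`), `informative`, `expected_freq_mutant`, `expected_freq_wildtype`
#'   (percent at full linkage, coupling phase).
#' @export
seg_types <- function() {
  tibble::tibble(
    name = c("<lmxmm>", "<lmxll>", "<hkxhk>", "<nnxnp>", "<qqxqq>", "<abxcd>", "<efxeg>"),
    type_label = c("I", "II", "III", NA, NA, NA, NA),
    informative = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    expected_freq_mutant = c(50, 100, 75, 25, 100, NA, NA),
    expected_freq_wildtype = c(0, 50, 25, 25, 100, NA, NA)
  )
}

# parental allele configuration at the variant locus for each modelled type:
# seed = c(first, second) allele variant indicator (first is causal-linked in
# coupling phase), other = variant indicators of the non-seed parent's alleles
seg_type_alleles <- function(name) {
  switch(name,
    "<lmxmm>" = list(seed = c(1, 0), other = c(0, 0)),
    "<lmxll>" = list(seed = c(1, 0), other = c(1, 1)),
    "<hkxhk>" = list(seed = c(1, 0), other = c(1, 0)),
    "<nnxnp>" = list(seed = c(0, 0), other = c(0, 1)),
    "<qqxqq>" = list(seed = c(1, 1), other = c(1, 1)),
    rlang::abort(sprintf(
      "segregation type %s is not modelled quantitatively (multi-allelic)", name
    ))
  )
}

#' Expected pooled allele frequency for a segregation type under linkage
#'
#' Computes the Mendelian expectation of the variant allele frequency in one
#' phenotype pool, for a variant at recombination fraction `r` from the
#' dominant causal locus, by exact enumeration of ordered parental gamete
#' classes conditioned on the progeny phenotype. The seed parent's gametes
#' combine the causal allele and the variant-locus allele with weights
#' `(1 - r) / 2` (parental) and `r / 2` (recombinant); the other parent is
#' homozygous wildtype at the causal locus, so its transmission is
#' unconditioned. At `r = 0` the informative types reproduce (50, 0),
#' (100, 50) and (75, 25); at `r = 0.5` both pools equal the unlinked
#' expectation (25, 75 and 50 percent respectively).
#'
#' @param type Segregation type name, e.g. `"<hkxhk>"` (one of
#'   `seg_types()$name` except the multi-allelic `<abxcd>` / `<efxeg>`).
#' @param r Recombination fraction between the variant and the causal locus,
#'   in `[0, 0.5]`.
#' @param pool `"mutant"` or `"wildtype"`.
#' @param phase `"coupling"` (the variant allele of the seed parent is on the
#'   causal haplotype) or `"repulsion"`.
#' @return Expected variant allele frequency in percent.
#' @examples
#' expected_pool_frequency("<hkxhk>", r = 0, pool = "mutant")    # 75
#' expected_pool_frequency("<lmxll>", r = 0, pool = "wildtype")  # 50
#' @export
expected_pool_frequency <- function(type, r, pool = c("mutant", "wildtype"),
                                    phase = c("coupling", "repulsion")) {
  pool <- match.arg(pool)
  phase <- match.arg(phase)
  if (!is.finite(r) || r < 0 || r > 0.5) {
    rlang::abort("recombination fraction must lie in [0, 0.5]")
  }
  cfg <- seg_type_alleles(type)
  seed <- cfg$seed
  if (phase == "repulsion") seed <- rev(seed)

  # ordered seed gamete classes: (causal allele, variant indicator, weight)
  seed_gametes <- data.frame(
    causal = c(1, 1, 0, 0),
    variant = c(seed[1], seed[2], seed[1], seed[2]),
    w = c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  )
  other_gametes <- data.frame(variant = cfg$other, w = 0.5)

  want_causal <- if (pool == "mutant") 1 else 0
  sel <- seed_gametes[seed_gametes$causal == want_causal, ]
  sel$w <- sel$w / sum(sel$w)

  # E[# variant alleles in a pooled progeny] / 2 alleles
  e_seed <- sum(sel$w * sel$variant)
  e_other <- sum(other_gametes$w * other_gametes$variant)
  100 * (e_seed + e_other) / 2
}

#' Assign genotype groups to pool-common variants
#'
#' Classifies each pool-common variant by the zygosity of its allele
#' frequency in each pool: `G1` heterozygous/heterozygous, `G2` homozygous in
#' the mutant pool / heterozygous in the wildtype pool, `G3`
#' heterozygous/homozygous, `G4` homozygous/homozygous, and `G5` ("complex")
#' for sites involving three or more distinct DNA bases across the two pools.
#' Variants at `low_frequency` in either pool are labelled `excluded` and
#' reported separately, never silently dropped.
#'
#' @param matched A matched-variant tibble from [match_pools()]; all rows must
#'   have `membership == "common"`.
#' @param bands A [zygosity_bands()].
#' @return The input with an added `group` column
#'   (`G1`–`G5` or `excluded`).
#' @export
assign_genotype_groups <- function(matched, bands = zygosity_bands()) {
  if (nrow(matched) > 0 && any(matched$membership != "common")) {
    rlang::abort("genotype groups are defined for pool-common variants only")
  }
  if (nrow(matched) == 0) {
    matched$group <- character()
    return(matched)
  }
  # distinct bases at the site across both pools, reference included
  site <- paste(matched$chrom, matched$pos)
  alleles_per_site <- tapply(
    paste(matched$ref, matched$alt, sep = ","), site,
    function(x) length(unique(unlist(strsplit(x, ",", fixed = TRUE))))
  )
  n_alleles <- as.integer(alleles_per_site[site])

  zm <- classify_zygosity(matched$frequency_mutant, bands)
  zw <- classify_zygosity(matched$frequency_wildtype, bands)
  matched$group <- dplyr::case_when(
    n_alleles >= 3 ~ "G5",
    zm == "low_frequency" | zw == "low_frequency" ~ "excluded",
    zm == "heterozygous" & zw == "heterozygous" ~ "G1",
    zm == "homozygous" & zw == "heterozygous" ~ "G2",
    zm == "heterozygous" & zw == "homozygous" ~ "G3",
    TRUE ~ "G4"
  )
  matched
}

#' Summarise genotype-group counts
#'
#' @param grouped Output of [assign_genotype_groups()].
#' @return A tibble with columns `group`, `n`, `percent` covering
#'   `G1`–`G5` and `excluded`.
#' @export
summarise_genotype_groups <- function(grouped) {
  lv <- c("G1", "G2", "G3", "G4", "G5", "excluded")
  tab <- table(factor(grouped$group, levels = lv))
  tibble::tibble(
    group = lv,
    n = as.integer(tab),
    percent = if (nrow(grouped) > 0) 100 * as.integer(tab) / nrow(grouped) else 0
  )
}

#' Candidate segregation types for a genotype group
#'
#' Maps an observed genotype group to the segregation types (with phase)
#' that could produce it at full linkage. This is a reconstruction over the
#' six base types in both phases; `G1` notably mixes the informative
#' `<hkxhk>` (type III) with non-informative configurations, while `G2` is
#' essentially diagnostic for `<lmxll>` (type II).
#'
#' @param group Genotype group label (`"G1"`–`"G5"`), vectorised.
#' @return A tibble with columns `group`, `seg_type`, `phase`, `informative`,
#'   `type_label`.
#' @export
infer_candidate_types <- function(group) {
  map <- list(
    G1 = tibble::tibble(
      seg_type = c("<hkxhk>", "<hkxhk>", "<nnxnp>"),
      phase = c("coupling", "repulsion", "coupling")
    ),
    G2 = tibble::tibble(seg_type = "<lmxll>", phase = "coupling"),
    G3 = tibble::tibble(
      seg_type = c("<lmxmm>", "<lmxll>"),
      phase = c("coupling", "repulsion")
    ),
    G4 = tibble::tibble(seg_type = "<qqxqq>", phase = "coupling"),
    G5 = tibble::tibble(seg_type = c("<abxcd>", "<efxeg>"), phase = c("coupling", "coupling"))
  )
  bad <- setdiff(unique(group), names(map))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown genotype group(s): %s", paste(bad, collapse = ", ")))
  }
  st <- seg_types()
  out <- dplyr::bind_rows(lapply(unique(group), function(g) {
    cbind(group = g, map[[g]])
  }))
  out <- tibble::as_tibble(out)
  # informative only in coupling phase (variant allele on the causal haplotype)
  out$informative <- st$informative[match(out$seg_type, st$name)] & out$phase == "coupling"
  out$type_label <- ifelse(out$informative, st$type_label[match(out$seg_type, st$name)], NA)
  out
}

#' Frequency-band response of pool-common variants
#'
#' Selects pool-common variants whose mutant-pool frequency lies in a band
#' and summarises where their wildtype-pool frequencies fall. Under the
#' segregation-type model, selecting near-fixed mutant-pool variants
#' (e.g. frequency at least 95%) enriches type II variants, whose
#' wildtype-pool frequencies concentrate near 50% in the causal region;
#' selecting the 70–80% band enriches type III variants, concentrating near
#' 25%.
#'
#' @param matched Matched-variant tibble (`membership == "common"` rows are
#'   used).
#' @param mutant_band Length-2 numeric, inclusive mutant-pool frequency band
#'   in percent.
#' @param hist_bin Width of the wildtype-pool frequency histogram bins, in
#'   percentage points.
#' @return A list with `n_selected`, `per_chromosome` (tibble `chrom`, `n`)
#'   and `wildtype_hist` (tibble `bin_start`, `bin_mid`, `n`).
#' @export
evaluate_type_response <- function(matched, mutant_band, hist_bin = 5) {
  stopifnot(length(mutant_band) == 2, mutant_band[1] <= mutant_band[2],
            mutant_band[1] >= 0, mutant_band[2] <= 100)
  common <- matched[matched$membership == "common", , drop = FALSE]
  sel <- common[common$frequency_mutant >= mutant_band[1] &
                  common$frequency_mutant <= mutant_band[2], , drop = FALSE]
  if (nrow(sel) == 0) {
    return(list(
      n_selected = 0L,
      per_chromosome = tibble::tibble(chrom = character(), n = integer()),
      wildtype_hist = tibble::tibble(bin_start = double(), bin_mid = double(), n = integer())
    ))
  }
  per_chrom <- dplyr::count(sel, .data$chrom, name = "n")
  breaks <- seq(0, 100, by = hist_bin)
  cut_idx <- pmin(findInterval(sel$frequency_wildtype, breaks,
                               rightmost.closed = TRUE), length(breaks) - 1)
  tab <- table(factor(cut_idx, levels = seq_len(length(breaks) - 1)))
  list(
    n_selected = nrow(sel),
    per_chromosome = per_chrom,
    wildtype_hist = tibble::tibble(
      bin_start = breaks[-length(breaks)],
      bin_mid = breaks[-length(breaks)] + hist_bin / 2,
      n = as.integer(tab)
    )
  )
}
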