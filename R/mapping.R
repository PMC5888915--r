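new_mapping_result <- function(method, n_input, n_selected, profile, bins, regions, params) {
  structure(
    list(method = method, n_input = n_input, n_selected = n_selected,
         profile = profile, bins = bins, regions = regions, params = params),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("%s mapping: %d input variants, %d selected (%s)\n",
              x$method, x$n_input, x$n_selected,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  cat(sprintf("  %d bins, %d significant; %d region(s)\n",
              nrow(x$bins), sum(x$bins$significant), nrow(x$regions)))
  if (nrow(x$regions) > 0) {
    for (i in seq_len(nrow(x$regions))) {
      r <- x$regions[i, ]
      cat(sprintf("  %s  peak z=%.1f (P=%.2g)\n", r$name, r$peak_z, z_to_p(r$peak_z)))
    }
  }
  invisible(x)
}

#' Mutant allele frequency and density (MAFD) mapping
#'
#' Maps a dominant trait from mutant-pool-specific variants under the
#' assumption that trait-linked variants follow segregation type `<lmxmm>`
#' (type I): heterozygous in the seed parent and absent from the other, so
#' their pooled frequency approaches 50% in the causal region. The scan has
#' two tracks: a moving-window mean frequency profile over *all*
#' mutant-specific variants, and a per-Mb density z-score test over the
#' variants whose frequency falls in the target band (default 40–60%,
#' inclusive). Maximal runs of contiguous significant bins are merged into
#' candidate regions.
#'
#' @param mutant_specific Pool-call tibble of mutant-pool-specific variants
#'   (already filtered).
#' @param layout A [genome_layout()].
#' @param band Length-2 inclusive frequency band (percent) selecting variants
#'   for the density track.
#' @param window Moving-average window, in variants.
#' @param bin_size Density bin width in bp.
#' @param z_cutoff Inclusive significance cutoff.
#' @return A `mapping_result` with elements `profile`, `bins`, `regions`.
#' @export
mafd_map <- function(mutant_specific, layout, band = c(40, 60), window = 20,
                     bin_size = 1e6, z_cutoff = 2.6) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  calls <- dplyr::arrange(mutant_specific, .data$chrom, .data$pos)
  profile <- moving_average(
    tibble::tibble(chrom = calls$chrom, pos = calls$pos, value = calls$frequency),
    window = window
  )
  sel <- calls[calls$frequency >= band[1] & calls$frequency <= band[2], , drop = FALSE]
  if (nrow(sel) == 0) {
    rlang::warn("no variants in the frequency band; empty density track")
    bins <- bin_density(sel, layout, bin_size)
    bins <- z_test(bins, z_cutoff)
  } else {
    bins <- z_test(bin_density(sel, layout, bin_size), z_cutoff)
  }
  new_mapping_result(
    "MAFD", nrow(calls), nrow(sel), profile, bins,
    merge_significant_regions(bins),
    list(band = paste(band, collapse = "-"), window = window,
         bin_size = bin_size, z_cutoff = z_cutoff)
  )
}

#' Allele frequency directional difference and density (AFDDD) mapping
#'
#' Maps a dominant trait from variants *common* to both pools, exploiting
#' segregation types `<lmxll>` (type II) and `<hkxhk>` (type III), whose
#' expected mutant-pool frequency exceeds the wildtype-pool frequency by 50
#' percentage points in the causal region. The allele frequency directional
#' difference, `AFDD = mutant frequency - wildtype frequency` (signed
#' percentage points), selects variants with `AFDD >= afdd_min` (default 30,
#' inclusive — deliberately below the 50-point optimum to accommodate
#' deviations); the scan then profiles the moving-window mean AFDD of the
#' selected variants and tests their per-Mb density for z-score peaks.
#'
#' @param matched Matched-variant tibble from [match_pools()]; rows must all
#'   be `membership == "common"`.
#' @param layout A [genome_layout()].
#' @param afdd_min Inclusive AFDD selection threshold in percentage points.
#' @param window,bin_size,z_cutoff As in [mafd_map()].
#' @param reverse If `TRUE`, swap pool roles (wildtype minus mutant) for a
#'   control scan.
#' @return A `mapping_result`.
#' @export
afddd_map <- function(matched, layout, afdd_min = 30, window = 20,
                      bin_size = 1e6, z_cutoff = 2.6, reverse = FALSE) {
  if (nrow(matched) > 0 && any(matched$membership != "common")) {
    rlang::abort("AFDDD mapping takes pool-common variants only")
  }
  matched <- dplyr::arrange(matched, .data$chrom, .data$pos)
  afdd <- matched$frequency_mutant - matched$frequency_wildtype
  if (reverse) afdd <- -afdd
  sel <- matched[!is.na(afdd) & afdd >= afdd_min, , drop = FALSE]
  sel_afdd <- afdd[!is.na(afdd) & afdd >= afdd_min]
  profile <- moving_average(
    tibble::tibble(chrom = sel$chrom, pos = sel$pos, value = sel_afdd),
    window = window
  )
  if (nrow(sel) == 0) {
    rlang::warn("no variants at or above the AFDD threshold; empty density track")
  }
  bins <- z_test(bin_density(sel, layout, bin_size), z_cutoff)
  new_mapping_result(
    "AFDDD", nrow(matched), nrow(sel), profile, bins,
    merge_significant_regions(bins),
    list(afdd_min = afdd_min, window = window, bin_size = bin_size,
         z_cutoff = z_cutoff, reverse = reverse)
  )
}

#' Write a mapping result's tables
#'
#' Writes the moving-window profile TSV, the density-bin TSV (with z, p and
#' significance) and the merged significant regions as BED6, each with a
#' comment header recording the generating parameters.
#'
#' @param result A `mapping_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; defaults to the lower-cased method name.
#' @param layout Optional layout for BED bounds checking.
#' @return Named character vector of the files written, invisibly.
#' @export
write_mapping_result <- function(result, dir, prefix = tolower(result$method), layout = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(c(list(method = result$method), result$params))
  profile_path <- file.path(dir, paste0(prefix, "_profile.tsv"))
  con <- file(profile_path, "w")
  writeLines(hdr, con)
  utils::write.table(result$profile, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  bins_path <- file.path(dir, paste0(prefix, "_bins.tsv"))
  con <- file(bins_path, "w")
  writeLines(hdr, con)
  bins <- result$bins
  bins$p <- signif(bins$p, 2)
  utils::write.table(bins, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  bed_path <- file.path(dir, paste0(prefix, "_regions.bed"))
  write_regions_bed(result$regions, bed_path, layout)
  invisible(c(profile = profile_path, bins = bins_path, regions = bed_path))
}
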