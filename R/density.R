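#' Moving-window average profile
#'
#' Computes, per chromosome, the mean of `value` over a sliding window of a
#' fixed number of consecutive variants (step 1 variant). The window anchor
#' is the mean position of the window's members. Chromosomes with fewer
#' variants than the window yield no windows; windows never span chromosomes.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `value`, sorted by
#'   `(chrom, pos)`.
#' @param window Number of consecutive variants per window.
#' @return A tibble with columns `chrom`, `anchor` (bp), `mean`, `window`.
#' @export
moving_average <- function(variants, window = 20) {
  stopifnot(window >= 1)
  if (nrow(variants) == 0) {
    return(tibble::tibble(chrom = character(), anchor = double(),
                          mean = double(), window = integer()))
  }
  by_chrom <- split(variants, factor(variants$chrom, levels = unique(variants$chrom)))
  out <- lapply(by_chrom, function(v) {
    if (is.unsorted(v$pos)) {
      rlang::abort(sprintf("variants on %s are not sorted by position", v$chrom[1]))
    }
    n <- nrow(v)
    if (n < window) return(NULL)
    cs_val <- cumsum(c(0, v$value))
    cs_pos <- cumsum(c(0, as.numeric(v$pos)))
    i <- seq_len(n - window + 1)
    tibble::tibble(
      chrom = v$chrom[1],
      anchor = (cs_pos[i + window] - cs_pos[i]) / window,
      mean = (cs_val[i + window] - cs_val[i]) / window,
      window = as.integer(window)
    )
  })
  dplyr::bind_rows(out)
}

#' Per-Mb variant density bins
#'
#' Tiles each layout chromosome with non-overlapping bins anchored at
#' position 1 and counts variants per bin. Density is reported in variants
#' per Mb; the final partial bin's density is scaled by its true length.
#' Empty bins are included with count 0 (they enter the genome-wide mean and
#' standard deviation of the z-score test).
#'
#' @param variants Tibble with columns `chrom`, `pos`.
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `variant_count`, `density`.
#' @export
bin_density <- function(variants, layout, bin_size = 1e6) {
  stopifnot(bin_size >= 1)
  if (nrow(variants) > 0) {
    check_on_layout(variants$chrom, variants$pos, layout)
  }
  bins <- dplyr::bind_rows(lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(1, len, by = bin_size)
    tibble::tibble(
      chrom = layout$chrom[i],
      start = starts,
      end = pmin(starts + bin_size - 1, len)
    )
  }))
  if (nrow(variants) > 0) {
    bin_index <- paste(variants$chrom, (as.numeric(variants$pos) - 1) %/% bin_size)
    tab <- table(bin_index)
    key <- paste(bins$chrom, (bins$start - 1) %/% bin_size)
    bins$variant_count <- as.integer(ifelse(key %in% names(tab), tab[key], 0L))
  } else {
    bins$variant_count <- 0L
  }
  bins$density <- bins$variant_count * 1e6 / (bins$end - bins$start + 1)
  bins
}

#' Standard-score test on variant densities
#'
#' Annotates density bins with the standard score `z = (X - mu) / sigma`,
#' where `X` is the bin's variant density (variants per Mb), `mu` is the mean
#' density over all bins genome-wide and `sigma` the population standard
#' deviation (divisor N). Bins with `z` at or above the cutoff are flagged
#' significant; the cutoff 2.6 corresponds to a two-tailed normal P of about
#' 0.01.
#'
#' @param bins Output of [bin_density()] (at least 2 rows).
#' @param z_cutoff Inclusive significance cutoff on `z`.
#' @return `bins` with added columns `z`, `p` (two-tailed normal), and
#'   `significant`.
#' @export
z_test <- function(bins, z_cutoff = 2.6) {
  if (nrow(bins) < 2) {
    rlang::abort("z test needs at least 2 bins")
  }
  mu <- mean(bins$density)
  sigma <- sqrt(mean((bins$density - mu)^2))
  if (sigma == 0) {
    rlang::warn("all bin densities identical; z set to 0 for every bin")
    bins$z <- 0
  } else {
    bins$z <- (bins$density - mu) / sigma
  }
  bins$p <- z_to_p(bins$z)
  bins$significant <- bins$z >= z_cutoff
  bins
}

#' Two-tailed normal p-value for a standard score
#'
#' `p = 2 * (1 - pnorm(|z|))`.
#'
#' @param z Numeric vector of standard scores.
#' @return Two-tailed p-values.
#' @examples
#' z_to_p(2.9)  # ~3.7e-3
#' @export
z_to_p <- function(z) {
  if (any(!is.finite(z))) rlang::abort("z must be finite")
  2 * stats::pnorm(-abs(z))
}

# maximal runs of contiguous significant bins, per chromosome
merge_significant_regions <- function(bins) {
  empty <- tibble::tibble(chrom = character(), start = double(), end = double(),
                          n_bins = integer(), peak_z = double(), name = character())
  if (nrow(bins) == 0 || !any(bins$significant)) return(empty)
  bins <- dplyr::arrange(bins, match(.data$chrom, unique(bins$chrom)), .data$start)
  runs <- rle(paste(bins$chrom, bins$significant))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  keep <- which(bins$significant[idx_start])
  out <- lapply(keep, function(k) {
    b <- bins[idx_start[k]:idx_end[k], ]
    tibble::tibble(
      chrom = b$chrom[1], start = min(b$start), end = max(b$end),
      n_bins = nrow(b), peak_z = max(b$z)
    )
  })
  out <- dplyr::bind_rows(out)
  out$name <- sprintf("%s:%.0f-%.0f", out$chrom, out$start, out$end)
  out
}
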