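#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosomes (name and length in bp)
#' that density binning and region export are computed against. Input variants
#' must lie on a layout chromosome, within its length.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp, in the
#'   desired order (e.g. `c(chr1 = 30e6, chr2 = 30e6)`), or a data frame with
#'   columns `chrom` and `length`.
#' @return A tibble with columns `chrom` (character) and `length` (double),
#'   one row per chromosome.
#' @examples
#' genome_layout(c(chr1 = 30e6, chr2 = 25e6))
#' @export
genome_layout <- function(lengths) {
  if (is.data.frame(lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(lengths)))
    out <- tibble::tibble(
      chrom = as.character(lengths$chrom),
      length = as.numeric(lengths$length)
    )
  } else {
    if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
      rlang::abort("`lengths` must be a named vector of chromosome lengths")
    }
    out <- tibble::tibble(chrom = names(lengths), length = as.numeric(lengths))
  }
  if (any(duplicated(out$chrom))) {
    rlang::abort("duplicated chromosome names in layout")
  }
  if (any(!is.finite(out$length) | out$length <= 0)) {
    rlang::abort("chromosome lengths must be positive")
  }
  out
}

#' Default five-chromosome test layout
#'
#' A small uniform genome (5 chromosomes of 30 Mb) used as the simulator
#' default; large enough for density mapping to have a genome-wide background,
#' small enough for fast tests.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
default_layout <- function(n_chrom = 5, chrom_length = 30e6) {
  genome_layout(stats::setNames(rep(chrom_length, n_chrom), paste0("chr", seq_len(n_chrom))))
}

# error unless every (chrom, pos) is on the layout and within bounds
check_on_layout <- function(chrom, pos, layout, what = "variant") {
  unknown <- setdiff(unique(chrom), layout$chrom)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "%s on contig(s) not in layout: %s", what, paste(unknown, collapse = ", ")
    ))
  }
  len <- layout$length[match(chrom, layout$chrom)]
  bad <- which(pos < 1 | pos > len)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s at %s:%d beyond chromosome length %d",
      what, chrom[bad[1]], as.integer(pos[bad[1]]), as.integer(len[bad[1]])
    ))
  }
  invisible(TRUE)
}
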