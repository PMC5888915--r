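# brute-force reimplementations of the scan primitives, used as independent
# oracles; loops on purpose, no shared code with the package internals

naive_moving_average <- function(variants, window) {
  out <- NULL
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, ]
    if (nrow(v) < window) next
    for (i in seq_len(nrow(v) - window + 1)) {
      idx <- i:(i + window - 1)
      out <- rbind(out, data.frame(
        chrom = ch, anchor = mean(v$pos[idx]), mean = mean(v$value[idx]),
        window = as.integer(window)
      ))
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(), anchor = double(),
                      mean = double(), window = integer())
  }
  out
}

naive_bin_density <- function(variants, layout, bin_size) {
  out <- NULL
  for (i in seq_len(nrow(layout))) {
    start <- 1
    while (start <= layout$length[i]) {
      end <- min(start + bin_size - 1, layout$length[i])
      n <- sum(variants$chrom == layout$chrom[i] &
                 variants$pos >= start & variants$pos <= end)
      out <- rbind(out, data.frame(
        chrom = layout$chrom[i], start = start, end = end,
        variant_count = as.integer(n), density = n * 1e6 / (end - start + 1)
      ))
      start <- start + bin_size
    }
  }
  out
}

naive_z <- function(density, cutoff = 2.6) {
  mu <- sum(density) / length(density)
  sigma <- sqrt(sum((density - mu)^2) / length(density))
  z <- (density - mu) / sigma
  list(z = z, significant = z >= cutoff)
}
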