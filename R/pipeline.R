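#' Run the full MAFD + AFDDD mapping pipeline
#'
#' Orchestrates the end-to-end workflow: read the two pools' variant calls,
#' apply the primary and confidence filter cascades, match variants across
#' pools, assign genotype groups to pool-common variants, run MAFD mapping on
#' the mutant-pool-specific variants and AFDDD mapping on the common
#' variants, and write all tables plus a manifest recording versions,
#' parameters and input checksums. Identical config and inputs produce
#' identical outputs.
#'
#' @param config A named list or a path to a YAML file with entries:
#'   \describe{
#'     \item{mutant, wildtype}{input file per pool (`.vcf` or the TSV
#'       variant-table dialect, chosen by extension)}
#'     \item{layout}{named list/vector of chromosome lengths in bp}
#'     \item{out_dir}{output directory}
#'     \item{filter}{optional list of [filter_config()] arguments}
#'     \item{bands}{optional list of [zygosity_bands()] arguments}
#'     \item{mapping}{optional list: `band` (length 2), `afdd_min`, `window`,
#'       `bin_size`, `z_cutoff`}
#'     \item{force}{overwrite an existing run directory (default `FALSE`)}
#'   }
#' @return The output directory path, invisibly. Side effects: filter
#'   reports, genotype-group summary, MAFD and AFDDD profile/bin/region
#'   files, and `manifest.yaml` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  for (key in c("mutant", "wildtype", "layout", "out_dir")) {
    if (is.null(config[[key]])) {
      rlang::abort(sprintf("pipeline config lacks required entry '%s'", key))
    }
  }
  out_dir <- config$out_dir
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !isTRUE(config$force)) {
    rlang::abort(sprintf(
      "output directory %s exists and is not empty; set force: true to overwrite", out_dir
    ))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  layout <- genome_layout(unlist(config$layout))
  fcfg <- do.call(filter_config, config$filter %||% list())
  bands <- do.call(zygosity_bands, config$bands %||% list())
  map_par <- config$mapping %||% list()
  band <- unlist(map_par$band %||% c(40, 60))
  afdd_min <- map_par$afdd_min %||% 30
  window <- map_par$window %||% 20
  bin_size <- map_par$bin_size %||% 1e6
  z_cutoff <- map_par$z_cutoff %||% 2.6

  manifest <- list(
    tool = "mafdd",
    version = as.character(utils::packageVersion("mafdd")),
    inputs = list(mutant = config$mutant, wildtype = config$wildtype),
    checksums = as.list(tools::md5sum(c(config$mutant, config$wildtype))),
    parameters = list(
      filter = unclass(fcfg), zygosity_bands = unclass(bands),
      mafd_band = band, afdd_min = afdd_min, window = window,
      bin_size = bin_size, z_cutoff = z_cutoff
    ),
    stages = list()
  )
  flush_manifest <- function() {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      flush_manifest()
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "complete")
    res
  }
  reader <- function(path, label) {
    if (!file.exists(path)) {
      rlang::abort(sprintf("input file for the %s pool not found: %s", label, path))
    }
    if (grepl("\\.vcf(\\.gz)?$", path)) {
      read_pool_vcf(path, label, layout)
    } else {
      read_pool_table(path, label, layout)
    }
  }

  mutant <- stage("read_mutant", reader(config$mutant, "mutant"))
  wildtype <- stage("read_wildtype", reader(config$wildtype, "wildtype"))

  prim <- stage("filter_primary", {
    m <- filter_primary(mutant, config = fcfg)
    w <- filter_primary(wildtype, config = fcfg)
    write_filter_report(m$report, file.path(out_dir, "filter_primary_mutant.tsv"))
    write_filter_report(w$report, file.path(out_dir, "filter_primary_wildtype.tsv"))
    list(m = m$calls, w = w$calls)
  })
  conf <- stage("filter_confidence", {
    m <- filter_confidence(prim$m, config = fcfg)
    w <- filter_confidence(prim$w, config = fcfg)
    write_filter_report(m$report, file.path(out_dir, "filter_confidence_mutant.tsv"))
    write_filter_report(w$report, file.path(out_dir, "filter_confidence_wildtype.tsv"))
    list(m = m$calls, w = w$calls)
  })
  matched <- stage("match_pools", match_pools(conf$m, conf$w))
  common <- matched[matched$membership == "common", , drop = FALSE]
  mutant_specific_keys <- matched[matched$membership == "mutant_specific", , drop = FALSE]
  mutant_specific <- dplyr::semi_join(
    conf$m, mutant_specific_keys, by = c("chrom", "pos", "class", "ref", "alt")
  )

  stage("genotype_groups", {
    grouped <- assign_genotype_groups(common, bands)
    summ <- summarise_genotype_groups(grouped)
    con <- file(file.path(out_dir, "genotype_groups.tsv"), "w")
    writeLines(output_header(list(het_band = paste(bands$het_min, bands$het_max, sep = "-"))), con)
    utils::write.table(summ, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    grouped
  })
  mafd <- stage("mafd_map", mafd_map(mutant_specific, layout, band = band,
                                     window = window, bin_size = bin_size,
                                     z_cutoff = z_cutoff))
  afddd <- stage("afddd_map", afddd_map(common, layout, afdd_min = afdd_min,
                                        window = window, bin_size = bin_size,
                                        z_cutoff = z_cutoff))
  stage("write_results", {
    write_mapping_result(mafd, out_dir, layout = layout)
    write_mapping_result(afddd, out_dir, layout = layout)
  })

  manifest$counts <- list(
    mutant_input = nrow(mutant), wildtype_input = nrow(wildtype),
    mutant_filtered = nrow(conf$m), wildtype_filtered = nrow(conf$w),
    common = nrow(common), mutant_specific = nrow(mutant_specific),
    mafd_selected = mafd$n_selected, afddd_selected = afddd$n_selected
  )
  flush_manifest()
  invisible(out_dir)
}
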