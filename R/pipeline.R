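# config-driven orchestration: curate -> spectrum -> signature enrichment,
# with result tables and a reproducibility manifest

#' Run the full mutation-analysis pipeline from a config
#'
#' Executes curation ([curate()]), spectrum tabulation
#' ([mutation_spectrum()]) and cohort-level signature enrichment ([trims()])
#' from a single configuration, writing all result tables plus a manifest
#' (JSON) that records the package version, a hash of the normalized config,
#' and MD5 checksums of every input and output. Re-running with identical
#' inputs reproduces byte-identical result tables.
#'
#' @param config a named list or the path of a YAML file with fields:
#'   \describe{
#'     \item{genome}{path to the reference FASTA.}
#'     \item{mutations}{path to a VarScan-style variant TSV (all isolates).}
#'     \item{baseline}{optional path to the pre-treatment culture's variants.}
#'     \item{cohorts}{named mapping sample -> cohort; every sample in exactly
#'       one cohort.}
#'     \item{vaf_threshold}{VAF cutoff (default 0.9).}
#'     \item{share_min}{shared-sample cutoff (default 2).}
#'     \item{window, motif, alt}{signature parameters (defaults 20, `gCn`,
#'       `A`).}
#'     \item{out_dir}{output directory, created if missing.}
#'   }
#' @return the manifest, invisibly (class `"run_manifest"`).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_("config must be a list or a YAML file path")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  cfg <- stage("validate-config", .check_config(config))
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  genome <- stage("read-genome", read_fasta(cfg$genome))
  muts <- stage("read-mutations", read_mutations(cfg$mutations, "varscan"))
  baseline <- if (!is.null(cfg$baseline)) {
    stage("read-baseline", read_mutations(cfg$baseline, "varscan"))
  } else {
    NULL
  }
  stage("validate-mutations", validate_mutations(muts, genome))

  cohort_map <- unlist(cfg$cohorts)
  unmapped <- setdiff(unique(muts$sample), names(cohort_map))
  if (length(unmapped)) {
    stop_("stage 'validate-config' failed: sample(s) without a cohort: ",
          paste(unmapped, collapse = ", "))
  }

  cur <- stage("curate", curate(muts, baseline,
                                vaf_threshold = cfg$vaf_threshold,
                                share_min = cfg$share_min))
  spec <- stage("spectrum", mutation_spectrum(genome, cur$mutations))
  fit <- stage("trims", trims(genome, cur$mutations, cohort = cohort_map,
                              window = cfg$window, motif = cfg$motif,
                              alt = cfg$alt))

  paths <- c(filtered_mutations = "filtered_mutations.tsv",
             filter_report = "filter_report.tsv",
             spectrum_classes = "spectrum_classes.tsv",
             spectrum_contexts = "spectrum_contexts.tsv",
             trims_results = "trims_results.tsv")
  paths <- stats::setNames(file.path(out_dir, paths), names(paths))
  stage("write-results", {
    write_results(cur$mutations, paths[["filtered_mutations"]])
    write_results(cur$report, paths[["filter_report"]])
    cls <- data.frame(klass = rownames(spec$classes), spec$classes,
                      check.names = FALSE)
    write_results(cls, paths[["spectrum_classes"]])
    ctx <- data.frame(context = rownames(spec$contexts), spec$contexts,
                      check.names = FALSE)
    write_results(ctx, paths[["spectrum_contexts"]])
    write_results(fit, paths[["trims_results"]])
  })

  inputs <- c(genome = cfg$genome, mutations = cfg$mutations,
              baseline = cfg$baseline)
  manifest <- list(
    tool = "trimspect",
    version = as.character(utils::packageVersion("trimspect")),
    config = cfg,
    config_md5 = .hash_config(cfg),
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    output_md5 = as.list(tools::md5sum(unname(paths))),
    filter_report = as.data.frame(cur$report)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

.check_config <- function(config) {
  for (field in c("genome", "mutations", "cohorts", "out_dir")) {
    if (is.null(config[[field]])) stop_("config lacks field '", field, "'")
  }
  for (field in c("genome", "mutations", "baseline")) {
    path <- config[[field]]
    if (!is.null(path) && !file.exists(path)) {
      stop_("config file for '", field, "' not found: ", path)
    }
  }
  cm <- unlist(config$cohorts)
  if (length(cm) == 0L) stop_("config cohorts must be non-empty")
  if (anyDuplicated(names(cm))) {
    stop_("sample '", names(cm)[duplicated(names(cm))][1L],
          "' assigned to more than one cohort")
  }
  config$vaf_threshold <- config$vaf_threshold %||% 0.9
  config$share_min <- config$share_min %||% 2L
  config$window <- config$window %||% 20L
  config$motif <- config$motif %||% "gCn"
  config$alt <- config$alt %||% "A"
  config
}

.hash_config <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("trimspect run manifest (version ", x$version, ")\n", sep = "")
  cat("  config md5:", x$config_md5, "\n")
  cat("  outputs:\n")
  for (nm in names(x$output_md5)) cat("   ", nm, "\n")
  invisible(x)
}
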