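#' Assemble a run configuration
#'
#' @param pedigree,vcf,phenotypes input file paths.
#' @param out_dir output directory.
#' @param definitions phenotype definitions to analyze.
#' @param mode \code{"both_parents"} or \code{"het_only"}.
#' @param fdr_level BH level.
#' @param maf_threshold founder-MAF exclusion boundary.
#' @param min_informative informative-family testability threshold.
#' @param clustered family-clustered sandwich.
#' @param include_deterministic retain deterministic other-parent
#'   transmissions.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(pedigree, vcf, phenotypes, out_dir,
                       definitions = phenotype_definition_names(),
                       mode = "both_parents", fdr_level = 0.05,
                       maf_threshold = 0.05, min_informative = 21L,
                       clustered = TRUE, include_deterministic = TRUE) {
  stopifnot(fdr_level > 0, fdr_level < 1,
            maf_threshold >= 0, maf_threshold <= 0.5,
            min_informative >= 1L)
  mode <- match.arg(mode, c("both_parents", "het_only"))
  for (d in definitions) phenotype_definition(d)  # validates names
  structure(list(pedigree = pedigree, vcf = vcf, phenotypes = phenotypes,
                 out_dir = out_dir, definitions = definitions, mode = mode,
                 fdr_level = fdr_level, maf_threshold = maf_threshold,
                 min_informative = as.integer(min_informative),
                 clustered = clustered,
                 include_deterministic = include_deterministic),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the \code{\link{run_config}} arguments; entries in
#' \code{overrides} (e.g. parsed command-line flags) take precedence.
#'
#' @param path YAML file path.
#' @param overrides named list of overriding values.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  cfg <- utils::modifyList(cfg, overrides[!vapply(overrides, is.null, TRUE)])
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Reads the pedigree, genotypes and phenotypes, prepares the requested
#' phenotype definitions (log transform, founder EM imputation, covariate
#' adjustment, principal components), scans every retained variant and
#' writes to \code{out_dir}: \code{results.tsv}, the variant
#' \code{exclusions.tsv}, and \code{manifest.json} (configuration echo,
#' input checksums, package version).  Manifest-identical runs produce
#' byte-identical result files.  Per-variant problems are recorded in the
#' results status column and never abort the run.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, the \code{scan_results}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("pedigree", "vcf", "phenotypes")) {
    if (!file.exists(config[[f]])) stop(f, " file not found: ", config[[f]])
  }
  ql_log("info", "reading pedigree and genotypes")
  ped <- read_pedigree(config$pedigree)
  gen <- read_genotypes(config$vcf, ped)
  phen <- read_phenotypes(config$phenotypes)
  ql_log("info", sprintf("prepare: %d definitions", length(config$definitions)))
  prep <- prepare_phenotypes(phen, ped, config$definitions)
  ql_log("info", sprintf("scan: %d variants, mode %s",
                         nrow(gen$variants), config$mode))
  res <- run_scan(ped, gen, prep, definitions = config$definitions,
                  mode = config$mode, fdr_level = config$fdr_level,
                  maf_threshold = config$maf_threshold,
                  min_informative = config$min_informative,
                  include_deterministic = config$include_deterministic,
                  clustered = config$clustered)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_prepared_phenotypes(prep, config$out_dir)
  write_results(res, file.path(config$out_dir, "results.tsv"))
  write_exclusion_log(attr(res, "exclusions"),
                      file.path(config$out_dir, "exclusions.tsv"))
  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(c(config$pedigree, config$vcf,
                                     config$phenotypes))),
    package_version = as.character(utils::packageVersion("qltdt"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
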