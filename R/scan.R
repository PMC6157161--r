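#' Prepare analysis phenotypes from raw longitudinal trait tables
#'
#' Runs the full phenotype pipeline: natural-log transform of both traits,
#' advisory KS normality report, EM estimation of the multivariate-normal
#' parameters on founders, conditional-expectation imputation of missing
#' cells for all individuals, founder-fitted covariate adjustment, and
#' principal-component construction for each requested definition.
#'
#' @param phen named list of raw trait matrices (first element the primary
#'   trait, second the covariate trait), as from
#'   \code{\link{read_phenotypes}}.
#' @param pedigree a \code{pedigree_table}.
#' @param definitions character vector of definition names
#'   (default all six).
#' @return list with \code{scores} (named list of individuals x k
#'   matrices, one per definition), \code{trait_log}, \code{trait_adjusted}
#'   (completed matrices), \code{em} (founder \code{mvn_params}) and
#'   \code{normality} (per-column KS report, raw and log scale).
#' @export
prepare_phenotypes <- function(phen, pedigree,
                               definitions = phenotype_definition_names()) {
  stopifnot(length(phen) >= 1L)
  trait_name <- names(phen)[1L]
  logged <- lapply(phen, log_transform)

  normality <- lapply(names(phen), function(nm) {
    do.call(rbind, lapply(colnames(phen[[nm]]), function(cl) {
      raw <- ks_normality(phen[[nm]][, cl])
      lg <- ks_normality(logged[[nm]][, cl])
      data.frame(column = cl, raw_p = raw$p_value, raw_departs = raw$departs,
                 log_p = lg$p_value, log_departs = lg$departs)
    }))
  })
  names(normality) <- names(phen)

  imp <- impute_phenotypes(logged, pedigree)
  trait_log <- imp$completed[[trait_name]]

  needs_adj <- any(vapply(definitions,
                          function(d) phenotype_definition(d)$adjusted, TRUE))
  trait_adj <- NULL
  if (needs_adj) {
    if (length(phen) < 2L) stop("adjusted definitions need a covariate trait")
    trait_adj <- adjust_for_covariate(trait_log, imp$completed[[names(phen)[2L]]],
                                      founder_ids(pedigree))
  }

  scores <- lapply(definitions, function(d) {
    build_phenotypes(d, trait_log, trait_adj)
  })
  names(scores) <- definitions

  list(scores = scores, trait_log = trait_log, trait_adjusted = trait_adj,
       em = imp$params, normality = normality)
}

#' Write prepared phenotype scores to per-definition TSV files
#'
#' One file \code{phenotypes_<definition>.tsv} per definition, with
#' \code{individual_id} and the k score columns.
#'
#' @param prepared result of \code{\link{prepare_phenotypes}}.
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
write_prepared_phenotypes <- function(prepared, out_dir) {
  paths <- character(0)
  for (d in names(prepared$scores)) {
    sc <- prepared$scores[[d]]
    out <- data.frame(individual_id = rownames(sc),
                      sc, check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(out_dir, sprintf("phenotypes_%s.tsv", d))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with ordered p-values, reject the largest i such
#' that p(i) <= (i/m) * level and all smaller; the reported q-values are
#' the usual monotone BH-adjusted p-values (so rejection is equivalent to
#' q <= level).
#'
#' @param p_values numeric vector in [0, 1].
#' @param fdr_level target FDR (default 0.05).
#' @return list with \code{q_values} and logical \code{reject}.
#' @export
benjamini_hochberg <- function(p_values, fdr_level = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= fdr_level)
}

#' Genome scan: test every retained variant under each phenotype definition
#'
#' Applies the founder-MAF variant filter, extracts informative nuclear-
#' family units per variant, runs the quasi-likelihood transmission test
#' for each (variant, definition) pair and controls the FDR with the
#' Benjamini-Hochberg procedure separately within each definition
#' (untested/degenerate variants carry no p-value and do not enter m).
#' Output rows are deterministically ordered by chromosome, position and
#' definition, so the scan is invariant to the input variant order.
#'
#' @param pedigree a \code{pedigree_table}.
#' @param genotypes a \code{genotype_matrix}.
#' @param prepared result of \code{\link{prepare_phenotypes}} (or a named
#'   list of score matrices).
#' @param definitions definition names to scan (default: those available
#'   in \code{prepared}).
#' @param mode \code{"both_parents"} or \code{"het_only"}.
#' @param fdr_level BH level (default 0.05).
#' @param maf_threshold founder-MAF exclusion boundary (default 0.05).
#' @param min_informative minimum informative families for testability
#'   (default 21).
#' @param include_deterministic,clustered passed to \code{\link{ql_fit}}.
#' @return object of class \code{scan_results}: a data.frame with columns
#'   variant_id, chromosome, position, phenotype_definition, mode,
#'   n_informative_families, n_offspring_used, statistic, df, p_value,
#'   q_value, significant, status; the variant exclusion log is attached
#'   as attribute \code{"exclusions"}.
#' @export
run_scan <- function(pedigree, genotypes, prepared,
                     definitions = NULL, mode = c("both_parents", "het_only"),
                     fdr_level = 0.05, maf_threshold = 0.05,
                     min_informative = 21L, include_deterministic = TRUE,
                     clustered = TRUE) {
  mode <- match.arg(mode)
  scores <- if (!is.null(prepared$scores)) prepared$scores else prepared
  if (is.null(definitions)) definitions <- names(scores)
  stopifnot(all(definitions %in% names(scores)))

  flt <- filter_variants(genotypes, pedigree, maf_threshold)
  vinfo <- genotypes$variants
  rows <- vector("list", length(flt$retained) * length(definitions))
  ri <- 0L
  for (vid in flt$retained) {
    fam_units <- suppressWarnings(
      informative_families(vid, pedigree, genotypes,
                           min_informative = min_informative)
    )
    vi <- vinfo[match(vid, vinfo$variant_id), ]
    for (d in definitions) {
      vr <- test_variant(fam_units, scores[[d]], mode = mode,
                         include_deterministic = include_deterministic,
                         clustered = clustered)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        variant_id = vid, chromosome = vi$chromosome, position = vi$position,
        phenotype_definition = d, mode = mode,
        n_informative_families = vr$n_informative_families,
        n_offspring_used = vr$n_offspring_used,
        statistic = vr$statistic, df = vr$df, p_value = vr$p_value,
        q_value = NA_real_, significant = NA, status = vr$status,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (ri) do.call(rbind, rows[seq_len(ri)]) else empty_scan_results()

  # BH within each definition over the rows with a valid test
  for (d in definitions) {
    idx <- which(res$phenotype_definition == d & res$status == "ok")
    if (length(idx)) {
      bh <- benjamini_hochberg(res$p_value[idx], fdr_level)
      res$q_value[idx] <- bh$q_values
      res$significant[idx] <- bh$reject
    }
  }

  chrn <- suppressWarnings(as.numeric(res$chromosome))
  ord <- order(is.na(chrn), chrn, res$chromosome, res$position,
               res$phenotype_definition)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "exclusions") <- flt$exclusions
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("scan_results", "data.frame")
  res
}

empty_scan_results <- function() {
  data.frame(variant_id = character(0), chromosome = character(0),
             position = integer(0), phenotype_definition = character(0),
             mode = character(0), n_informative_families = integer(0),
             n_offspring_used = integer(0), statistic = numeric(0),
             df = integer(0), p_value = numeric(0), q_value = numeric(0),
             significant = logical(0), status = character(0),
             stringsAsFactors = FALSE)
}

#' Write scan results to a TSV
#'
#' Fixed column order, header line, floating-point columns at 6
#' significant digits, NA written as "NA".
#'
#' @param results a \code{scan_results} data.frame.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  for (cl in c("statistic", "p_value", "q_value")) {
    out[[cl]] <- format_num6(out[[cl]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to ", path)
  invisible(path)
}

#' Read back a results TSV written by \code{\link{write_results}}
#' @param path TSV path.
#' @return data.frame with the scan-result columns.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE,
                    colClasses = c(variant_id = "character",
                                   chromosome = "character"))
}
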