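#' Read a wide longitudinal phenotype table
#'
#' Expects a TSV with an \code{individual_id} column followed by one column
#' per trait x time point (e.g. \code{TG1..TG4}, \code{HDL1..HDL4}); empty
#' cells or "NA" denote missing measurements.
#'
#' @param path TSV path.
#' @param traits character vector of trait prefixes to extract
#'   (default \code{c("TG", "HDL")}).
#' @return named list of numeric matrices (individuals x time points, NA
#'   for missing), one per trait, rownames = individual IDs.
#' @export
read_phenotypes <- function(path, traits = c("TG", "HDL")) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""), check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(tab)) stop("phenotype TSV must have an individual_id column")
  out <- list()
  for (tr in traits) {
    cols <- grep(paste0("^", tr, "[0-9]+$"), names(tab), value = TRUE)
    if (!length(cols)) stop("no columns found for trait prefix: ", tr)
    cols <- cols[order(as.integer(sub(paste0("^", tr), "", cols)))]
    m <- as.matrix(tab[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- tab$individual_id
    out[[tr]] <- m
  }
  out
}

#' Natural-log transform of a phenotype matrix
#'
#' Observed cells are replaced by their natural logarithm; the missingness
#' pattern is unchanged.  Lipid-panel traits are strongly right-skewed on
#' the raw scale and close to normal after the log, which the downstream
#' multivariate-normal imputation relies on.
#'
#' @param m numeric matrix with NA for missing cells; observed values must
#'   be strictly positive.
#' @return matrix of the same shape on the log scale.
#' @export
log_transform <- function(m) {
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    rn <- if (is.null(rownames(m))) as.character(bad[1, 1]) else rownames(m)[bad[1, 1]]
    cn <- if (is.null(colnames(m))) as.character(bad[1, 2]) else colnames(m)[bad[1, 2]]
    stop(sprintf("nonpositive phenotype value for individual %s, column %s", rn, cn))
  }
  log(m)
}

#' Kolmogorov-Smirnov normality check with plug-in parameters
#'
#' One-sample KS test of the observed values against a normal distribution
#' with the sample's estimated mean and standard deviation.  With estimated
#' parameters the classical KS p-value is anti-conservative
#' (Lilliefors-style plug-in), so the result is advisory - a logged report
#' used to justify the log transform - not a gate that alters the pipeline.
#'
#' @param values numeric vector; NAs dropped; needs >= 8 observed values
#'   and nonzero variance.
#' @param level departure flag level (default 0.05).
#' @return list with \code{statistic}, \code{p_value}, \code{departs}.
#' @export
ks_normality <- function(values, level = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 8L) stop("need at least 8 observed values")
  s <- stats::sd(x)
  if (s == 0) stop("constant vector: normality check undefined")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean = mean(x), sd = s))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       departs = kt$p.value < level)
}
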