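#' Adjust a trait for a covariate trait using founder-fitted regressions
#'
#' For each trait time point, an ordinary least-squares regression with
#' intercept on all covariate time points is fitted on founders only; the
#' returned matrix holds residuals (observed minus predicted) for every
#' individual, computed with the founder-fitted coefficients.  Fitting on
#' founders keeps the adjustment free of within-family correlation.
#'
#' @param trait complete (post-imputation) numeric matrix, individuals x
#'   time points.
#' @param covariate complete numeric matrix with the same rownames.
#' @param founders character vector of founder individual IDs.
#' @return residual matrix with the dimensions and dimnames of
#'   \code{trait}.
#' @export
adjust_for_covariate <- function(trait, covariate, founders) {
  stopifnot(!anyNA(trait), !anyNA(covariate),
            identical(rownames(trait), rownames(covariate)))
  founders <- intersect(founders, rownames(trait))
  if (!length(founders)) stop("no founders among phenotype rows")
  xf <- cbind(1, covariate[founders, , drop = FALSE])
  if (qr(xf)$rank < ncol(xf)) stop("rank-deficient covariate design among founders")
  beta <- qr.solve(xf, trait[founders, , drop = FALSE])
  xall <- cbind(1, covariate)
  res <- trait - xall %*% beta
  dimnames(res) <- dimnames(trait)
  res
}
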