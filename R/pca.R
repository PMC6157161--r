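#' First principal component of a two-column matrix
#'
#' Projects the column-centered data onto the leading eigenvector of the
#' 2 x 2 sample covariance matrix.  The eigenvector sign is fixed so its
#' component sum is positive (if the sum is zero, the first component is
#' made positive), which keeps scores stable across runs and platforms.
#'
#' @param x numeric matrix with exactly 2 columns and n >= 3 complete rows.
#' @return numeric vector of scores (mean zero; variance equal to the
#'   leading eigenvalue of the sample covariance).
#' @export
first_principal_component <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("expected a two-column matrix")
  if (nrow(x) < 3L) stop("need at least 3 rows")
  if (anyNA(x)) stop("matrix must be complete (impute first)")
  cc <- stats::cov(x)
  if (all(cc == 0)) stop("zero covariance matrix: no principal axis")
  e <- eigen(cc, symmetric = TRUE)
  v <- e$vectors[, 1L]
  s <- sum(v)
  if (s < 0 || (s == 0 && v[1L] < 0)) v <- -v
  drop(sweep(x, 2L, colMeans(x)) %*% v)
}

#' Phenotype definitions
#'
#' The six analysis phenotypes built from a 4-time-point trait, around a
#' treatment administered between time points 2 and 3:
#' \itemize{
#'   \item \code{TBATPre}: PC1 of time points 1-2 (pre-treatment), k = 1;
#'   \item \code{TBATPost}: PC1 of time points 3-4 (post-treatment), k = 1;
#'   \item \code{MTBAT}: bivariate (TBATPre, TBATPost), k = 2;
#'   \item \code{*Adj}: same constructions on the covariate-adjusted
#'     residual trait.
#' }
#'
#' @param name definition name.
#' @return list with \code{name}, \code{k}, \code{adjusted},
#'   \code{blocks} (list of time-point index pairs).
#' @export
phenotype_definition <- function(name) {
  defs <- list(
    MTBAT       = list(k = 2L, adjusted = FALSE, blocks = list(c(1L, 2L), c(3L, 4L))),
    MTBATAdj    = list(k = 2L, adjusted = TRUE,  blocks = list(c(1L, 2L), c(3L, 4L))),
    TBATPre     = list(k = 1L, adjusted = FALSE, blocks = list(c(1L, 2L))),
    TBATPreAdj  = list(k = 1L, adjusted = TRUE,  blocks = list(c(1L, 2L))),
    TBATPost    = list(k = 1L, adjusted = FALSE, blocks = list(c(3L, 4L))),
    TBATPostAdj = list(k = 1L, adjusted = TRUE,  blocks = list(c(3L, 4L)))
  )
  if (!name %in% names(defs)) {
    stop("unknown phenotype definition: ", name,
         " (expected one of ", paste(names(defs), collapse = ", "), ")")
  }
  c(list(name = name), defs[[name]])
}

#' All phenotype definition names
#' @return character vector of the six definition names.
#' @export
phenotype_definition_names <- function() {
  c("MTBAT", "MTBATAdj", "TBATPre", "TBATPreAdj", "TBATPost", "TBATPostAdj")
}

#' Build per-individual phenotype vectors for a definition
#'
#' Principal-component scores are computed over all individuals in the
#' supplied complete matrices; callers subset to offspring afterwards.
#'
#' @param definition a name or a \code{\link{phenotype_definition}} result.
#' @param trait complete log-scale trait matrix (individuals x 4 time
#'   points).
#' @param trait_adjusted complete residual matrix (required for the
#'   \code{*Adj} definitions).
#' @return numeric matrix, individuals x k, rownames preserved.
#' @export
build_phenotypes <- function(definition, trait, trait_adjusted = NULL) {
  if (is.character(definition)) definition <- phenotype_definition(definition)
  src <- if (definition$adjusted) {
    if (is.null(trait_adjusted)) stop("adjusted definition needs trait_adjusted")
    trait_adjusted
  } else trait
  scores <- vapply(definition$blocks, function(b) {
    first_principal_component(src[, b, drop = FALSE])
  }, numeric(nrow(src)))
  scores <- matrix(scores, nrow = nrow(src),
                   dimnames = list(rownames(src),
                                   paste0("PC", seq_along(definition$blocks))))
  scores
}
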