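#' EM estimation of a multivariate normal with missing data
#'
#' Maximum-likelihood estimation of the mean vector and covariance matrix
#' of a multivariate normal from a data matrix with ignorable (MCAR/MAR)
#' missingness.  The E-step replaces each row's missing block by its
#' conditional expectation given the observed block and accumulates the
#' conditional covariance; the M-step recomputes the mean and the ML (1/n)
#' covariance.  The observed-data log-likelihood is monotone nondecreasing
#' across iterations and convergence is declared when its change drops
#' below \code{tol}.
#'
#' @param y numeric matrix (rows = independent observations, e.g. pedigree
#'   founders); NA marks missing cells.  All-missing rows are dropped with
#'   a warning; every column needs at least 2 observed values.
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter maximum EM iterations (default 2000).
#' @return object of class \code{mvn_params}: list with \code{mean},
#'   \code{covariance}, \code{loglik} (trajectory), \code{converged},
#'   \code{n_iter}, \code{n_used}.
#' @export
em_mvn_fit <- function(y, tol = 1e-8, max_iter = 2000L) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  p <- ncol(y)
  all_miss <- rowSums(!is.na(y)) == 0L
  if (any(all_miss)) {
    warning(sum(all_miss), " all-missing row(s) dropped from EM fit")
    y <- y[!all_miss, , drop = FALSE]
  }
  n <- nrow(y)
  if (any(colSums(!is.na(y)) < 2L)) stop("every column needs >= 2 observed values")

  mu <- colMeans(y, na.rm = TRUE)
  sigma <- init_pairwise_cov(y, mu)

  obs <- !is.na(y)
  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  pat_rows <- split(seq_len(n), pat_key)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step (grouped by missingness pattern) + observed-data loglik
    yhat <- y
    cc <- matrix(0, p, p)
    ll <- 0
    for (rows in pat_rows) {
      o <- obs[rows[1L], ]
      m <- !o
      yo <- y[rows, o, drop = FALSE]
      soo <- sigma[o, o, drop = FALSE]
      ll <- ll + sum(dmvnorm_log(yo, mu[o], soo))
      if (any(m)) {
        som <- sigma[o, m, drop = FALSE]
        w <- safe_solve(soo, som)                       # Soo^-1 Som
        cond <- sweep(yo, 2L, mu[o]) %*% w              # (yo - mu_o) Soo^-1 Som
        yhat[rows, m] <- rep(mu[m], each = length(rows)) + cond
        cmm <- sigma[m, m, drop = FALSE] - crossprod(som, w)
        cc[m, m] <- cc[m, m] + length(rows) * cmm
      }
    }
    ll_trace <- c(ll_trace, ll)
    # M-step
    mu <- colMeans(yhat)
    dev <- sweep(yhat, 2L, mu)
    sigma <- (crossprod(dev) + cc) / n
    sigma <- (sigma + t(sigma)) / 2
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")
  structure(list(mean = mu, covariance = sigma, loglik = ll_trace,
                 converged = converged, n_iter = iter, n_used = n),
            class = "mvn_params")
}

# available-case initial covariance projected to the nearest PSD matrix
init_pairwise_cov <- function(y, mu) {
  p <- ncol(y)
  s <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      both <- !is.na(y[, j]) & !is.na(y[, k])
      njk <- sum(both)
      v <- if (njk >= 2L) {
        sum((y[both, j] - mu[j]) * (y[both, k] - mu[k])) / njk
      } else 0
      s[j, k] <- s[k, j] <- v
    }
  }
  e <- eigen(s, symmetric = TRUE)
  lam <- pmax(e$values, 1e-8 * max(abs(e$values), 1))
  e$vectors %*% (lam * t(e$vectors))
}

dmvnorm_log <- function(x, mean, sigma) {
  x <- as.matrix(x)
  q <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) chol(sigma + diag(1e-10, q)))
  z <- forwardsolve(t(ch), t(sweep(x, 2L, mean)))
  -0.5 * (q * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

# solve(a, b) with SVD pseudo-inverse fallback for singular blocks
safe_solve <- function(a, b, warn = TRUE) {
  out <- tryCatch(solve(a, b), error = function(e) NULL)
  if (is.null(out)) {
    if (warn) warning("singular observed-block covariance: pseudo-inverse used")
    out <- pseudo_inverse(a) %*% b
  }
  out
}

pseudo_inverse <- function(a, rtol = 1e-12) {
  s <- svd(a)
  pos <- s$d > rtol * max(s$d)
  dinv <- ifelse(pos, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

#' Conditional-expectation imputation of one partially observed row
#'
#' Missing entries are set to the conditional mean under a multivariate
#' normal with the given parameters:
#' mu_m + Sigma_mo Sigma_oo^-1 (y_o - mu_o).  Observed entries are left
#' untouched; an all-missing row is filled with the mean vector.
#'
#' @param row numeric vector with NA for missing entries.
#' @param params an \code{mvn_params} (or list with \code{mean} and
#'   \code{covariance}).
#' @return the completed numeric vector.
#' @export
conditional_impute <- function(row, params) {
  mu <- params$mean; sigma <- params$covariance
  stopifnot(length(row) == length(mu))
  m <- is.na(row)
  if (!any(m)) return(row)
  if (all(m)) { row[] <- mu; return(row) }
  o <- !m
  w <- safe_solve(sigma[o, o, drop = FALSE], sigma[o, m, drop = FALSE])
  row[m] <- mu[m] + drop(crossprod(w, row[o] - mu[o]))
  row
}

#' Impute missing phenotype cells via founder-estimated MVN parameters
#'
#' Fits the EM estimator on the founder rows of the (column-bound) trait
#' matrices, then completes every individual's missing cells by plug-in
#' conditional expectation under the founder-estimated parameters
#' (founders' own missing cells included).
#'
#' @param mats named list of log-scale phenotype matrices sharing rownames
#'   (individual IDs), e.g. \code{list(TG = ..., HDL = ...)}.
#' @param pedigree a \code{pedigree_table}.
#' @param tol,max_iter passed to \code{\link{em_mvn_fit}}.
#' @return list with \code{completed} (list of completed matrices in the
#'   input layout) and \code{params} (the founder \code{mvn_params}).
#' @export
impute_phenotypes <- function(mats, pedigree, tol = 1e-8, max_iter = 2000L) {
  joint <- do.call(cbind, unname(mats))
  widths <- vapply(mats, ncol, 0L)
  fnd <- intersect(founder_ids(pedigree), rownames(joint))
  if (!length(fnd)) stop("no founders with phenotype rows")
  fit <- em_mvn_fit(joint[fnd, , drop = FALSE], tol = tol, max_iter = max_iter)
  done <- t(apply(joint, 1L, conditional_impute, params = fit))
  dimnames(done) <- dimnames(joint)
  completed <- list()
  off <- 0L
  for (nm in names(mats)) {
    completed[[nm]] <- done[, off + seq_len(widths[[nm]]), drop = FALSE]
    colnames(completed[[nm]]) <- colnames(mats[[nm]])
    off <- off + widths[[nm]]
  }
  list(completed = completed, params = fit)
}
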