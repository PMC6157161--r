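#' Fit the quasi-likelihood transmission model
#'
#' Solves the quasi-score equations
#' \deqn{\sum_j D_j^T V_j^{-1} (X_j - \lambda_j(\alpha, \gamma)) = 0}
#' by Fisher scoring, where per offspring the transmission indicator of
#' the designated heterozygous parent (Z) has conditional mean
#' \eqn{expit(\alpha_1 + \gamma^T Y_j)} given the phenotype vector
#' \eqn{Y_j}, the other parent's indicator (W) has mean
#' \eqn{expit(\alpha_2 + \gamma^T Y_j)}, and \eqn{V_j} is the diagonal
#' Bernoulli working covariance \eqn{\lambda(1 - \lambda)}.  Double-
#' heterozygote ambiguous offspring contribute through the observable
#' total S = Z + W, with mean the sum of the two link means and variance
#' the sum of the two Bernoulli variances.  Transmissions from homozygous
#' (noninformative) other parents are deterministic observations; by
#' default they are retained with the same working model, which is where
#' the method draws power beyond heterozygous-parent-only tests (and also
#' why, like any use of noninformative-parent information, it is exposed
#' to population stratification; see the package vignette).  Setting
#' \code{include_deterministic = FALSE} restricts to non-deterministic
#' components.
#'
#' The covariance of the estimate is the sandwich
#' \eqn{A^{-1} B A^{-1}} with \eqn{A = \sum D^T V^{-1} D} and
#' \eqn{B = \sum_g U_g U_g^T} accumulated over independent units
#' \eqn{g} - families when labels are supplied (the default, see
#' \code{clustered}), otherwise offspring.
#'
#' @param obs data.frame from \code{\link{encode_transmissions}} (valid
#'   rows only), one row per offspring.
#' @param y numeric matrix of offspring phenotypes, rows aligned with
#'   \code{obs}, k columns.
#' @param mode \code{"both_parents"} (default) or \code{"het_only"}; in
#'   het-only mode only unambiguous Z components from heterozygous parents
#'   enter (classical-TDT-style information) and the model has a single
#'   intercept.
#' @param include_deterministic retain deterministic W components
#'   (default TRUE; both-parents mode only).
#' @param family optional vector of family labels aligned with \code{obs}
#'   for the clustered sandwich.
#' @param clustered accumulate the sandwich meat by family (default TRUE
#'   when family labels are supplied).  Family-level accumulation is
#'   required for valid inference whenever deterministic components are
#'   retained: a homozygous parent transmits the same allele to every
#'   offspring, so those components are perfectly correlated within a
#'   family.  It reduces to offspring-level accumulation for
#'   single-offspring families and is never anti-conservative, so it is
#'   the default.
#' @param tol convergence tolerance on the max-abs quasi-score
#'   (default 1e-8).
#' @param max_iter maximum Fisher-scoring iterations (default 100).
#' @return object of class \code{ql_fit}: list with \code{theta}
#'   (named: alpha1[, alpha2], gamma1..gammak), \code{vcov}, \code{k},
#'   \code{mode}, \code{converged}, \code{degenerate}, \code{n_iter},
#'   \code{n_offspring_used}, \code{n_families_used} and component
#'   \code{counts}.
#' @export
ql_fit <- function(obs, y, mode = c("both_parents", "het_only"),
                   include_deterministic = TRUE, family = NULL,
                   clustered = !is.null(family), tol = 1e-8,
                   max_iter = 100L) {
  mode <- match.arg(mode)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(obs)
  stopifnot(nrow(y) == n)
  if (anyNA(y) || any(!is.finite(y))) stop("phenotype vectors must be finite")
  k <- ncol(y)
  if (n < 2L + k) stop("too few usable transmission components (", n, ")")
  sds <- apply(y, 2L, stats::sd)
  if (any(sds == 0)) stop("constant phenotype column(s): ",
                          paste(which(sds == 0), collapse = ", "))
  if (clustered && is.null(family)) stop("clustered sandwich needs family labels")

  amb <- obs$ambiguous
  if (mode == "het_only") {
    use_z <- !amb
    use_w <- rep(FALSE, n)
    use_s <- rep(FALSE, n)
    pnames <- c("alpha1", paste0("gamma", seq_len(k)))
    a2_pos <- NA_integer_
  } else {
    use_z <- !amb
    use_w <- !amb & (!obs$w_deterministic | include_deterministic)
    use_s <- amb
    pnames <- c("alpha1", "alpha2", paste0("gamma", seq_len(k)))
    a2_pos <- 2L
  }
  n_par <- length(pnames)
  g_pos <- seq.int(n_par - k + 1L, n_par)
  if (mode == "both_parents" && !any(use_w) && !any(use_s)) {
    stop("no components informing alpha2; use het_only mode")
  }
  n_contrib <- sum(use_z) + sum(use_w) + sum(use_s)
  if (n_contrib < n_par) stop("too few usable transmission components (", n_contrib, ")")

  zr <- which(use_z); wr <- which(use_w); sr <- which(use_s)
  xz <- obs$z[zr]; xw <- obs$w[wr]

  score_parts <- function(theta) {
    a1 <- theta[1L]
    a2 <- if (is.na(a2_pos)) NA_real_ else theta[a2_pos]
    g <- theta[g_pos]
    yg <- drop(y %*% g)
    u <- matrix(0, length(zr) + length(wr) + length(sr), n_par)
    a <- matrix(0, n_par, n_par)
    unit <- integer(nrow(u))
    row0 <- 0L
    if (length(zr)) {
      p1 <- expit(a1 + yg[zr]); v1 <- p1 * (1 - p1)
      x <- cbind(1, matrix(0, length(zr), n_par - 1L - k), y[zr, , drop = FALSE])
      u[row0 + seq_along(zr), ] <- x * (xz - p1)
      a <- a + crossprod(x * sqrt(v1))
      unit[row0 + seq_along(zr)] <- zr
      row0 <- row0 + length(zr)
    }
    if (length(wr)) {
      p2 <- expit(a2 + yg[wr]); v2 <- p2 * (1 - p2)
      x <- cbind(0, 1, y[wr, , drop = FALSE])
      u[row0 + seq_along(wr), ] <- x * (xw - p2)
      a <- a + crossprod(x * sqrt(v2))
      unit[row0 + seq_along(wr)] <- wr
      row0 <- row0 + length(wr)
    }
    if (length(sr)) {
      p1 <- expit(a1 + yg[sr]); v1 <- p1 * (1 - p1)
      p2 <- expit(a2 + yg[sr]); v2 <- p2 * (1 - p2)
      v <- v1 + v2
      d <- cbind(v1, v2, (v1 + v2) * y[sr, , drop = FALSE])
      r <- (1 - (p1 + p2)) / v
      u[row0 + seq_along(sr), ] <- d * r
      a <- a + crossprod(d / sqrt(v))
      unit[row0 + seq_along(sr)] <- sr
    }
    list(u = u, a = a, unit = unit)
  }

  theta <- stats::setNames(rep(0, n_par), pnames)
  converged <- FALSE
  degenerate <- FALSE
  iter <- 0L
  sp <- score_parts(theta)
  snorm <- max(abs(colSums(sp$u)))
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(sp$a, colSums(sp$u)), error = function(e) NULL)
    if (is.null(step)) { degenerate <- TRUE; break }
    # step-halving on the score norm
    lam <- 1
    repeat {
      cand <- theta + lam * step
      spc <- score_parts(cand)
      scn <- max(abs(colSums(spc$u)))
      if (is.finite(scn) && (scn < snorm || lam < 1e-4)) break
      lam <- lam / 2
    }
    theta <- cand; sp <- spc; snorm <- scn
    if (max(abs(theta[seq_len(n_par - k)])) > 15) { degenerate <- TRUE; break }
    if (snorm < tol) { converged <- TRUE; break }
  }
  if (!converged && !degenerate) {
    warning("quasi-score iteration did not converge in ", max_iter, " steps")
  }

  # sandwich: meat accumulated per family (default) or per offspring, with
  # the standard G/(G-1) small-sample multiplier over the G independent units
  grp <- if (clustered) as.character(family)[sp$unit] else sp$unit
  umat <- rowsum(sp$u, group = grp, reorder = FALSE)
  gg <- nrow(umat)
  ainv <- tryCatch(solve(sp$a), error = function(e) NULL)
  if (is.null(ainv)) {
    degenerate <- TRUE
    vc <- matrix(NA_real_, n_par, n_par)
  } else {
    vc <- (gg / max(gg - 1, 1)) * ainv %*% crossprod(umat) %*% ainv
    vc <- (vc + t(vc)) / 2
  }
  dimnames(vc) <- list(pnames, pnames)

  used <- sort(unique(c(zr, wr, sr)))
  structure(list(
    theta = theta, vcov = vc, k = k, mode = mode,
    converged = converged, degenerate = degenerate, n_iter = iter,
    score_norm = snorm,
    n_offspring_used = length(used),
    n_families_used = if (!is.null(family)) length(unique(as.character(family)[used])) else NA_integer_,
    counts = c(n_z = length(zr), n_w = length(wr),
               n_w_deterministic = sum(obs$w_deterministic[wr]),
               n_s_ambiguous = length(sr),
               n_ambiguous_dropped = if (mode == "het_only") sum(amb) else 0L)
  ), class = "ql_fit")
}

#' Wald test of no association (gamma = 0)
#'
#' Computes \eqn{\hat\gamma^T [vcov_{\gamma\gamma}]^{-1} \hat\gamma},
#' referred to a chi-squared distribution with k degrees of freedom.
#'
#' @param fit a \code{\link{ql_fit}} result.
#' @return list with \code{statistic}, \code{df}, \code{p_value}; all NA
#'   with \code{status = "degenerate"} when the fit failed or the gamma
#'   covariance block is singular, else \code{status = "ok"}.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "ql_fit"))
  k <- fit$k
  bad <- list(statistic = NA_real_, df = k, p_value = NA_real_,
              status = "degenerate")
  if (fit$degenerate || !fit$converged || anyNA(fit$vcov)) return(bad)
  gi <- grep("^gamma", names(fit$theta))
  g <- fit$theta[gi]
  vg <- fit$vcov[gi, gi, drop = FALSE]
  qf <- tryCatch(drop(crossprod(g, solve(vg, g))), error = function(e) NA_real_)
  if (!is.finite(qf) || qf < 0) return(bad)
  list(statistic = qf, df = k,
       p_value = stats::pchisq(qf, df = k, lower.tail = FALSE),
       status = "ok")
}

#' @export
print.ql_fit <- function(x, ...) {
  cat(sprintf("ql_fit (%s, k = %d): %s after %d iterations\n", x$mode, x$k,
              if (x$degenerate) "degenerate" else if (x$converged) "converged" else "not converged",
              x$n_iter))
  est <- cbind(estimate = x$theta, se = sqrt(diag(x$vcov)))
  print(round(est, 4))
  invisible(x)
}

#' Test one variant across its informative nuclear-family units
#'
#' Encodes transmissions for every offspring in the units, fits the
#' quasi-likelihood model against the prepared phenotype vectors and
#' returns the Wald test.  Variants with too few informative families are
#' flagged untested; fitting failures are flagged degenerate and never
#' raise (the genome scan must not stop on one SNP).
#'
#' @param fam_units result of \code{\link{informative_families}}.
#' @param phenotypes numeric matrix of prepared phenotype vectors
#'   (individuals x k) with offspring IDs as rownames.
#' @param mode,include_deterministic,clustered passed to
#'   \code{\link{ql_fit}}.
#' @return list (class \code{variant_result}) with \code{status}
#'   (\code{"ok"}, \code{"untested"} or \code{"degenerate"}),
#'   \code{n_informative_families}, \code{n_offspring_used},
#'   \code{statistic}, \code{df}, \code{p_value} and \code{diagnostics}.
#' @export
test_variant <- function(fam_units, phenotypes,
                         mode = c("both_parents", "het_only"),
                         include_deterministic = TRUE, clustered = TRUE) {
  mode <- match.arg(mode)
  phenotypes <- as.matrix(phenotypes)
  k <- ncol(phenotypes)
  base <- list(status = "untested",
               n_informative_families = fam_units$n_informative,
               n_offspring_used = 0L,
               statistic = NA_real_, df = k, p_value = NA_real_,
               diagnostics = NULL)
  class(base) <- "variant_result"
  if (!fam_units$testable) return(base)

  fa <- mo <- ch <- integer(0); ids <- character(0); fam <- character(0)
  for (u in fam_units$units) {
    keep <- u$offspring_ids %in% rownames(phenotypes)
    if (!any(keep)) next
    m <- sum(keep)
    fa <- c(fa, rep(u$father_dosage, m)); mo <- c(mo, rep(u$mother_dosage, m))
    ch <- c(ch, u$offspring_dosage[keep]); ids <- c(ids, u$offspring_ids[keep])
    fam <- c(fam, rep(u$family_id, m))
  }
  if (!length(ids)) return(base)
  enc <- encode_transmissions(fa, mo, ch)
  ok <- enc$valid
  enc <- enc[ok, , drop = FALSE]
  y <- phenotypes[ids[ok], , drop = FALSE]
  fam <- fam[ok]

  fit <- tryCatch(
    ql_fit(enc, y, mode = mode, include_deterministic = include_deterministic,
           family = fam, clustered = clustered),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    base$status <- "degenerate"
    base$diagnostics <- list(error = conditionMessage(fit))
    return(base)
  }
  wt <- wald_test(fit)
  base$status <- wt$status
  base$n_offspring_used <- fit$n_offspring_used
  base$statistic <- wt$statistic
  base$df <- wt$df
  base$p_value <- wt$p_value
  base$diagnostics <- as.list(fit$counts)
  base$fit <- fit
  base
}
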