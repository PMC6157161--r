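# Independent oracles used across the suite.  Each is deliberately written
# by a different route than the implementation it checks.

# Transmission oracle: enumerate all parental gamete pairs.  A dosage-d
# parent carries d copies of the minor allele; each of the two alleles is
# transmitted with probability 1/2.  Conditional on the child dosage, a
# parent's transmission indicator is determined iff it takes the same value
# in every consistent gamete pair.
gamete_oracle <- function(father, mother, child) {
  gametes <- function(d) switch(as.character(d),
                                "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L))
  pairs <- expand.grid(tf = gametes(father), tm = gametes(mother))
  ok <- pairs$tf + pairs$tm == child
  if (!any(ok)) return(list(consistent = FALSE))
  het <- if (father == 1L) "father" else "mother"
  z_vals <- unique(if (het == "father") pairs$tf[ok] else pairs$tm[ok])
  w_vals <- unique(if (het == "father") pairs$tm[ok] else pairs$tf[ok])
  list(consistent = TRUE, het_parent = het,
       z = if (length(z_vals) == 1L) z_vals else NA_integer_,
       w = if (length(w_vals) == 1L) w_vals else NA_integer_,
       ambiguous = length(z_vals) > 1L)
}

# Brute-force BH step-up: literal definition, including the q-value as the
# running minimum of (m/j) p_(j).
bh_oracle <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- ps <= level * seq_len(m) / m
  kmax <- if (any(crit)) max(which(crit)) else 0L
  reject_sorted <- seq_len(m) <= kmax
  q_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m); reject <- logical(m)
  q[o] <- q_sorted; reject[o] <- reject_sorted
  list(q = q, reject = reject)
}

# PC1 oracle by SVD of the centered matrix (different decomposition route
# from the implementation's eigen on the covariance), with the same sign
# convention applied to the right singular vector.
pc1_oracle <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc)
  v <- sv$v[, 1L]
  s <- sum(v)
  if (s < 0 || (s == 0 && v[1L] < 0)) v <- -v
  drop(xc %*% v)
}

# Closed-form ML for bivariate normal with a monotone missingness pattern
# (variable 1 complete, variable 2 missing on a subset): factored
# likelihood / regression estimates.
monotone_mvn_oracle <- function(y) {
  stopifnot(ncol(y) == 2L, !anyNA(y[, 1L]))
  n <- nrow(y)
  mu1 <- mean(y[, 1L])
  s11 <- mean((y[, 1L] - mu1)^2)
  cc <- !is.na(y[, 2L])
  x <- y[cc, 1L]; z <- y[cc, 2L]
  beta <- sum((x - mean(x)) * (z - mean(z))) / sum((x - mean(x))^2)
  alpha <- mean(z) - beta * mean(x)
  s22_res <- mean((z - alpha - beta * x)^2)
  mu2 <- alpha + beta * mu1
  s12 <- beta * s11
  s22 <- s22_res + beta^2 * s11
  list(mean = c(mu1, mu2),
       covariance = matrix(c(s11, s12, s12, s22), 2L))
}

# Write a small pedigree/VCF fixture pair for ingestion tests.
write_trio_vcf <- function(path, samples, gt_rows, ids = NULL,
                           alts = NULL) {
  nv <- length(gt_rows)
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(nv))
  if (is.null(alts)) alts <- rep("G", nv)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_len(nv), function(i) {
      paste(c("1", 1000 + i, ids[i], "A", alts[i], ".", "PASS", ".", "GT",
              gt_rows[[i]]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}

write_ped_lines <- function(path, lines) {
  writeLines(lines, path)
  path
}

# Synthetic het-only transmission observations for fit-equivalence tests:
# unambiguous Z data (other parent homozygous reference).
make_z_obs <- function(n, alpha, gamma, seed) {
  set.seed(seed)
  k <- length(gamma)
  y <- matrix(rnorm(n * k), n, k)
  z <- rbinom(n, 1L, 1 / (1 + exp(-(alpha + drop(y %*% gamma)))))
  obs <- encode_transmissions(rep(1L, n), rep(0L, n), z)
  list(obs = obs, y = y, z = z)
}
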