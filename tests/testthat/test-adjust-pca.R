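test_that("covariate adjustment regresses out founder-fitted structure", {
  set.seed(601)
  n <- 117; ids <- sprintf("I%d", 1:(n + 50))
  founders <- ids[1:n]
  covar <- matrix(rnorm((n + 50) * 4, 4, 0.5), n + 50, 4,
                  dimnames = list(ids, paste0("H", 1:4)))
  # trait exactly linear in covariates: founder residuals must vanish
  beta <- c(0.2, -0.1, 0.4, 0.05)
  trait <- 1.5 + covar %*% matrix(rep(beta, 4), 4) +
    matrix(0, n + 50, 4)
  dimnames(trait) <- list(ids, paste0("T", 1:4))
  res <- adjust_for_covariate(trait, covar, founders)
  expect_equal(max(abs(res[founders, ])), 0, tolerance = 1e-10)

  # noisy same-time coefficient is recovered near 0.8 at founder n = 117
  reps <- vapply(1:30, function(r) {
    set.seed(700 + r)
    cv <- matrix(rnorm(n * 4, 4, 0.5), n, 4)
    tr <- 0.8 * cv + matrix(rnorm(n * 4, sd = 0.3), n, 4)
    rownames(cv) <- rownames(tr) <- sprintf("F%d", 1:n)
    xf <- cbind(1, cv)
    qr.solve(xf, tr[, 1L])[2L]  # same-time coefficient, time point 1
  }, 0)
  expect_equal(mean(reps), 0.8, tolerance = 3 * sd(reps) / sqrt(30))
})

test_that("rank-deficient covariate designs are rejected", {
  ids <- sprintf("I%d", 1:20)
  covar <- matrix(0, 20, 4, dimnames = list(ids, NULL))
  trait <- matrix(rnorm(80), 20, 4, dimnames = list(ids, NULL))
  expect_error(adjust_for_covariate(trait, covar, ids), "rank-deficient")
})

test_that("PC1 honours known eigenstructure and the sign convention", {
  set.seed(602)
  x <- rnorm(40, 2, 1.3)
  # identical columns: loading (1,1)/sqrt(2), scores sqrt(2) * centered x
  expect_equal(first_principal_component(cbind(x, x)),
               sqrt(2) * (x - mean(x)), tolerance = 1e-10)
  # exactly uncorrelated columns with variances 4 and 1: the dominant
  # axis is column 1 and scores are its centered values
  a <- 2 * scale(rnorm(40))[, 1]
  b <- unname(scale(resid(lm(rnorm(40) ~ a)))[, 1])
  sc <- first_principal_component(cbind(a + 10, b))
  expect_equal(sc, a, tolerance = 1e-10)
  expect_error(first_principal_component(matrix(1, 5, 2)), "zero covariance")
})

test_that("PC1 matches an SVD oracle, is centered, and carries the top eigenvalue", {
  for (seed in c(603, 604, 605)) {
    set.seed(seed)
    x <- matrix(rnorm(100), 50, 2) %*% matrix(c(1, 0.6, 0, 1), 2)
    sc <- first_principal_component(x)
    expect_equal(sc, pc1_oracle(x), tolerance = 1e-10)
    expect_equal(mean(sc), 0, tolerance = 1e-10)
    lam1 <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values[1L]
    expect_equal(var(sc), lam1, tolerance = 1e-10)
  }
})

test_that("definitions compose: MTBAT equals (TBATPre, TBATPost)", {
  set.seed(606)
  tr <- matrix(rnorm(200, 4.5, 0.5), 50, 4,
               dimnames = list(sprintf("I%d", 1:50), paste0("TG", 1:4)))
  m <- build_phenotypes("MTBAT", tr)
  expect_equal(dim(m), c(50L, 2L))
  expect_equal(m[, 1L], build_phenotypes("TBATPre", tr)[, 1L])
  expect_equal(m[, 2L], build_phenotypes("TBATPost", tr)[, 1L])
  # equal T1 = T2 degenerates to centered T1 (up to the sqrt(2) loading)
  tr2 <- tr; tr2[, 2L] <- tr2[, 1L]
  expect_equal(build_phenotypes("TBATPre", tr2)[, 1L],
               sqrt(2) * (tr2[, 1L] - mean(tr2[, 1L])), tolerance = 1e-10)
  expect_error(build_phenotypes("NotADef", tr), "unknown phenotype definition")
  expect_error(build_phenotypes("MTBATAdj", tr), "trait_adjusted")
})

test_that("definition metadata is consistent", {
  for (nm in phenotype_definition_names()) {
    d <- phenotype_definition(nm)
    expect_equal(d$k, length(d$blocks))
    expect_equal(d$adjusted, grepl("Adj$", nm))
    expect_equal(d$k, if (grepl("^MTBAT", nm)) 2L else 1L)
  }
})
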