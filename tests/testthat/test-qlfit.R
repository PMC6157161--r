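test_that("het-only fits equal logistic maximum likelihood (canonical-link identity)", {
  for (seed in c(701, 702, 703)) {
    for (k in 1:2) {
      dat <- make_z_obs(n = 300, alpha = 0.2,
                        gamma = rep(0.4, k), seed = seed + 10 * k)
      fit <- ql_fit(dat$obs, dat$y, mode = "het_only")
      ref <- glm(dat$z ~ dat$y, family = binomial())
      expect_true(fit$converged)
      expect_equal(unname(fit$theta), unname(coef(ref)), tolerance = 1e-6)
    }
  }
})

test_that("degenerate inputs are rejected or flagged, never mis-fitted", {
  dat <- make_z_obs(150, 0, 0.3, seed = 704)
  # constant phenotype column
  y0 <- cbind(dat$y, 0)
  expect_error(ql_fit(dat$obs, y0, mode = "het_only"), "constant phenotype")
  # complete separation: all transmissions identical
  obs1 <- encode_transmissions(rep(1L, 60), rep(0L, 60), rep(1L, 60))
  fit <- suppressWarnings(ql_fit(obs1, matrix(rnorm(60)), mode = "het_only"))
  expect_true(fit$degenerate)
  expect_equal(wald_test(fit)$status, "degenerate")
  # too few contributions
  obs2 <- encode_transmissions(1L, 0L, 1L)
  expect_error(ql_fit(obs2, matrix(rnorm(1))), "too few")
})

test_that("under fair Mendelian transmission both intercepts estimate logit(1/2)", {
  # null data: transmissions are fair coin flips independent of phenotype,
  # so alpha1 and alpha2 should both sit near 0 (expit(0) = 1/2)
  set.seed(705)
  n <- 4000
  fa <- rep(1L, n)
  mo <- sample(c(0L, 1L, 2L), n, replace = TRUE)
  ch <- rbinom(n, 1, fa / 2) + rbinom(n, 1, mo / 2)
  enc <- encode_transmissions(fa, mo, ch)
  y <- matrix(rnorm(n), ncol = 1)
  fit <- ql_fit(enc, y, include_deterministic = FALSE,
                family = seq_len(n))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$theta[["alpha1"]]), 3 * se[1L])
  expect_lt(abs(fit$theta[["alpha2"]]), 3 * se[2L])
  expect_lt(abs(fit$theta[["gamma1"]]), 3 * se[3L])
})

test_that("the Wald statistic is the quadratic form in the gamma block", {
  # k = 1: 0.5^2 / 0.0651 sits just above the 5% chi-square(1) point
  fit1 <- structure(list(theta = c(alpha1 = 0, gamma1 = 0.5),
                         vcov = diag(c(0.1, 0.0651)), k = 1L,
                         converged = TRUE, degenerate = FALSE),
                    class = "ql_fit")
  wt <- wald_test(fit1)
  expect_equal(wt$statistic, 0.25 / 0.0651, tolerance = 1e-12)
  expect_equal(wt$df, 1L)
  expect_equal(wt$p_value, 0.05, tolerance = 0.002)

  # gamma = 0 gives statistic 0, p = 1
  fit0 <- structure(list(theta = c(alpha1 = 0.3, gamma1 = 0),
                         vcov = diag(2), k = 1L,
                         converged = TRUE, degenerate = FALSE),
                    class = "ql_fit")
  expect_equal(wald_test(fit0)$statistic, 0)
  expect_equal(wald_test(fit0)$p_value, 1)

  # k = 2: explicit 2x2 inversion agrees with the linear-solve route
  set.seed(706)
  v <- crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2)
  g <- c(0.3, -0.2)
  fit2 <- structure(list(theta = c(alpha1 = 0, alpha2 = 0,
                                   gamma1 = g[1], gamma2 = g[2]),
                         vcov = rbind(cbind(diag(2), matrix(0, 2, 2)),
                                      cbind(matrix(0, 2, 2), v)),
                         k = 2L, converged = TRUE, degenerate = FALSE),
                    class = "ql_fit")
  vinv <- matrix(c(v[2, 2], -v[1, 2], -v[2, 1], v[1, 1]), 2) /
    (v[1, 1] * v[2, 2] - v[1, 2] * v[2, 1])
  expect_equal(wald_test(fit2)$statistic, drop(t(g) %*% vinv %*% g),
               tolerance = 1e-10)
})

test_that("swapping parental labels leaves the Wald statistic unchanged", {
  set.seed(707)
  n <- 240
  fa <- sample(0:2, n, replace = TRUE)
  mo <- sample(0:2, n, replace = TRUE)
  keep <- fa == 1L | mo == 1L
  fa <- fa[keep]; mo <- mo[keep]
  ch <- rbinom(sum(keep), 1, fa / 2) + rbinom(sum(keep), 1, mo / 2)
  y <- matrix(rnorm(sum(keep), sd = 0.8), ncol = 1)
  fam <- seq_along(ch)
  enc1 <- encode_transmissions(fa, mo, ch)
  enc2 <- encode_transmissions(mo, fa, ch)
  f1 <- ql_fit(enc1, y, family = fam)
  f2 <- ql_fit(enc2, y, family = fam)
  expect_equal(wald_test(f1)$statistic, wald_test(f2)$statistic,
               tolerance = 1e-8)
})

test_that("test_variant respects the informative-family boundary and never raises", {
  set.seed(708)
  mk_units <- function(n_fam) {
    units <- lapply(seq_len(n_fam), function(i) {
      list(family_id = sprintf("F%d", i), father_dosage = 1L,
           mother_dosage = sample(0:1, 1L),
           offspring_ids = sprintf("F%d_C1", i),
           offspring_dosage = sample(0:1, 1L))
    })
    list(units = units, n_informative = n_fam,
         testable = n_fam >= 21L, n_mendel_dropped = 0L)
  }
  ids <- sprintf("F%d_C1", 1:30)
  phen <- matrix(rnorm(30), dimnames = list(ids, "PC1"))
  expect_equal(test_variant(mk_units(20L), phen)$status, "untested")
  vr <- test_variant(mk_units(25L), phen)
  expect_true(vr$status %in% c("ok", "degenerate"))
  if (vr$status == "ok") {
    expect_true(vr$p_value >= 0 && vr$p_value <= 1)
    expect_equal(vr$df, 1L)
  }
  # constant phenotypes are caught and flagged, not raised
  phen0 <- matrix(0, 30, 1, dimnames = list(ids, "PC1"))
  expect_equal(test_variant(mk_units(25L), phen0)$status, "degenerate")
})
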