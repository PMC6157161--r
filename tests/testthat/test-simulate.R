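test_that("identical seeds give byte-identical output files", {
  cfg <- sim_config(n_families = 20, n_variants = 4, seed = 901)
  d1 <- tempfile("s1"); d2 <- tempfile("s2")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("families.ped", "genotypes.vcf", "phenotypes.tsv",
              "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("zero missingness yields a complete phenotype table", {
  cfg <- sim_config(n_families = 15,
                    missing_rates = list(trait = rep(0, 4),
                                         covariate = rep(0, 4)),
                    seed = 902)
  out <- simulate_dataset(cfg, tempfile())
  ph <- read_phenotypes(out$phenotypes)
  expect_false(anyNA(ph$TG))
  expect_false(anyNA(ph$HDL))
})

test_that("founder genotypes follow HWE and offspring obey Mendel", {
  cfg <- sim_config(n_families = 200, n_variants = 3, maf = 0.3, seed = 903)
  dr <- sim_draw(cfg)
  fd <- dr$dosage[dr$is_founder, ]
  n <- nrow(fd)
  # allele frequency within binomial error of the target
  for (v in 1:3) {
    phat <- sum(fd[, v]) / (2 * n)
    expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * n)))
    # genotype frequencies near p^2, 2pq, q^2
    counts <- tabulate(fd[, v] + 1L, 3L) / n
    hwe <- c(0.49, 0.42, 0.09)
    expect_true(all(abs(counts - hwe) < 4 * sqrt(hwe * (1 - hwe) / n)))
  }
  # exhaustive Mendelian consistency of offspring dosages
  nf <- length(dr$n_offspring)
  fa <- dr$dosage[seq_len(nf), , drop = FALSE]
  mo <- dr$dosage[nf + seq_len(nf), , drop = FALSE]
  kid <- dr$dosage[!dr$is_founder, , drop = FALSE]
  kf <- dr$offspring_family
  lo <- function(d) (d == 2L) + 0L
  hi <- function(d) (d >= 1L) + 0L
  expect_true(all(kid >= lo(fa[kf, ]) + lo(mo[kf, ])))
  expect_true(all(kid <= hi(fa[kf, ]) + hi(mo[kf, ])))
})

test_that("empirical missingness tracks the configured per-column rates", {
  cfg <- sim_config(n_families = 200, seed = 904)
  dr <- sim_draw(cfg)
  n <- nrow(dr$trait_raw)
  for (j in 1:4) {
    rate <- cfg$missing_rates$trait[j]
    emp <- mean(is.na(dr$trait_raw[, j]))
    expect_lt(abs(emp - rate), 3 * sqrt(max(rate * (1 - rate), 1e-4) / n) + 1e-9)
  }
})

test_that("the truth record reproduces every phenotype cell", {
  cfg <- sim_config(n_families = 10, seed = 905)
  out <- simulate_dataset(cfg, tempfile())
  truth <- jsonlite::read_json(out$truth, simplifyVector = TRUE)
  ph <- read_phenotypes(out$phenotypes)
  recomputed <- exp(truth$trait_latent)
  recomputed[truth$trait_missing] <- NA
  expect_equal(unname(ph$TG), unname(recomputed), tolerance = 1e-15)
  expect_equal(truth$config$seed, 905)
})

test_that("infeasible or incomplete configurations are rejected", {
  expect_error(sim_config(n_families = 10), "seed")
  expect_error(sim_config(rho = 1.2, seed = 1), "correlation")
  expect_error(sim_config(maf = 0.7, seed = 1))
  expect_error(sim_config(missing_rates = list(trait = rep(1, 4),
                                               covariate = rep(0, 4)),
                          seed = 1))
})

test_that("null statistics harness is seed-reproducible and well-behaved", {
  cfg <- calibration_config(seed = 906, n_families = 60)
  a <- simulate_null_statistics(cfg, 25)
  b <- simulate_null_statistics(cfg, 25)
  expect_identical(a$statistics, b$statistics)
  expect_true(all(a$p_values >= 0 & a$p_values <= 1))
  expect_equal(a$df, 2L)
})

test_that("power is monotone in the effect size (small-scale check)", {
  cfg <- calibration_config(seed = 907, n_families = 120)
  pw <- simulate_power_curve(cfg, a_grid = c(0, 0.25), n_replicates = 40,
                             modes = "both_parents")
  expect_lt(pw$power[pw$a == 0], 0.25)
  expect_gt(pw$power[pw$a == 0.25], pw$power[pw$a == 0])
})
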