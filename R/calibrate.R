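#' Configuration for Monte-Carlo calibration and power studies
#'
#' A \code{\link{sim_config}} preset for the replicate harnesses: one
#' variant, complete phenotypes (the harness targets the sampling
#' distribution of the test statistic; the imputation stage has its own
#' oracle tests), and otherwise the default study conditions (200
#' families, 2-8 offspring each, MAF 0.3).
#'
#' @param seed master seed.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
calibration_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(n_variants = 1L,
                   missing_rates = list(trait = rep(0, 4),
                                        covariate = rep(0, 4)),
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# one replicate: draw a dataset, build the phenotype scores, test variant 1
sim_replicate_test <- function(config, mode = "both_parents",
                               definition = "MTBAT",
                               include_deterministic = TRUE,
                               min_informative = 21L) {
  dr <- sim_draw(config)
  if (any(dr$trait_miss) || any(dr$cov_miss)) {
    stop("replicate harness expects complete phenotypes (use calibration_config)")
  }
  trait_log <- log(dr$trait_raw)
  def <- phenotype_definition(definition)
  trait_adj <- NULL
  if (def$adjusted) {
    trait_adj <- adjust_for_covariate(trait_log, log(dr$cov_raw),
                                      dr$ids[dr$is_founder])
  }
  scores <- build_phenotypes(def, trait_log, trait_adj)

  nf <- length(dr$n_offspring)
  fa_d <- dr$dosage[seq_len(nf), 1L]
  mo_d <- dr$dosage[nf + seq_len(nf), 1L]
  kid_rows <- which(!dr$is_founder)
  kf <- dr$offspring_family

  informative <- fa_d == 1L | mo_d == 1L
  n_inf <- sum(informative)
  if (n_inf < min_informative) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                status = "untested", n_informative = n_inf))
  }
  keep <- informative[kf]
  enc <- encode_transmissions(fa_d[kf][keep], mo_d[kf][keep],
                              dr$dosage[kid_rows, 1L][keep])
  y <- scores[kid_rows, , drop = FALSE][keep, , drop = FALSE]
  fit <- tryCatch(
    ql_fit(enc, y, mode = mode,
           include_deterministic = include_deterministic,
           family = kf[keep]),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                status = "degenerate", n_informative = n_inf))
  }
  wt <- wald_test(fit)
  list(statistic = wt$statistic, p_value = wt$p_value, status = wt$status,
       n_informative = n_inf)
}

#' Null distribution of the transmission test by Monte Carlo
#'
#' Runs the in-memory pipeline on one variant per replicate under the
#' configured generative model and collects the Wald statistics and
#' p-values.  Reports the empirical size at the 0.05 level with a 99%
#' binomial confidence interval and a KS comparison of the statistics to
#' the reference chi-squared distribution.  Replicate seeds are named
#' substreams of the config seed, so results are reproducible and
#' replicate r is the same draw in every scenario sharing the master seed
#' (which pairs scenarios in power comparisons).
#'
#' @param config a \code{sim_config} with \code{a = 0} for null studies
#'   (stratification scenarios keep \code{a = 0} too: any excess
#'   rejection there is confounding, not signal).
#' @param n_replicates number of Monte-Carlo replicates.
#' @param mode,definition,include_deterministic passed to the per-variant
#'   test (defaults: both parents, bivariate MTBAT phenotype).
#' @param level nominal test level for the size report (default 0.05).
#' @return list with \code{statistics}, \code{p_values} (length =
#'   usable replicates), \code{size}, \code{size_ci} (99% binomial),
#'   \code{ks_p} (statistics vs chi-squared k df), \code{df},
#'   \code{n_excluded} (untested or degenerate replicates).
#' @export
simulate_null_statistics <- function(config, n_replicates,
                                     mode = "both_parents",
                                     definition = "MTBAT",
                                     include_deterministic = TRUE,
                                     level = 0.05) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1L)
  k <- phenotype_definition(definition)$k
  stat <- p <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, "replicate", r)
    out <- sim_replicate_test(cfg, mode = mode, definition = definition,
                              include_deterministic = include_deterministic)
    if (out$status == "ok") { stat[r] <- out$statistic; p[r] <- out$p_value }
  }
  ok <- !is.na(p)
  n_ok <- sum(ok)
  size <- mean(p[ok] < level)
  se <- sqrt(size * (1 - size) / n_ok)
  ks <- suppressWarnings(stats::ks.test(stat[ok], "pchisq", df = k))
  list(statistics = stat[ok], p_values = p[ok], size = size,
       size_ci = c(size - 2.576 * se, size + 2.576 * se),
       ks_p = ks$p.value, df = k, n_excluded = n_replicates - n_ok)
}

#' Monte-Carlo power of the transmission test over a grid of effect sizes
#'
#' Power is the fraction of usable replicates with p below \code{level}.
#' The replicate substreams are shared across grid cells and modes, so the
#' both-parents versus heterozygous-parent-only comparison is paired.
#'
#' @param config base \code{sim_config} (its \code{a} is overridden by the
#'   grid).
#' @param a_grid numeric vector of genetic effect sizes (log-scale trait
#'   units per minor allele); include 0 to read off the size.
#' @param n_replicates replicates per cell.
#' @param modes character vector of fitting modes (default both).
#' @param definition phenotype definition (default MTBAT).
#' @param level rejection level (default 0.05).
#' @return data.frame with columns \code{a}, \code{mode}, \code{power},
#'   \code{mcse} (binomial Monte-Carlo SE), \code{n_ok}.
#' @export
simulate_power_curve <- function(config, a_grid, n_replicates,
                                 modes = c("both_parents", "het_only"),
                                 definition = "MTBAT", level = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (a in a_grid) {
    for (mode in modes) {
      hits <- 0L; n_ok <- 0L
      for (r in seq_len(n_replicates)) {
        cfg <- config
        cfg$a <- a
        cfg$seed <- substream_seed(config$seed, "replicate", r)
        out <- sim_replicate_test(cfg, mode = mode, definition = definition)
        if (out$status == "ok") {
          n_ok <- n_ok + 1L
          hits <- hits + (out$p_value < level)
        }
      }
      pw <- hits / n_ok
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, mode = mode, power = pw,
        mcse = sqrt(pw * (1 - pw) / n_ok), n_ok = n_ok,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
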