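#' Simulation configuration for synthetic nuclear-family datasets
#'
#' Defines the generative model the package uses for calibration and power
#' studies: nuclear families with genotyped parents drawn under
#' Hardy-Weinberg equilibrium, offspring genotypes by fair Mendelian
#' gamete draws, and two correlated log-normal longitudinal traits at four
#' time points with a treatment shift on time points 3-4 (emulating a
#' lipid-lowering drug administered between visits 2 and 3), per-cell
#' missingness, and an optional confounded two-subpopulation
#' stratification scenario.
#'
#' @param n_families number of nuclear families (default 200).
#' @param offspring_min,offspring_max offspring per family drawn uniformly
#'   on this range (default 2..8, expected 5 per family, so about 1000
#'   offspring at the default family count).
#' @param n_variants number of independent biallelic SNPs (default 1).
#' @param maf minor-allele frequency for parent draws (default 0.3).
#' @param a genetic effect: log-scale trait units per minor allele carried
#'   (applies to every time point and every individual; default 0 = null).
#' @param d treatment effect: log-scale shift applied at time points 3-4
#'   (default -0.3, a lowering drug).
#' @param mu log-scale trait means per time point (default rep(4.7, 4),
#'   about 110 raw units).
#' @param sigma residual log-scale SD per time point (default 0.5).
#' @param rho exchangeable residual correlation across time points
#'   (default 0.5).
#' @param family_sd SD of the shared offspring random intercept (founders
#'   receive independent intercepts of the same SD; default 0.3).
#' @param b coupling of the trait to the (centered) covariate trait at the
#'   same time point (default -0.4, traits negatively related).
#' @param cov_mu,cov_sigma,cov_rho,cov_family_sd same-role parameters for
#'   the covariate trait (defaults log(50) scale: rep(3.9, 4), 0.25, 0.5,
#'   0.15).
#' @param missing_rates list with numeric length-4 vectors \code{trait}
#'   and \code{covariate}: per-time-point independent missingness
#'   probabilities.  Defaults mirror the heaviest-at-visit-3 availability
#'   pattern of the motivating study (trait: 0.27, 0.002, 0.44, 0.26;
#'   covariate: 0.27, 0.001, 0.28, 0.22).
#' @param stratification list: \code{enabled}, \code{maf} (length 2,
#'   per-subpopulation MAF), \code{delta} (log-scale trait mean shift in
#'   subpopulation 2), \code{prop} (probability a family belongs to
#'   subpopulation 1).  Defaults off; when enabled the MAF difference and
#'   the mean shift are coupled so naive association is confounded.
#' @param seed master seed (mandatory); named substreams for genotypes,
#'   phenotypes and missingness are derived from it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 200L, offspring_min = 2L,
                       offspring_max = 8L, n_variants = 1L, maf = 0.3,
                       a = 0, d = -0.3, mu = rep(4.7, 4), sigma = 0.5,
                       rho = 0.5, family_sd = 0.3, b = -0.4,
                       cov_mu = rep(3.9, 4), cov_sigma = 0.25,
                       cov_rho = 0.5, cov_family_sd = 0.15,
                       missing_rates = list(
                         trait = c(0.27, 0.002, 0.44, 0.26),
                         covariate = c(0.27, 0.001, 0.28, 0.22)),
                       stratification = list(enabled = FALSE,
                                             maf = c(0.1, 0.4),
                                             delta = 0.6, prop = 0.5),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_families >= 1L, offspring_min >= 1L,
            offspring_max >= offspring_min, n_variants >= 1L,
            maf > 0, maf <= 0.5, length(mu) == 4L, length(cov_mu) == 4L,
            sigma > 0, cov_sigma > 0,
            length(missing_rates$trait) == 4L,
            length(missing_rates$covariate) == 4L,
            all(unlist(missing_rates) >= 0), all(unlist(missing_rates) < 1))
  if (rho < 0 || rho >= 1 || cov_rho < 0 || cov_rho >= 1) {
    stop("exchangeable correlation must lie in [0, 1) for a valid covariance")
  }
  if (isTRUE(stratification$enabled)) {
    stopifnot(length(stratification$maf) == 2L,
              all(stratification$maf > 0), all(stratification$maf <= 0.5),
              stratification$prop > 0, stratification$prop < 1)
  }
  structure(list(
    n_families = as.integer(n_families),
    offspring_min = as.integer(offspring_min),
    offspring_max = as.integer(offspring_max),
    n_variants = as.integer(n_variants), maf = maf, a = a, d = d,
    mu = mu, sigma = sigma, rho = rho, family_sd = family_sd, b = b,
    cov_mu = cov_mu, cov_sigma = cov_sigma, cov_rho = cov_rho,
    cov_family_sd = cov_family_sd, missing_rates = missing_rates,
    stratification = stratification, seed = as.integer(seed)
  ), class = "sim_config")
}

# exchangeable-correlation noise: sqrt(rho) * shared + sqrt(1-rho) * own
exch_noise <- function(n, p, sigma, rho) {
  shared <- stats::rnorm(n)
  sigma * (sqrt(rho) * matrix(shared, n, p) +
           sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p))
}

#' Draw one synthetic dataset in memory
#'
#' The in-memory core behind \code{\link{simulate_dataset}} and the
#' calibration harnesses.  Parents are drawn under Hardy-Weinberg at the
#' configured MAF (per subpopulation when stratified); each parent
#' transmits its minor allele to each offspring independently with
#' probability dosage/2; the log-scale traits follow the model described
#' in \code{\link{sim_config}}.
#'
#' @param config a \code{sim_config}.
#' @return list with pedigree fields (\code{ids}, \code{family},
#'   \code{father_id}, \code{mother_id}, \code{is_founder},
#'   \code{subpop}), \code{dosage} (individuals x variants),
#'   \code{trait_latent} and \code{cov_latent} (log-scale, individuals x
#'   4), missingness masks \code{trait_miss}/\code{cov_miss}, and raw
#'   matrices \code{trait_raw}/\code{cov_raw} with NA at masked cells.
#' @export
sim_draw <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  nf <- cfg$n_families

  set.seed(substream_seed(cfg$seed, "structure"))
  n_off <- sample(seq.int(cfg$offspring_min, cfg$offspring_max), nf,
                  replace = TRUE)
  strat <- isTRUE(cfg$stratification$enabled)
  subpop_fam <- if (strat) {
    1L + (stats::runif(nf) >= cfg$stratification$prop)
  } else rep(1L, nf)

  fam_lab <- sprintf("F%04d", seq_len(nf))
  fa_id <- paste0(fam_lab, "_P1")
  mo_id <- paste0(fam_lab, "_P2")
  kid_fam <- rep(seq_len(nf), n_off)
  kid_id <- unlist(lapply(seq_len(nf), function(i) {
    sprintf("%s_C%d", fam_lab[i], seq_len(n_off[i]))
  }))
  n_kid <- length(kid_id)
  ids <- c(fa_id, mo_id, kid_id)
  family <- c(fam_lab, fam_lab, fam_lab[kid_fam])
  father_id <- c(rep(NA_character_, 2L * nf), fa_id[kid_fam])
  mother_id <- c(rep(NA_character_, 2L * nf), mo_id[kid_fam])
  is_founder <- c(rep(TRUE, 2L * nf), rep(FALSE, n_kid))
  subpop <- c(subpop_fam, subpop_fam, subpop_fam[kid_fam])

  set.seed(substream_seed(cfg$seed, "genotypes"))
  maf_fam <- if (strat) cfg$stratification$maf[subpop_fam] else rep(cfg$maf, nf)
  nv <- cfg$n_variants
  fa_d <- matrix(stats::rbinom(nf * nv, 2L, maf_fam), nf, nv)
  mo_d <- matrix(stats::rbinom(nf * nv, 2L, maf_fam), nf, nv)
  tf <- matrix(stats::rbinom(n_kid * nv, 1L, fa_d[kid_fam, , drop = FALSE] / 2),
               n_kid, nv)
  tm <- matrix(stats::rbinom(n_kid * nv, 1L, mo_d[kid_fam, , drop = FALSE] / 2),
               n_kid, nv)
  kid_d <- tf + tm
  dosage <- rbind(fa_d, mo_d, kid_d)
  rownames(dosage) <- ids
  colnames(dosage) <- sprintf("snp%04d", seq_len(nv))

  set.seed(substream_seed(cfg$seed, "phenotypes"))
  n_ind <- length(ids)
  # shared intercept for offspring of a family; independent for founders
  fam_eff <- stats::rnorm(nf, sd = cfg$family_sd)
  fam_eff_cov <- stats::rnorm(nf, sd = cfg$cov_family_sd)
  ind_eff <- c(stats::rnorm(2L * nf, sd = cfg$family_sd), fam_eff[kid_fam])
  ind_eff_cov <- c(stats::rnorm(2L * nf, sd = cfg$cov_family_sd),
                   fam_eff_cov[kid_fam])

  cov_latent <- matrix(cfg$cov_mu, n_ind, 4L, byrow = TRUE) + ind_eff_cov +
    exch_noise(n_ind, 4L, cfg$cov_sigma, cfg$cov_rho)
  causal <- dosage[, 1L]
  shift <- if (strat) cfg$stratification$delta * (subpop == 2L) else 0
  trait_latent <- matrix(cfg$mu, n_ind, 4L, byrow = TRUE) +
    cfg$d * matrix(c(0, 0, 1, 1), n_ind, 4L, byrow = TRUE) +
    cfg$a * causal + shift + ind_eff +
    cfg$b * sweep(cov_latent, 2L, cfg$cov_mu) +
    exch_noise(n_ind, 4L, cfg$sigma, cfg$rho)
  dimnames(trait_latent) <- list(ids, paste0("TG", 1:4))
  dimnames(cov_latent) <- list(ids, paste0("HDL", 1:4))

  set.seed(substream_seed(cfg$seed, "missingness"))
  trait_miss <- matrix(stats::runif(n_ind * 4L), n_ind, 4L) <
    matrix(cfg$missing_rates$trait, n_ind, 4L, byrow = TRUE)
  cov_miss <- matrix(stats::runif(n_ind * 4L), n_ind, 4L) <
    matrix(cfg$missing_rates$covariate, n_ind, 4L, byrow = TRUE)

  trait_raw <- exp(trait_latent); trait_raw[trait_miss] <- NA
  cov_raw <- exp(cov_latent); cov_raw[cov_miss] <- NA

  list(ids = ids, family = family, father_id = father_id,
       mother_id = mother_id, is_founder = is_founder, subpop = subpop,
       n_offspring = n_off, offspring_family = kid_fam, dosage = dosage,
       trait_latent = trait_latent, cov_latent = cov_latent,
       trait_miss = trait_miss, cov_miss = cov_miss,
       trait_raw = trait_raw, cov_raw = cov_raw)
}

#' Write a synthetic dataset to PED / VCF / TSV files plus a truth record
#'
#' Emits exactly the formats the ingestion layer consumes: a whitespace
#' pedigree file, a VCF v4.2 with GT fields for every pedigree member, a
#' wide phenotype TSV (TG1..TG4, HDL1..HDL4, NA = missing) and a JSON
#' truth record holding every parameter and each individual's latent
#' log-scale values, from which every phenotype cell can be recomputed
#' exactly.  Identical seeds yield byte-identical files.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the four file paths and the in-memory
#'   draw.
#' @export
simulate_dataset <- function(config, out_dir) {
  dr <- sim_draw(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ped_path <- file.path(out_dir, "families.ped")
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  phen_path <- file.path(out_dir, "phenotypes.tsv")
  truth_path <- file.path(out_dir, "truth.json")

  ped_lines <- sprintf("%s %s %s %s 0 -9", dr$family, dr$ids,
                       ifelse(is.na(dr$father_id), "0", dr$father_id),
                       ifelse(is.na(dr$mother_id), "0", dr$mother_id))
  writeLines(ped_lines, ped_path)

  write_sim_vcf(dr, vcf_path)

  phen <- cbind(dr$trait_raw, dr$cov_raw)
  cells <- matrix("NA", nrow(phen), ncol(phen))
  obs <- !is.na(phen)
  cells[obs] <- sprintf("%.17g", phen[obs])
  header <- paste(c("individual_id", colnames(phen)), collapse = "\t")
  body <- paste(dr$ids, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), phen_path)

  truth <- list(
    config = unclass(config),
    individuals = dr$ids, family = dr$family, subpop = dr$subpop,
    dosage = dr$dosage,
    trait_latent = dr$trait_latent, cov_latent = dr$cov_latent,
    trait_missing = dr$trait_miss, cov_missing = dr$cov_miss
  )
  # I(17) significant digits so every stored double round-trips exactly
  jsonlite::write_json(truth, truth_path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)

  invisible(list(pedigree = ped_path, vcf = vcf_path, phenotypes = phen_path,
                 truth = truth_path, draw = dr))
}

write_sim_vcf <- function(dr, path) {
  nv <- ncol(dr$dosage)
  chrom <- ((seq_len(nv) - 1L) %% 22L) + 1L
  pos <- 10000L + seq_len(nv) * 137L
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[dr$dosage + 1L], nrow(dr$dosage), nv)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=qltdt synthetic nuclear-family generator",
    paste0("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dr$ids), collapse = "\t"),
    vapply(seq_len(nv), function(v) {
      paste(c(chrom[v], pos[v], colnames(dr$dosage)[v], "A", "G", ".",
              "PASS", ".", "GT", gt[, v]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
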