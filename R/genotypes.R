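#' Read biallelic SNP genotypes from a VCF into minor-allele dosages
#'
#' Diploid GT fields are converted to counts of the minor allele, where
#' "minor" is decided per variant from the founder allele frequency: if the
#' ALT frequency among genotyped founders exceeds 0.5 the counted allele is
#' switched to REF (ties keep ALT).  Multi-allelic records are skipped with
#' a warning; samples absent from the pedigree are ignored.
#'
#' @param path path to a VCF (v4.x) file.
#' @param pedigree a \code{\link{read_pedigree}} result; sample IDs must
#'   intersect its individual IDs.
#' @return an object of class \code{genotype_matrix}: a list with
#'   \itemize{
#'     \item \code{dosage} integer matrix, individuals x variants, values
#'       0/1/2 or NA, counting minor alleles after orientation;
#'     \item \code{variants} data.frame with \code{variant_id},
#'       \code{chromosome}, \code{position}, \code{flipped};
#'     \item \code{individuals} character vector of row labels.
#'   }
#' @export
read_genotypes <- function(path, pedigree) {
  stopifnot(inherits(pedigree, "pedigree_table"))
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || !ncol(gt)) stop("malformed VCF: no GT sample data")
  samples <- colnames(gt)
  keep_samples <- samples %in% pedigree$individual_id
  if (!any(keep_samples)) stop("no overlap between VCF samples and pedigree individuals")

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, keep_samples, drop = FALSE]
  if (!nrow(fix)) stop("no biallelic records in VCF")

  alt_dose <- gt_to_alt_dosage(gt)        # variants x samples
  dosage <- t(alt_dose)                   # individuals x variants
  individuals <- samples[keep_samples]
  rownames(dosage) <- individuals

  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vid) | vid == "."]
  colnames(dosage) <- vid

  # orientation: count the founder-minor allele
  fnd <- intersect(founder_ids(pedigree), individuals)
  if (!length(fnd)) stop("no genotyped founders; cannot orient minor alleles")
  fd <- dosage[fnd, , drop = FALSE]
  alt_freq <- colSums(fd, na.rm = TRUE) / (2 * colSums(!is.na(fd)))
  flipped <- !is.na(alt_freq) & alt_freq > 0.5
  dosage[, flipped] <- 2L - dosage[, flipped]

  structure(list(
    dosage = dosage,
    variants = data.frame(
      variant_id = vid,
      chromosome = fix[, "CHROM"],
      position = as.integer(fix[, "POS"]),
      flipped = unname(flipped),
      stringsAsFactors = FALSE
    ),
    individuals = individuals
  ), class = "genotype_matrix")
}

# "0/1", "0|1", "./." -> count of "1" alleles; anything unparseable -> NA
gt_to_alt_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean == "0/0"] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean == "1/1"] <- 2L
  d
}

#' Minor-allele frequency among founders
#'
#' Frequency of the counted (minor) allele computed over genotyped founders:
#' sum of dosages divided by twice the number of non-missing founders.
#' Founders are used as the independent draws from the population; by the
#' orientation rule the result never exceeds 0.5.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param pedigree the matching \code{pedigree_table}.
#' @return named numeric vector of per-variant MAF; NaN where no founder is
#'   genotyped (variant unusable).
#' @export
minor_allele_frequency <- function(genotypes, pedigree) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  fnd <- intersect(founder_ids(pedigree), genotypes$individuals)
  fd <- genotypes$dosage[fnd, , drop = FALSE]
  n_obs <- colSums(!is.na(fd))
  maf <- colSums(fd, na.rm = TRUE) / (2 * n_obs)
  maf[n_obs == 0L] <- NaN
  maf
}

#' Filter variants on founder minor-allele frequency
#'
#' Retains variants with MAF >= \code{maf_threshold} that are not
#' monomorphic; excluded variants are logged with a reason
#' (\code{"monomorphic"}, \code{"low_maf"} or \code{"no_founder_data"}).
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param pedigree the matching \code{pedigree_table}.
#' @param maf_threshold exclusion boundary; variants with MAF strictly below
#'   it are dropped (default 0.05).
#' @return list with \code{retained} (character vector of variant IDs) and
#'   \code{exclusions} (data.frame \code{variant_id}, \code{reason}).
#' @export
filter_variants <- function(genotypes, pedigree, maf_threshold = 0.05) {
  maf <- minor_allele_frequency(genotypes, pedigree)
  reason <- rep(NA_character_, length(maf))
  reason[is.nan(maf)] <- "no_founder_data"
  reason[!is.nan(maf) & maf == 0] <- "monomorphic"
  reason[!is.nan(maf) & maf > 0 & maf < maf_threshold] <- "low_maf"
  keep <- is.na(reason)
  list(
    retained = names(maf)[keep],
    exclusions = data.frame(
      variant_id = names(maf)[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Write a variant exclusion log
#' @param exclusions data.frame from \code{\link{filter_variants}}.
#' @param path output TSV path.
#' @export
write_exclusion_log <- function(exclusions, path) {
  utils::write.table(exclusions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Informative nuclear-family units for one variant
#'
#' A nuclear family is informative at a SNP when both parents are genotyped
#' and at least one parent is heterozygous, so that allelic transmission is
#' non-deterministic for at least one parent.  Offspring with missing
#' genotypes are dropped from the unit; Mendelian-inconsistent offspring are
#' dropped with a warning.  A variant is testable when the number of
#' informative families exceeds \code{min_informative - 1}.
#'
#' @param variant_id variant to extract.
#' @param pedigree a \code{pedigree_table}.
#' @param genotypes a \code{genotype_matrix}.
#' @param min_informative minimum count of informative families for the
#'   testable flag (default 21, i.e. strictly more than 20).
#' @param warn warn on Mendelian-inconsistent offspring (default TRUE).
#' @return list with \code{units} (list of per-family units, each with
#'   \code{father_dosage}, \code{mother_dosage}, \code{offspring_ids},
#'   \code{offspring_dosage}), \code{n_informative}, \code{testable} and
#'   \code{n_mendel_dropped}.
#' @export
informative_families <- function(variant_id, pedigree, genotypes,
                                 min_informative = 21L, warn = TRUE) {
  stopifnot(variant_id %in% colnames(genotypes$dosage))
  dos <- genotypes$dosage[, variant_id]
  nucs <- nuclear_families(pedigree)
  units <- list()
  n_mendel <- 0L
  for (nf in nucs) {
    fa <- dos[nf$father_id]; mo <- dos[nf$mother_id]
    if (is.na(fa) || is.na(mo)) next         # transmission cannot be encoded
    if (fa != 1L && mo != 1L) next           # no heterozygous parent
    kid_ids <- nf$offspring_ids[nf$offspring_ids %in% names(dos)]
    kd <- dos[kid_ids]
    kid_ids <- kid_ids[!is.na(kd)]
    kd <- kd[!is.na(kd)]
    if (!length(kd)) next
    ok <- mendel_consistent(fa, mo, kd)
    n_mendel <- n_mendel + sum(!ok)
    kid_ids <- kid_ids[ok]; kd <- kd[ok]
    if (!length(kd)) next
    units[[length(units) + 1L]] <- list(
      family_id = nf$family_id,
      father_dosage = unname(fa), mother_dosage = unname(mo),
      offspring_ids = kid_ids, offspring_dosage = unname(kd)
    )
  }
  if (n_mendel > 0L && warn) {
    warning(sprintf("variant %s: %d Mendelian-inconsistent offspring dropped",
                    variant_id, n_mendel))
  }
  n_inf <- length(units)
  list(units = units, n_informative = n_inf,
       testable = n_inf >= min_informative,
       n_mendel_dropped = n_mendel)
}

# a child dosage is consistent iff it can be written as tf + tm with
# tf a transmissible allele count from the father (0 -> {0}, 1 -> {0,1},
# 2 -> {1}) and likewise tm from the mother
mendel_consistent <- function(fa, mo, kid) {
  tf <- switch(as.character(fa), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  tm <- switch(as.character(mo), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  kid %in% outer(tf, tm, "+")
}
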