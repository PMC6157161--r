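#' Encode parental minor-allele transmissions for one offspring
#'
#' Given parental and offspring minor-allele dosages at a biallelic SNP
#' with at least one heterozygous parent, encodes the transmission
#' indicators: Z for the designated heterozygous parent (the father when
#' both parents are heterozygous, by convention) and W for the other
#' parent.  W is deterministic when the other parent is homozygous
#' (dosage 0 implies W = 0, dosage 2 implies W = 1).  When both parents
#' are heterozygous and the child is heterozygous, exactly one parent
#' transmitted the minor allele but which one is unidentifiable: Z and W
#' are individually undefined and only their total S = 1 is observed.
#' S always equals the child dosage.
#'
#' @param father_dosage,mother_dosage,child_dosage minor-allele counts in
#'   \{0, 1, 2\}.
#' @return list with \code{z}, \code{w} (NA when ambiguous), \code{s},
#'   \code{het_parent} ("father"/"mother"), \code{w_deterministic},
#'   \code{double_het_ambiguous}.
#' @export
encode_transmission <- function(father_dosage, mother_dosage, child_dosage) {
  e <- encode_transmissions(father_dosage, mother_dosage, child_dosage)
  if (!e$valid) {
    stop(sprintf("cannot encode transmission for trio (%d, %d, %d): %s",
                 father_dosage, mother_dosage, child_dosage, e$reason))
  }
  list(z = e$z, w = e$w, s = e$s, het_parent = e$het_parent,
       w_deterministic = e$w_deterministic,
       double_het_ambiguous = e$ambiguous)
}

#' Vectorized transmission encoding
#'
#' @param father,mother,child integer vectors of minor-allele dosages.
#' @return data.frame with one row per trio: \code{z}, \code{w}, \code{s},
#'   \code{het_parent}, \code{w_deterministic}, \code{ambiguous},
#'   \code{valid}, \code{reason} (NA when valid).  Invalid trios (no
#'   heterozygous parent, dosage out of range, Mendelian inconsistency)
#'   are flagged rather than raised, so scan code can drop them.
#' @export
encode_transmissions <- function(father, mother, child) {
  n <- length(child)
  stopifnot(length(father) == n, length(mother) == n)
  reason <- rep(NA_character_, n)
  in_range <- father %in% 0:2 & mother %in% 0:2 & child %in% 0:2
  reason[!in_range] <- "dosage outside {0,1,2}"
  has_het <- in_range & (father == 1L | mother == 1L)
  reason[in_range & !has_het] <- "neither parent heterozygous"

  het_parent <- ifelse(father == 1L, "father", "mother")
  other <- ifelse(father == 1L, mother, father)

  # Mendelian range: transmissible counts are {0} for dosage 0, {0,1} for 1,
  # {1} for 2, so child must lie in [lo_f+lo_m, hi_f+hi_m]
  lo <- function(d) as.integer(d == 2L)
  hi <- function(d) as.integer(d >= 1L)
  mendel_ok <- child >= lo(father) + lo(mother) & child <= hi(father) + hi(mother)
  reason[has_het & !mendel_ok] <- "Mendelian inconsistency"
  valid <- has_het & mendel_ok

  w_det <- other != 1L
  w <- ifelse(other == 0L, 0L, ifelse(other == 2L, 1L, NA_integer_))
  ambiguous <- valid & other == 1L & child == 1L
  z <- rep(NA_integer_, n)
  z[valid & other == 0L] <- child[valid & other == 0L]
  z[valid & other == 2L] <- child[valid & other == 2L] - 1L
  dh <- valid & other == 1L & !ambiguous
  z[dh] <- as.integer(child[dh] == 2L)
  w[dh] <- as.integer(child[dh] == 2L)
  w[!valid] <- NA_integer_

  data.frame(z = z, w = w, s = ifelse(valid, child, NA_integer_),
             het_parent = ifelse(valid, het_parent, NA_character_),
             w_deterministic = ifelse(valid, w_det, NA),
             ambiguous = ifelse(valid, ambiguous, NA),
             valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}
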