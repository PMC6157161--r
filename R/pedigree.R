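#' Read a PED/FAM pedigree file
#'
#' Reads a whitespace-delimited pedigree with columns family, individual,
#' father, mother and optionally sex and a phenotype placeholder.  "0"
#' denotes a missing parent.  Founders are individuals with both parents
#' missing; individuals with exactly one recorded parent are rejected.
#'
#' @param path path to the pedigree file.
#' @return an object of class \code{pedigree_table}: a data.frame with
#'   columns \code{family_id}, \code{individual_id}, \code{father_id},
#'   \code{mother_id}, \code{sex} (may be NA) and \code{founder}, plus a
#'   nuclear-family decomposition in attribute \code{"nuclear"} (see
#'   \code{\link{nuclear_families}}).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("pedigree file must have >= 4 columns (family, individual, father, mother)")
  ped <- data.frame(
    family_id     = raw[[1L]],
    individual_id = raw[[2L]],
    father_id     = raw[[3L]],
    mother_id     = raw[[4L]],
    sex           = if (ncol(raw) >= 5L) raw[[5L]] else NA_character_,
    stringsAsFactors = FALSE
  )
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  dup <- ped$individual_id[duplicated(ped$individual_id)]
  if (length(dup)) stop("duplicate individual ID(s): ", paste(unique(dup), collapse = ", "))

  half <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(half)) {
    stop("individual(s) with exactly one recorded parent: ",
         paste(ped$individual_id[half], collapse = ", "))
  }
  ped$founder <- is.na(ped$father_id) & is.na(ped$mother_id)

  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    known <- is.na(ref) | ref %in% ped$individual_id
    if (!all(known)) {
      stop("parent ID(s) not present in pedigree: ",
           paste(unique(ref[!known]), collapse = ", "))
    }
    # parent must be in the same family
    idx <- match(ref, ped$individual_id)
    ok <- is.na(ref) | ped$family_id[idx] == ped$family_id
    if (!all(ok, na.rm = TRUE)) {
      stop("parent in a different family for individual(s): ",
           paste(ped$individual_id[!ok], collapse = ", "))
    }
  }

  check_acyclic(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  attr(ped, "nuclear") <- decompose_nuclear(ped)
  ped
}

# Kahn-style peel: repeatedly remove individuals whose parents are all
# removed; leftover individuals lie on a cycle of parent links.
check_acyclic <- function(ped) {
  id <- ped$individual_id
  fa <- match(ped$father_id, id)
  mo <- match(ped$mother_id, id)
  done <- is.na(fa) & is.na(mo)
  repeat {
    newly <- !done & (is.na(fa) | done[ifelse(is.na(fa), 1L, fa)]) &
                     (is.na(mo) | done[ifelse(is.na(mo), 1L, mo)])
    if (!any(newly)) break
    done <- done | newly
  }
  if (!all(done)) stop("cyclic parentage involving: ",
                       paste(id[!done], collapse = ", "))
  invisible(TRUE)
}

decompose_nuclear <- function(ped) {
  kids <- ped[!ped$founder, , drop = FALSE]
  if (!nrow(kids)) return(list())
  key <- paste(kids$family_id, kids$father_id, kids$mother_id, sep = "\r")
  split_idx <- split(seq_len(nrow(kids)), key)
  lapply(unname(split_idx), function(ii) {
    list(family_id = kids$family_id[ii[1L]],
         father_id = kids$father_id[ii[1L]],
         mother_id = kids$mother_id[ii[1L]],
         offspring_ids = kids$individual_id[ii])
  })
}

#' Nuclear-family decomposition of a pedigree
#'
#' Each father-mother pair together with their common offspring forms one
#' nuclear family.
#'
#' @param ped a \code{pedigree_table}.
#' @return a list of nuclear families, each with \code{family_id},
#'   \code{father_id}, \code{mother_id} and \code{offspring_ids}.
#' @export
nuclear_families <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  attr(ped, "nuclear")
}

#' Founder IDs of a pedigree
#' @param ped a \code{pedigree_table}.
#' @return character vector of founder individual IDs.
#' @export
founder_ids <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  ped$individual_id[ped$founder]
}

#' @export
print.pedigree_table <- function(x, ...) {
  cat(sprintf("pedigree_table: %d individuals, %d founders, %d nuclear families\n",
              nrow(x), sum(x$founder), length(attr(x, "nuclear"))))
  invisible(x)
}
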