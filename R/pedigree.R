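#' Validate a pedigree and put it in topological order
#'
#' Checks a table of parent-offspring records and returns a canonical
#' pedigree: ids unique, every named parent present, no individual its own
#' ancestor, and rows ordered so that parents always precede their offspring.
#' Founders are records with both parents missing; `"0"`, `""`, `"-"` and
#' `NA` all denote a missing parent. A `generation` column (founders = 0) is
#' computed when absent and checked for consistency when present.
#'
#' @param records A data frame with columns `id`, `sire`, `dam` and
#'   optionally `sex` (`"M"`, `"F"`, anything else is kept as `"unknown"`)
#'   and `generation`.
#' @return A tibble of class `"pedigree"` with columns `id`, `sire`, `dam`,
#'   `sex`, `generation`, topologically ordered. The original row order is
#'   kept in attribute `"original_order"`.
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   id = c("kid", "pa", "ma"),
#'   sire = c("pa", NA, NA),
#'   dam = c("ma", NA, NA)
#' ))
#' ped$generation
#' @export
validate_pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- setdiff(c("id", "sire", "dam"), names(records))
  if (length(need) > 0) {
    stop("pedigree is missing column(s): ", paste(need, collapse = ", "))
  }
  id <- as.character(records$id)
  sire <- norm_parent(records$sire)
  dam <- norm_parent(records$dam)
  if (anyNA(id) || any(id == "")) stop("pedigree ids must be non-missing")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    stop("duplicate pedigree id(s): ", paste(dup, collapse = ", "))
  }
  unknown <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(unknown) > 0) {
    stop("parent id(s) not present as records: ", paste(unknown, collapse = ", "))
  }
  both <- intersect(stats::na.omit(sire), stats::na.omit(dam))
  if (length(both) > 0) {
    stop("individual(s) listed as both sire and dam: ", paste(both, collapse = ", "))
  }

  sex <- if ("sex" %in% names(records)) {
    s <- toupper(as.character(records$sex))
    ifelse(s %in% c("M", "F"), s, "unknown")
  } else {
    rep("unknown", length(id))
  }

  # generation by longest path from founders; also detects cycles
  si <- match(sire, id)
  di <- match(dam, id)
  gen <- rep(NA_integer_, length(id))
  gen[is.na(si) & is.na(di)] <- 0L
  repeat {
    pending <- which(is.na(gen))
    if (length(pending) == 0) break
    gs <- gen[si[pending]]
    gd <- gen[di[pending]]
    ready <- (is.na(si[pending]) | !is.na(gs)) & (is.na(di[pending]) | !is.na(gd))
    if (!any(ready)) {
      stop(
        "cycle detected in pedigree involving id(s): ",
        paste(id[pending], collapse = ", ")
      )
    }
    idx <- pending[ready]
    gen[idx] <- pmax(gs[ready], gd[ready], 0L, na.rm = TRUE) + 1L
  }
  if ("generation" %in% names(records) && !all(is.na(records$generation))) {
    gen <- as.integer(records$generation)
    # stated generations must still give parents smaller values
    bad <- which(!is.na(si) & gen[si] >= gen | !is.na(di) & gen[di] >= gen)
    if (length(bad) > 0) {
      stop(
        "stated generation does not place parents before offspring for: ",
        paste(id[bad], collapse = ", ")
      )
    }
  }

  ord <- order(gen, seq_along(id))
  out <- tibble::tibble(
    id = id[ord], sire = sire[ord], dam = dam[ord],
    sex = sex[ord], generation = gen[ord]
  )
  attr(out, "original_order") <- match(id, out$id)
  class(out) <- c("pedigree", class(out))
  out
}

norm_parent <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "0", "-", "NA")] <- NA_character_
  x
}

is_pedigree <- function(x) inherits(x, "pedigree")

as_validated_pedigree <- function(ped) {
  if (is_pedigree(ped)) ped else validate_pedigree(ped)
}

# integer parent indices in topological order (0 = unknown), for the engines
ped_indices <- function(ped) {
  list(
    sire = ifelse(is.na(ped$sire), 0L, match(ped$sire, ped$id)),
    dam = ifelse(is.na(ped$dam), 0L, match(ped$dam, ped$id))
  )
}

#' Pairwise kinship matrix from a pedigree
#'
#' Computes the kinship coefficient \eqn{\phi_{ij}} (probability that one
#' random allele from each of i and j is identical by descent) for all pairs,
#' by the standard tabular recursion in topological order: founders are
#' mutually unrelated and non-inbred, \eqn{\phi(a,b) =
#' [\phi(sire_a,b)+\phi(dam_a,b)]/2} for a following b, and
#' \eqn{\phi(a,a) = [1+\phi(sire_a,dam_a)]/2}.
#'
#' @param ped A pedigree (from [validate_pedigree()]) or raw records.
#' @return A symmetric named matrix with \eqn{\phi_{ii} = (1+f_i)/2}.
#' @export
kinship_matrix <- function(ped) {
  ped <- as_validated_pedigree(ped)
  pi <- ped_indices(ped)
  phi <- kinship_engine(pi$sire, pi$dam)
  dimnames(phi) <- list(ped$id, ped$id)
  phi
}

#' Inbreeding coefficients from a pedigree
#'
#' The inbreeding coefficient of an individual is the kinship of its parents;
#' founders (and offspring of unknown parents) have f = 0.
#'
#' @inheritParams kinship_matrix
#' @return A tibble with columns `id` and `f`.
#' @export
inbreeding <- function(ped) {
  ped <- as_validated_pedigree(ped)
  phi <- kinship_matrix(ped)
  tibble::tibble(id = ped$id, f = unname(2 * diag(phi) - 1))
}

#' Read a pedigree CSV
#'
#' Expects header `id,sire,dam,sex,generation` (`sex` and `generation`
#' optional); `0` or an empty field denotes a missing parent.
#'
#' @param path Path to a CSV file.
#' @return A validated pedigree tibble.
#' @export
read_pedigree <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_pedigree(tab)
}
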