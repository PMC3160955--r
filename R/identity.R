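# Condensed identity coefficients via generalized kinship.
#
# For a pair (i, j), Jacquard's nine condensed states partition the IBD
# configurations of the four alleles carried at a locus. The nine
# probabilities Delta_1..Delta_9 are recovered from nine linear equations in
# quantities the recursive engine computes: the total probability, the two
# inbreeding coefficients, phi(i,j), phi(i,i,j), phi(i,j,j), phi(i,i,j,j),
# phi22(ii|jj) and phi22(ij|ij). Each row below lists the coefficients of
# Delta_1..Delta_9 in one of those quantities, derived by conditioning on
# which physical alleles the independent random draws land on within each
# condensed state.
identity_system_matrix <- function() {
  rbind(
    rep(1, 9),                                            # total
    c(1, 1, 1, 1, 0, 0, 0, 0, 0),                         # f_i
    c(1, 1, 0, 0, 1, 1, 0, 0, 0),                         # f_j
    c(1, 0, 1 / 2, 0, 1 / 2, 0, 1 / 2, 1 / 4, 0),         # phi(i,j)
    c(1, 0, 1 / 2, 0, 1 / 4, 0, 1 / 4, 1 / 8, 0),         # phi(i,i,j)
    c(1, 0, 1 / 4, 0, 1 / 2, 0, 1 / 4, 1 / 8, 0),         # phi(i,j,j)
    c(1, 0, 1 / 4, 0, 1 / 4, 0, 1 / 8, 1 / 16, 0),        # phi(i,i,j,j)
    c(1, 1, 1 / 2, 1 / 2, 1 / 2, 1 / 2, 1 / 4, 1 / 4, 1 / 4), # phi22(ii|jj)
    c(1, 0, 1 / 4, 0, 1 / 4, 0, 1 / 4, 1 / 16, 0)         # phi22(ij|ij)
  )
}

#' Condensed identity coefficients for pairs of individuals
#'
#' Computes Jacquard's nine condensed identity coefficients
#' \eqn{\Delta_1..\Delta_9} for every unordered pair (including self-pairs)
#' of the target individuals, from the pedigree alone, by a
#' generalized-kinship recursion. Founders are taken as non-inbred and
#' mutually unrelated.
#'
#' The three strategies return identical values and differ only in the
#' evaluation schedule: `"bottom_up"` recurses lazily from the target pairs
#' towards the founders (minimal storage); `"top_down"` first fills the
#' pairwise-kinship cache for the whole pedigree in generation order before
#' answering queries (more storage, bounded recursion depth per query);
#' `"hybrid"` fills the cache down to `split_generation` and recurses below
#' it, which is the practical choice for very deep pedigrees.
#'
#' @param ped A pedigree (see [validate_pedigree()]).
#' @param ids Target individuals; defaults to every individual.
#' @param strategy `"bottom_up"` (default), `"top_down"` or `"hybrid"`.
#' @param split_generation For `strategy = "hybrid"`: coefficients involving
#'   generations up to this index are pre-tabulated top-down. Defaults to
#'   `max(0, depth - 6)`. Must lie within the pedigree's generation range.
#' @return A tibble of class `"identity_coefs"` with columns `id1`, `id2`,
#'   `d1`..`d9`, one row per unordered pair (self-pairs included), plus an
#'   `"f"` attribute holding a tibble of per-individual inbreeding
#'   coefficients.
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   id = c("a", "b", "x", "y"), sire = c(NA, NA, "a", "a"),
#'   dam = c(NA, NA, "b", "b")
#' ))
#' condensed_identity(ped, c("x", "y"))
#' @export
condensed_identity <- function(ped, ids = NULL,
                               strategy = c("bottom_up", "top_down", "hybrid"),
                               split_generation = NULL) {
  ped <- as_validated_pedigree(ped)
  strategy <- match.arg(strategy)
  if (is.null(ids)) ids <- ped$id
  ids <- as.character(ids)
  miss <- setdiff(ids, ped$id)
  if (length(miss) > 0) {
    stop("unknown target id(s): ", paste(miss, collapse = ", "))
  }
  depth <- max(ped$generation)
  seed_upto <- switch(strategy,
    bottom_up = 0L,
    top_down = nrow(ped),
    hybrid = {
      if (is.null(split_generation)) split_generation <- max(0, depth - 6)
      if (split_generation < 0 || split_generation > depth) {
        stop("split_generation must be between 0 and the pedigree depth (", depth, ")")
      }
      sum(ped$generation <= split_generation)
    }
  )

  idx <- match(ids, ped$id)
  pairs <- which(upper.tri(diag(length(idx)), diag = TRUE), arr.ind = TRUE)
  pairs <- cbind(idx[pairs[, "row"]], idx[pairs[, "col"]])
  pi <- ped_indices(ped)
  q <- cic_engine(pi$sire, pi$dam, pairs, seed_upto)

  delta <- matrix(0, nrow(pairs), 9)
  self <- pairs[, 1] == pairs[, 2]
  if (any(self)) {
    f <- q[self, 1]
    delta[self, 1] <- f
    delta[self, 7] <- 1 - f
  }
  if (any(!self)) {
    v <- rbind(1, t(q[!self, , drop = FALSE]))
    d <- solve(identity_system_matrix(), v)
    d[abs(d) < 1e-13] <- 0 # solver noise on structural zeros
    delta[!self, ] <- t(d)
  }

  out <- tibble::tibble(
    id1 = ped$id[pairs[, 1]],
    id2 = ped$id[pairs[, 2]]
  )
  colnames(delta) <- paste0("d", 1:9)
  out <- dplyr::bind_cols(out, tibble::as_tibble(delta))
  # per-individual f from the self-pairs
  selfrows <- which(self)
  ftab <- tibble::tibble(id = ped$id[pairs[selfrows, 1]], f = q[selfrows, 1])
  attr(out, "f") <- ftab
  class(out) <- c("identity_coefs", class(out))
  out
}

#' Exact identity coefficients by exhaustive gene-drop enumeration
#'
#' An independent brute-force verifier: every founder receives two globally
#' unique allele labels, each of the m non-founder meioses is expanded into
#' its four possible transmission patterns, and each of the \eqn{4^m}
#' equally likely patterns is classified into one of Jacquard's nine
#' condensed states. Counts are exact integers over \eqn{4^m}, so the
#' returned probabilities are exact rationals. The pedigree is pruned to
#' ancestors of the pair before enumeration.
#'
#' @param ped A pedigree.
#' @param i,j Individual ids (may be equal).
#' @param max_nonfounders Guard on the pruned number of non-founders m;
#'   enumeration is \eqn{4^m}.
#' @param chunk Number of transmission patterns processed per block (memory
#'   guard).
#' @return A list with `delta` (numeric, length 9), `numerator` (exact state
#'   counts), `denominator` (\eqn{4^m}) and `m`.
#' @export
enumerate_ibd_oracle <- function(ped, i, j, max_nonfounders = 12, chunk = 2^16) {
  ped <- as_validated_pedigree(ped)
  i <- as.character(i)
  j <- as.character(j)
  miss <- setdiff(c(i, j), ped$id)
  if (length(miss) > 0) stop("unknown target id(s): ", paste(miss, collapse = ", "))

  # prune to ancestors of {i, j}
  keep <- unique(c(i, j))
  repeat {
    par <- stats::na.omit(unique(c(
      ped$sire[ped$id %in% keep],
      ped$dam[ped$id %in% keep]
    )))
    new <- setdiff(par, keep)
    if (length(new) == 0) break
    keep <- c(keep, new)
  }
  sub <- ped[ped$id %in% keep, , drop = FALSE]
  si <- ifelse(is.na(sub$sire), 0L, match(sub$sire, sub$id))
  di <- ifelse(is.na(sub$dam), 0L, match(sub$dam, sub$id))
  nonf <- which(!(si == 0L & di == 0L))
  # individuals with one known parent: the unknown side is a phantom founder
  m <- length(nonf)
  if (m > max_nonfounders) {
    stop("pruned pedigree has ", m, " non-founders; enumeration guard is ", max_nonfounders)
  }

  n <- nrow(sub)
  npat <- 4^m
  counts <- numeric(9)
  ii <- match(i, sub$id)
  jj <- match(j, sub$id)

  start <- 0
  next_label <- 1L
  founder_alleles <- matrix(NA_integer_, n, 2)
  for (k in seq_len(n)) {
    for (s in 1:2) {
      # founders and unknown parental sides get fresh unique labels
      founder_alleles[k, s] <- next_label
      next_label <- next_label + 1L
    }
  }

  while (start < npat) {
    len <- min(chunk, npat - start)
    pat <- start + seq_len(len) - 1
    a1 <- matrix(NA_integer_, len, n) # paternal allele label per individual
    a2 <- matrix(NA_integer_, len, n) # maternal allele label
    div <- 1
    for (k in seq_len(n)) {
      if (si[k] == 0L && di[k] == 0L) {
        a1[, k] <- founder_alleles[k, 1]
        a2[, k] <- founder_alleles[k, 2]
      } else {
        pos <- match(k, nonf)
        code <- (pat %/% 4^(pos - 1)) %% 4
        cs <- code %% 2       # which of sire's two alleles
        cd <- code %/% 2      # which of dam's two alleles
        if (si[k] == 0L) {
          a1[, k] <- founder_alleles[k, 1]
        } else {
          a1[, k] <- ifelse(cs == 0, a1[, si[k]], a2[, si[k]])
        }
        if (di[k] == 0L) {
          a2[, k] <- founder_alleles[k, 2]
        } else {
          a2[, k] <- ifelse(cd == 0, a1[, di[k]], a2[, di[k]])
        }
      }
    }
    st <- classify_jacquard(a1[, ii], a2[, ii], a1[, jj], a2[, jj])
    counts <- counts + tabulate(st, nbins = 9)
    start <- start + len
  }

  list(delta = counts / npat, numerator = counts, denominator = npat, m = m)
}

# Jacquard condensed state (1..9) of allele label quadruples; IBD = equal label
classify_jacquard <- function(x1, x2, y1, y2) {
  A <- x1 == x2
  B <- y1 == y2
  c11 <- x1 == y1
  c12 <- x1 == y2
  c21 <- x2 == y1
  c22 <- x2 == y2
  cross_any <- c11 | c12 | c21 | c22
  st <- integer(length(x1))
  st[A & B & c11] <- 1L
  st[A & B & !c11] <- 2L
  st[A & !B & cross_any] <- 3L
  st[A & !B & !cross_any] <- 4L
  st[!A & B & cross_any] <- 5L
  st[!A & B & !cross_any] <- 6L
  both <- (c11 & c22) | (c12 & c21)
  st[!A & !B & both] <- 7L
  st[!A & !B & !both & cross_any] <- 8L
  st[!A & !B & !cross_any] <- 9L
  st
}

#' The five genetic incidence matrices from identity coefficients
#'
#' Assembles the matrices that carry the additive, dominance and
#' inbreeding-related genetic variance components of the polygenic model:
#' \describe{
#'   \item{AA}{additive: \eqn{2\phi_{ij}}, diagonal \eqn{1+f_i}}
#'   \item{DD}{dominance: \eqn{\Delta_7}, diagonal \eqn{1-f_i}}
#'   \item{AD}{additive-dominance covariance: \eqn{4\Delta_1+\Delta_3+\Delta_5},
#'     diagonal \eqn{4f_i}}
#'   \item{HH}{homozygous dominance: \eqn{\Delta_1}, diagonal \eqn{f_i}}
#'   \item{MH}{inbreeding-depression covariance:
#'     \eqn{\Delta_1+\Delta_2-f_i f_j}, diagonal \eqn{f_i(1-f_i)}}
#' }
#' In a completely outbred pedigree HH, AD and MH vanish and the AA and DD
#' diagonals are 1.
#'
#' @param ic An `"identity_coefs"` tibble from [condensed_identity()], or a
#'   pedigree (in which case coefficients are computed for `ids` first).
#' @param ids Individuals to include (default: all covered by `ic`).
#' @return A named list of five symmetric matrices, class
#'   `"genetic_matrices"`.
#' @export
genetic_matrices <- function(ic, ids = NULL) {
  if (is_pedigree(ic) || (!inherits(ic, "identity_coefs") && is.data.frame(ic) &&
    all(c("id", "sire", "dam") %in% names(ic)))) {
    ic <- condensed_identity(ic, ids = ids)
    ids <- NULL
  }
  stopifnot(inherits(ic, "identity_coefs"))
  f <- attr(ic, "f")
  if (is.null(ids)) ids <- f$id
  n <- length(ids)
  fv <- f$f[match(ids, f$id)]
  if (anyNA(fv)) stop("identity coefficients missing for some requested ids")

  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- stats::setNames(seq_len(nrow(ic)), key(ic$id1, ic$id2))
  grid_i <- rep(seq_len(n), times = n)
  grid_j <- rep(seq_len(n), each = n)
  rows <- lut[key(ids[grid_i], ids[grid_j])]
  if (anyNA(rows)) stop("identity coefficients missing for some pairs of requested ids")
  d <- as.matrix(ic[rows, paste0("d", 1:9)])

  mk <- function(v) {
    m <- matrix(v, n, n, dimnames = list(ids, ids))
    (m + t(m)) / 2
  }
  phi <- d[, 1] + (d[, 3] + d[, 5] + d[, 7]) / 2 + d[, 8] / 4
  AA <- mk(2 * phi)
  DD <- mk(d[, 7])
  HH <- mk(d[, 1])
  AD <- mk(4 * d[, 1] + d[, 3] + d[, 5])
  MH <- mk(d[, 1] + d[, 2] - fv[grid_i] * fv[grid_j])
  diag(AA) <- 1 + fv
  diag(DD) <- 1 - fv
  diag(HH) <- fv
  diag(AD) <- 4 * fv
  diag(MH) <- fv * (1 - fv)
  out <- list(AA = AA, DD = DD, AD = AD, HH = HH, MH = MH)
  class(out) <- c("genetic_matrices", class(out))
  out
}

#' Write identity coefficients to TSV
#'
#' Writes the pairwise coefficients as a long-format TSV
#' (`id1,id2,d1..d9`) and, if `f_path` is given, the per-individual
#' inbreeding coefficients as `id,f`.
#'
#' @param ic An `"identity_coefs"` object.
#' @param path Output TSV path for the pairwise table.
#' @param f_path Optional output TSV path for the inbreeding table.
#' @return `ic`, invisibly.
#' @export
write_identity <- function(ic, path, f_path = NULL) {
  readr::write_tsv(as.data.frame(ic), path, progress = FALSE)
  if (!is.null(f_path)) readr::write_tsv(attr(ic, "f"), f_path, progress = FALSE)
  invisible(ic)
}
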