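# Genome scans with the covariance held fixed.
#
# The covariance Sigma-hat estimated under the no-QTL null is whitened once
# by its Cholesky factor; each locus is then tested by the likelihood ratio
# of ordinary regression in the whitened space,
#   LRT = n log(RSS0 / RSS1),  LOD = LRT / (2 ln 10),
# comparing the null (covariates only) against covariates plus the locus
# terms a = count - 1 in {-1, 0, 1} and d = 1{heterozygote} (or their
# Haley-Knott expected values). Markers with missing genotypes are handled
# by subsetting Sigma to the observed individuals for that marker only.

#' Haldane map function
#'
#' Converts map distance in centimorgans to a recombination fraction under
#' no interference: \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d Distance in cM; must be non-negative.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

#' Validate a genetic map
#'
#' @param map Data frame with columns `marker`, `chr`, `pos` (cM). Markers
#'   must be uniquely named and positions nondecreasing within chromosome.
#' @return The map as a tibble, ordered by chromosome and position.
#' @export
validate_genemap <- function(map) {
  map <- tibble::as_tibble(map)
  need <- setdiff(c("marker", "chr", "pos"), names(map))
  if (length(need) > 0) stop("map is missing column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker)) {
    stop("duplicate marker name(s): ", paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  }
  if (any(!is.finite(map$pos)) || any(map$pos < 0)) stop("marker positions must be finite and >= 0")
  map$chr <- as.character(map$chr)
  map <- map[order(match(map$chr, unique(map$chr)), map$pos), , drop = FALSE]
  map
}

# Whitened regression pieces shared by scan_one / scan_two / thresholds.
# Returns function of an n x k matrix -> whitened matrix, plus the
# null-model QR and residual.
whiten_setup <- function(y, X, Sigma, n) {
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  stopifnot(length(y) == n, nrow(X) == n)
  if (is.null(Sigma)) {
    wh <- identity
  } else {
    stopifnot(all(dim(Sigma) == n))
    U <- tryCatch(chol(Sigma), error = function(e) {
      stop("Sigma is not positive definite")
    })
    wh <- function(M) backsolve(U, M, transpose = TRUE)
  }
  yt <- wh(y)
  Xt <- wh(as.matrix(X))
  qx <- qr(Xt)
  Q <- qr.Q(qx)
  r0 <- yt - Q %*% crossprod(Q, yt)
  list(wh = wh, X = X, yt = yt, Xt = Xt, Q = Q, r0 = r0, rss0 = sum(r0^2), n = n)
}

# locus codings from genotype counts (0/1/2 of the B allele)
locus_coding <- function(g) {
  d <- (g == 1) * 1
  list(a = g - 1, d = d)
}

# Core per-marker statistics for complete-data markers, fully vectorized.
# A, D: n x m whitened-and-X-residualized coding matrices; r0 whitened null
# residual. Returns gain (RSS0 - RSS1), effects, df per marker.
marker_gain <- function(A, D, r0, use_dom) {
  aa <- colSums(A^2)
  ar <- as.numeric(crossprod(A, r0))
  if (!use_dom) {
    testable <- aa > 1e-10
    gain <- ifelse(testable, ar^2 / aa, NA_real_)
    return(list(
      gain = gain, add = ifelse(testable, ar / aa, NA_real_),
      dom = rep(NA_real_, length(aa)), df = ifelse(testable, 1L, NA_integer_),
      testable = testable
    ))
  }
  dd <- colSums(D^2)
  ad <- colSums(A * D)
  dr <- as.numeric(crossprod(D, r0))
  det <- aa * dd - ad^2
  scale <- pmax(aa, 1e-300) * pmax(dd, 1e-300)
  full <- det > 1e-10 * scale & aa > 1e-10 & dd > 1e-10
  addonly <- !full & aa > 1e-10
  gain <- rep(NA_real_, length(aa))
  add <- rep(NA_real_, length(aa))
  dom <- rep(NA_real_, length(aa))
  df <- rep(NA_integer_, length(aa))
  gain[full] <- (ar[full]^2 * dd[full] - 2 * ar[full] * dr[full] * ad[full] +
    dr[full]^2 * aa[full]) / det[full]
  add[full] <- (ar[full] * dd[full] - dr[full] * ad[full]) / det[full]
  dom[full] <- (dr[full] * aa[full] - ar[full] * ad[full]) / det[full]
  df[full] <- 2L
  gain[addonly] <- ar[addonly]^2 / aa[addonly]
  add[addonly] <- ar[addonly] / aa[addonly]
  df[addonly] <- 1L
  list(gain = gain, add = add, dom = dom, df = df, testable = full | addonly)
}

#' Single-locus genome scan with fixed covariance
#'
#' Tests every marker (or every Haley-Knott position) for association with
#' the phenotype by a likelihood-ratio test in the whitened regression, with
#' the covariance matrix estimated once under the no-QTL null and then held
#' fixed, as in the measured-genotype/fixed-heritability family of mixed
#' model scans.
#'
#' @param y Phenotype vector.
#' @param geno Either an n-by-m genotype matrix with entries 0/1/2/NA
#'   (column names = marker names) or a `"geno_prob"` object from
#'   [genotype_probabilities()] for interval mapping.
#' @param X Covariate design matrix (default: intercept only).
#' @param Sigma Fixed covariance matrix; `NULL` means \eqn{\sigma^2 I}
#'   (plain regression; the scale of Sigma does not change the statistic
#'   ordering but does change the LRT, so supply the fitted matrix).
#' @param map Optional genetic map ([validate_genemap()]) used to annotate
#'   markers with `chr` and `pos`.
#' @param coding `"ad"` (additive + dominance, default) or `"a"`
#'   (additive only).
#' @return A tibble of class `"pedscan_scan"` with columns `marker`, `chr`,
#'   `pos`, `df`, `lrt`, `lod`, `p`, `add_effect`, `dom_effect`,
#'   `testable`. Monomorphic or all-missing markers have `testable = FALSE`
#'   and missing statistics.
#' @export
scan_one <- function(y, geno, X = NULL, Sigma = NULL, map = NULL,
                     coding = c("ad", "a")) {
  coding <- match.arg(coding)
  use_dom <- coding == "ad"
  if (inherits(geno, "geno_prob")) {
    A0 <- geno$add
    D0 <- geno$dom
    markers <- geno$positions$marker
    ann <- geno$positions
  } else {
    geno <- as.matrix(geno)
    cd <- locus_coding(geno)
    A0 <- cd$a
    D0 <- cd$d
    dim(D0) <- dim(A0)
    markers <- colnames(geno)
    if (is.null(markers)) markers <- paste0("m", seq_len(ncol(geno)))
    ann <- NULL
  }
  n <- length(y)
  stopifnot(nrow(A0) == n)
  m <- ncol(A0)
  w <- whiten_setup(y, X, Sigma, n)

  res <- list(
    lrt = rep(NA_real_, m), df = rep(NA_integer_, m),
    add = rep(NA_real_, m), dom = rep(NA_real_, m),
    testable = rep(FALSE, m), n_used = rep(n, m)
  )
  miss <- colSums(is.na(A0)) > 0
  complete <- which(!miss)
  if (length(complete) > 0) {
    At <- w$wh(A0[, complete, drop = FALSE])
    At <- At - w$Q %*% crossprod(w$Q, At)
    Dt <- if (use_dom) {
      Dtt <- w$wh(D0[, complete, drop = FALSE])
      Dtt - w$Q %*% crossprod(w$Q, Dtt)
    } else {
      NULL
    }
    g <- marker_gain(At, Dt, w$r0, use_dom)
    res$lrt[complete] <- ifelse(g$testable, n * log(w$rss0 / (w$rss0 - g$gain)), NA_real_)
    res$df[complete] <- g$df
    res$add[complete] <- g$add
    res$dom[complete] <- g$dom
    res$testable[complete] <- g$testable
  }
  for (k in which(miss)) {
    obs <- which(!is.na(A0[, k]))
    res$n_used[k] <- length(obs)
    if (length(obs) <= ncol(w$X) + 1) next
    ws <- whiten_setup(y[obs], w$X[obs, , drop = FALSE],
      if (is.null(Sigma)) NULL else Sigma[obs, obs, drop = FALSE],
      length(obs)
    )
    At <- ws$wh(A0[obs, k, drop = FALSE])
    At <- At - ws$Q %*% crossprod(ws$Q, At)
    Dt <- if (use_dom) {
      Dtt <- ws$wh(D0[obs, k, drop = FALSE])
      Dtt - ws$Q %*% crossprod(ws$Q, Dtt)
    } else {
      NULL
    }
    g <- marker_gain(At, Dt, ws$r0, use_dom)
    if (g$testable[1]) {
      res$lrt[k] <- length(obs) * log(ws$rss0 / (ws$rss0 - g$gain[1]))
      res$df[k] <- g$df[1]
      res$add[k] <- g$add[1]
      res$dom[k] <- g$dom[1]
      res$testable[k] <- TRUE
    }
  }
  res$lrt[res$testable] <- pmax(res$lrt[res$testable], 0)

  out <- tibble::tibble(
    marker = markers,
    chr = NA_character_, pos = NA_real_,
    df = res$df, lrt = res$lrt, lod = res$lrt / (2 * log(10)),
    p = ifelse(res$testable, stats::pchisq(res$lrt, res$df, lower.tail = FALSE), NA_real_),
    add_effect = res$add, dom_effect = res$dom,
    testable = res$testable, n_used = res$n_used
  )
  if (!is.null(ann)) {
    out$chr <- as.character(ann$chr)
    out$pos <- ann$pos
  } else if (!is.null(map)) {
    map <- validate_genemap(map)
    hit <- match(out$marker, map$marker)
    out$chr <- map$chr[hit]
    out$pos <- map$pos[hit]
  }
  class(out) <- c("pedscan_scan", class(out))
  out
}

#' Genotype probabilities for Haley-Knott interval mapping
#'
#' Computes, for each individual and each query position, the conditional
#' probabilities of the three genotype classes given the nearest non-missing
#' flanking markers, under a two-point Markov approximation with Haldane
#' distances and F2-like transition probabilities (phase-unknown ordered
#' genotypes with a uniform founder-origin prior, appropriate for an
#' advanced intercross). At a typed marker the observed genotype gets
#' probability 1; an individual with no typed marker on the chromosome gets
#' the (1/4, 1/2, 1/4) prior (with a warning).
#'
#' @param geno n-by-m genotype matrix (0/1/2/NA), columns named by marker.
#' @param map Genetic map covering the genotyped markers.
#' @param positions Tibble with columns `chr` and `pos` of query positions,
#'   or `NULL` for a grid every `step` cM across each chromosome.
#' @param step Grid spacing in cM when `positions` is `NULL`.
#' @param cross Cross type; only `"ail_f2_like"` is implemented.
#' @return A list of class `"geno_prob"`: `prob` (n x npos x 3 array),
#'   `add` and `dom` (n x npos expected codings), `positions` (tibble with
#'   `marker`, `chr`, `pos`).
#' @export
genotype_probabilities <- function(geno, map, positions = NULL, step = 1,
                                   cross = "ail_f2_like") {
  cross <- match.arg(cross, "ail_f2_like")
  map <- validate_genemap(map)
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) stop("genotype matrix must have marker column names")
  missing_mk <- setdiff(colnames(geno), map$marker)
  if (length(missing_mk) > 0) {
    stop("genotyped marker(s) absent from map: ", paste(missing_mk, collapse = ", "))
  }
  if (is.null(positions)) {
    positions <- dplyr::bind_rows(lapply(split(map, map$chr), function(mm) {
      tibble::tibble(chr = mm$chr[1], pos = seq(min(mm$pos), max(mm$pos), by = step))
    }))
  }
  positions <- tibble::as_tibble(positions)
  bad <- setdiff(unique(positions$chr), unique(map$chr))
  if (length(bad) > 0) stop("query position(s) on unknown chromosome: ", paste(bad, collapse = ", "))
  positions <- positions[order(
    match(positions$chr, unique(map$chr)),
    positions$pos
  ), , drop = FALSE]
  positions$marker <- sprintf("c%s_%.6g", positions$chr, positions$pos)

  n <- nrow(geno)
  npos <- nrow(positions)
  prob <- array(NA_real_, c(n, npos, 3))
  warned <- FALSE

  for (ch in unique(positions$chr)) {
    mm <- map[map$chr == ch, , drop = FALSE]
    span <- range(mm$pos)
    gch <- geno[, mm$marker, drop = FALSE]
    qidx <- which(positions$chr == ch)
    for (qi in qidx) {
      qp <- positions$pos[qi]
      if (qp < span[1] - 1e-9 || qp > span[2] + 1e-9) {
        stop("query position ", qp, " lies outside the marker span of chromosome ", ch)
      }
      # nearest non-missing flanking markers per individual
      left <- rep(NA_integer_, n)
      right <- rep(NA_integer_, n)
      for (k in seq_len(nrow(mm))) {
        if (mm$pos[k] <= qp + 1e-9) {
          typed <- !is.na(gch[, k])
          left[typed] <- k
        }
      }
      for (k in rev(seq_len(nrow(mm)))) {
        if (mm$pos[k] >= qp - 1e-9) {
          typed <- !is.na(gch[, k])
          right[typed] <- k
        }
      }
      groups <- paste(left, right,
        ifelse(is.na(left), -1, gch[cbind(seq_len(n), ifelse(is.na(left), 1L, left))]),
        ifelse(is.na(right), -1, gch[cbind(seq_len(n), ifelse(is.na(right), 1L, right))])
      )
      for (gr in unique(groups)) {
        rows <- which(groups == gr)
        l <- left[rows[1]]
        r <- right[rows[1]]
        gl <- if (is.na(l)) NA else gch[rows[1], l]
        gr2 <- if (is.na(r)) NA else gch[rows[1], r]
        if (is.na(l) && is.na(r)) {
          if (!warned) {
            warning("individual(s) with no typed marker on chromosome ", ch, "; using the F2 prior")
            warned <- TRUE
          }
          p <- c(0.25, 0.5, 0.25)
        } else {
          p <- hk_conditional(
            gl, gr2,
            if (is.na(l)) NA else qp - mm$pos[l],
            if (is.na(r)) NA else mm$pos[r] - qp
          )
        }
        prob[rows, qi, ] <- matrix(p, length(rows), 3, byrow = TRUE)
      }
    }
  }
  add <- prob[, , 3] - prob[, , 1]
  dom <- prob[, , 2]
  dim(add) <- c(n, npos)
  dim(dom) <- c(n, npos)
  structure(
    list(prob = prob, add = add, dom = dom, positions = positions),
    class = "geno_prob"
  )
}

# ordered two-haplotype genotype chain: states (0,0),(0,1),(1,0),(1,1) of
# B-allele dosage per haplotype; per-haplotype transition is a 2-state
# Markov switch with probability r.
hk_transition <- function(r) {
  M <- matrix(c(1 - r, r, r, 1 - r), 2, 2)
  kronecker(M, M)
}

# unordered genotype (0/1/2) observation matrix over ordered states
hk_obs <- function(g) {
  if (is.na(g)) {
    return(rep(1, 4))
  }
  switch(as.character(g),
    "0" = c(1, 0, 0, 0),
    "1" = c(0, 1, 1, 0),
    "2" = c(0, 0, 0, 1),
    stop("genotype values must be 0, 1, 2 or NA")
  )
}

hk_conditional <- function(gl, gr, dl, dr) {
  pri <- rep(0.25, 4)
  fl <- if (is.na(dl)) pri else pri * hk_obs(gl)
  TL <- if (is.na(dl)) diag(4) else hk_transition(haldane(dl))
  a <- as.numeric(t(fl) %*% TL) # P(state at q, obs left)
  if (!is.na(dr)) {
    TR <- hk_transition(haldane(dr))
    b <- as.numeric(TR %*% hk_obs(gr)) # P(obs right | state at q)
    a <- a * b
  }
  p <- c(a[1], a[2] + a[3], a[4])
  p / sum(p)
}

#' Two-locus epistasis scan
#'
#' For each marker pair, tests the interaction terms on top of both loci's
#' marginal terms by the whitened likelihood ratio. Pairs are all
#' inter-chromosome pairs plus intra-chromosome pairs separated by at least
#' `min_sep` cM (collinearity guard).
#'
#' @inheritParams scan_one
#' @param map Genetic map (required to form pairs).
#' @param interaction `"aa"` (additive-by-additive, default) or `"full"`
#'   (all four products of a and d terms).
#' @param min_sep Minimum intra-chromosome separation in cM.
#' @param pairs Optional two-column matrix/data frame of marker names,
#'   overriding pair formation.
#' @return A tibble with `marker1`, `marker2`, `df`, `lrt`, `lod`, `p`,
#'   `testable`.
#' @export
scan_two <- function(y, geno, map, X = NULL, Sigma = NULL,
                     interaction = c("aa", "full"), min_sep = 20,
                     pairs = NULL) {
  interaction <- match.arg(interaction)
  geno <- as.matrix(geno)
  map <- validate_genemap(map)
  markers <- colnames(geno)
  n <- length(y)
  if (is.null(pairs)) {
    hit <- match(markers, map$marker)
    chr <- map$chr[hit]
    pos <- map$pos[hit]
    idx <- utils::combn(length(markers), 2)
    ok <- chr[idx[1, ]] != chr[idx[2, ]] |
      abs(pos[idx[1, ]] - pos[idx[2, ]]) >= min_sep
    pairs <- cbind(markers[idx[1, ok]], markers[idx[2, ok]])
  } else {
    pairs <- as.matrix(pairs)
    if (any(pairs[, 1] == pairs[, 2])) stop("a pair may not use the same marker twice")
  }
  w <- whiten_setup(y, X, Sigma, n)
  cd <- locus_coding(geno)

  nres <- nrow(pairs)
  lrt <- rep(NA_real_, nres)
  df <- rep(NA_integer_, nres)
  testable <- rep(FALSE, nres)
  for (k in seq_len(nres)) {
    i <- match(pairs[k, 1], markers)
    j <- match(pairs[k, 2], markers)
    a1 <- cd$a[, i]
    d1 <- cd$d[, i]
    a2 <- cd$a[, j]
    d2 <- cd$d[, j]
    obs <- !is.na(a1) & !is.na(a2)
    wk <- if (all(obs)) {
      w
    } else {
      whiten_setup(y[obs], w$X[obs, , drop = FALSE],
        if (is.null(Sigma)) NULL else Sigma[obs, obs, drop = FALSE], sum(obs)
      )
    }
    marg <- cbind(a1, d1, a2, d2)[obs, , drop = FALSE]
    inter <- if (interaction == "aa") {
      cbind(a1 * a2)[obs, , drop = FALSE]
    } else {
      cbind(a1 * a2, a1 * d2, d1 * a2, d1 * d2)[obs, , drop = FALSE]
    }
    M0 <- cbind(wk$Xt, wk$wh(marg))
    M1 <- cbind(M0, wk$wh(inter))
    q0 <- qr(M0)
    q1 <- qr(M1)
    dfk <- q1$rank - q0$rank
    if (dfk <= 0) next
    rss0 <- sum(qr.resid(q0, wk$yt)^2)
    rss1 <- sum(qr.resid(q1, wk$yt)^2)
    if (rss1 <= 0) next
    lrt[k] <- max(0, sum(obs) * log(rss0 / rss1))
    df[k] <- dfk
    testable[k] <- TRUE
  }
  tibble::tibble(
    marker1 = pairs[, 1], marker2 = pairs[, 2],
    df = df, lrt = lrt, lod = lrt / (2 * log(10)),
    p = ifelse(testable, stats::pchisq(lrt, df, lower.tail = FALSE), NA_real_),
    testable = testable
  )
}

#' Forward step-wise multiple-QTL mapping
#'
#' Repeatedly scans the genome with previously selected loci added to the
#' covariates, selecting the genome-wide best locus while its statistic
#' exceeds `threshold`. Selected loci are excluded from later scans.
#'
#' @inheritParams scan_one
#' @param threshold LRT threshold for inclusion (e.g. from
#'   [gene_drop_threshold()] or [permutation_threshold()]).
#' @param max_qtl Maximum number of loci to select; must be positive.
#' @return A list of class `"forward_qtl"`: `selected` (tibble with the
#'   selection order, markers and per-step genome-wide maxima), `scans`
#'   (list of per-step scan tibbles) and `final_fit` (joint whitened
#'   regression effect estimates for the selected loci).
#' @export
forward_multiple_qtl <- function(y, geno, X = NULL, Sigma = NULL, map = NULL,
                                 threshold, max_qtl = 10,
                                 coding = c("ad", "a")) {
  coding <- match.arg(coding)
  if (max_qtl <= 0) stop("max_qtl must be positive")
  geno <- as.matrix(geno)
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  selected <- tibble::tibble(
    step = integer(), marker = character(), lrt = numeric(), lod = numeric()
  )
  scans <- list()
  Xcur <- as.matrix(X)
  excl <- character(0)
  for (step in seq_len(max_qtl)) {
    keep <- setdiff(colnames(geno), excl)
    if (length(keep) == 0) break
    sc <- scan_one(y, geno[, keep, drop = FALSE],
      X = Xcur, Sigma = Sigma,
      map = map, coding = coding
    )
    scans[[step]] <- sc
    ok <- which(sc$testable)
    if (length(ok) == 0) break
    best <- ok[which.max(sc$lrt[ok])]
    if (sc$lrt[best] <= threshold) break
    mk <- sc$marker[best]
    selected <- dplyr::bind_rows(selected, tibble::tibble(
      step = step, marker = mk, lrt = sc$lrt[best], lod = sc$lod[best]
    ))
    cd <- locus_coding(geno[, mk])
    newcols <- if (coding == "ad") {
      cbind(cd$a, cd$d)
    } else {
      cbind(cd$a)
    }
    colnames(newcols) <- paste0(mk, if (coding == "ad") c("_a", "_d") else "_a")
    # individuals missing at a selected marker would otherwise drop out of
    # every later step; impute the locus mean to keep rows comparable
    newcols[is.na(newcols)] <- 0
    Xcur <- cbind(Xcur, newcols)
    excl <- c(excl, mk)
  }
  final_fit <- NULL
  if (nrow(selected) > 0) {
    w <- whiten_setup(y, Xcur, Sigma, length(y))
    beta <- qr.coef(qr(w$Xt), w$yt)
    final_fit <- tibble::tibble(term = colnames(Xcur), estimate = as.numeric(beta))
  }
  structure(
    list(selected = selected, scans = scans, final_fit = final_fit),
    class = "forward_qtl"
  )
}

#' @export
print.forward_qtl <- function(x, ...) {
  cat("Forward multiple-QTL selection:", nrow(x$selected), "locus/loci\n")
  if (nrow(x$selected) > 0) print(as.data.frame(x$selected), row.names = FALSE)
  invisible(x)
}
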