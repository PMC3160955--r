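# Empirical genome-wide significance thresholds.
#
# Two methods: (1) permutation of whole genotype rows (genomes) against the
# fixed phenotype and covariance; (2) gene dropping, which simulates null
# genotypes through the pedigree with recombination and therefore preserves
# the family structure of the genotypes, controlling the type-I error even
# when polygenic variation is ignored in the scan model.

new_maxdist <- function(samples, method, seed) {
  structure(
    list(
      samples = as.numeric(samples), method = method,
      n_replicates = length(samples), seed = seed
    ),
    class = "maxdist"
  )
}

#' @export
print.maxdist <- function(x, ...) {
  cat(
    "Genome-wide max-statistic distribution (", x$method, "), ",
    x$n_replicates, " replicates\n",
    sep = ""
  )
  print(stats::quantile(x$samples, c(0.5, 0.9, 0.95, 0.99), type = 7))
  invisible(x)
}

#' Quantile of a max-statistic distribution
#'
#' @param x A `"maxdist"` object.
#' @param probs Quantile levels.
#' @param ... Unused.
#' @return Empirical quantiles (type-7 interpolation).
#' @export
quantile.maxdist <- function(x, probs = 0.95, ...) {
  stats::quantile(x$samples, probs, type = 7, names = FALSE)
}

scan_max <- function(y, geno, X, Sigma, coding) {
  sc <- scan_one(y, geno, X = X, Sigma = Sigma, coding = coding)
  max(sc$lrt[sc$testable], na.rm = TRUE)
}

# replicate-loop fast path: the whitening of (y, X, Sigma) is fixed across
# replicates, so it is computed once and only the genotype side is whitened
# per replicate; numerically identical to scan_one on complete-data markers
scan_max_pre <- function(w, geno, coding) {
  cd <- locus_coding(geno)
  At <- w$wh(cd$a)
  At <- At - w$Q %*% crossprod(w$Q, At)
  Dt <- NULL
  if (coding == "ad") {
    Dt <- w$wh(cd$d)
    Dt <- Dt - w$Q %*% crossprod(w$Q, Dt)
  }
  g <- marker_gain(At, Dt, w$r0, coding == "ad")
  max(w$n * log(w$rss0 / (w$rss0 - g$gain[g$testable])))
}

#' Permutation threshold for a genome scan
#'
#' Each replicate applies one random permutation to the rows of the
#' genotype matrix (all markers jointly, so within-genome LD is preserved)
#' while the phenotype, covariates and covariance are held constant, re-runs
#' the scan, and records the genome-wide maximum LRT. The threshold is the
#' empirical `q`-quantile of those maxima.
#'
#' @inheritParams scan_one
#' @param n_perm Number of permutations (at least 2; >= 100 recommended).
#' @param q Quantile level in (0, 1]; `q = 1` returns the sample maximum.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return A list with `threshold` (LRT scale) and `maxdist` (a
#'   `"maxdist"` object).
#' @export
permutation_threshold <- function(y, geno, X = NULL, Sigma = NULL,
                                  n_perm = 1000, q = 0.95, seed = NULL,
                                  coding = c("ad", "a")) {
  coding <- match.arg(coding)
  if (n_perm < 2) stop("n_perm must be at least 2")
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  geno <- as.matrix(geno)
  n <- length(y)
  if (!is.null(seed)) withr::local_seed(seed)
  complete <- !anyNA(geno)
  w <- if (complete) whiten_setup(y, X, Sigma, n) else NULL
  maxima <- vapply(seq_len(n_perm), function(r) {
    perm <- sample.int(n)
    Gp <- geno[perm, , drop = FALSE]
    if (complete) scan_max_pre(w, Gp, coding) else scan_max(y, Gp, X, Sigma, coding)
  }, numeric(1))
  md <- new_maxdist(maxima, "permutation", seed)
  list(threshold = quantile.maxdist(md, q), maxdist = md)
}

#' Simulate genotypes by gene dropping through a pedigree
#'
#' Assigns alleles to the founders and simulates every meiosis down the
#' pedigree: along each chromosome the first marker's allele is chosen
#' uniformly from the parent's two haplotypes and subsequent markers switch
#' haplotype with probability `haldane(delta_d)` (no interference). The
#' offspring genotype is the sum of the paternal and maternal gametes.
#'
#' @param ped A pedigree.
#' @param map Genetic map; genotypes are simulated at every marker.
#' @param founders Either the string `"two_strain"` (founders alternate
#'   between strain A, coded 0 at every marker, and strain B, coded 2 —
#'   the advanced-intercross default), a named vector assigning `"A"` or
#'   `"B"` to each founder id, or a list with elements `pat` and `mat`:
#'   founder-by-marker haplotype matrices of 0/1 B-allele dosages (row
#'   names = founder ids) to condition on observed founder genomes.
#' @param seed Integer seed.
#' @return An n-by-m genotype matrix (0/1/2), rows named by individual id,
#'   columns by marker.
#' @export
gene_drop <- function(ped, map, founders = "two_strain", seed = NULL) {
  ped <- as_validated_pedigree(ped)
  map <- validate_genemap(map)
  m <- nrow(map)
  if (m == 0) stop("the genetic map is empty")
  n <- nrow(ped)
  if (!is.null(seed)) withr::local_seed(seed)

  founder_rows <- which(is.na(ped$sire) & is.na(ped$dam))
  hap_p <- matrix(NA_real_, n, m) # paternal haplotype B-dosage
  hap_m <- matrix(NA_real_, n, m)
  if (is.character(founders) && length(founders) == 1 && founders == "two_strain") {
    strain <- rep(c("A", "B"), length.out = length(founder_rows))
    names(strain) <- ped$id[founder_rows]
    founders <- strain
  }
  if (is.list(founders) && !is.null(founders$pat)) {
    pat <- founders$pat
    mat <- founders$mat
    miss <- setdiff(ped$id[founder_rows], rownames(pat))
    if (length(miss) > 0 || is.null(mat)) {
      stop("founder haplotype specification incomplete; missing: ", paste(miss, collapse = ", "))
    }
    hap_p[founder_rows, ] <- pat[ped$id[founder_rows], , drop = FALSE]
    hap_m[founder_rows, ] <- mat[ped$id[founder_rows], , drop = FALSE]
  } else {
    strain <- founders[ped$id[founder_rows]]
    if (anyNA(strain)) {
      stop(
        "founder allele specification incomplete; missing: ",
        paste(ped$id[founder_rows][is.na(strain)], collapse = ", ")
      )
    }
    dos <- ifelse(strain == "A", 1, 0) # strain A carries the counted allele
    hap_p[founder_rows, ] <- matrix(dos, length(founder_rows), m)
    hap_m[founder_rows, ] <- hap_p[founder_rows, , drop = FALSE]
  }

  # switch probabilities between consecutive markers; 0.5 across chromosomes
  newchr <- c(TRUE, map$chr[-1] != map$chr[-m])
  d <- c(0, diff(map$pos))
  d[newchr] <- 0
  r <- haldane(d)
  r[newchr] <- 0.5

  # process generation by generation, vectorizing meioses within a cohort
  for (g in sort(unique(ped$generation[-founder_rows]))) {
    rows <- which(ped$generation == g & !(is.na(ped$sire) & is.na(ped$dam)))
    if (length(rows) == 0) next
    si <- match(ped$sire[rows], ped$id)
    di <- match(ped$dam[rows], ped$id)
    hap_p[rows, ] <- make_gametes(hap_p, hap_m, si, r)
    hap_m[rows, ] <- make_gametes(hap_p, hap_m, di, r)
  }
  G <- hap_p + hap_m
  dimnames(G) <- list(ped$id, map$marker)
  G
}

# one gamete per parent index; vectorized over the cohort
make_gametes <- function(hap_p, hap_m, parent, r) {
  k <- length(parent)
  m <- length(r)
  sw <- matrix(stats::runif(k * m), k, m) < matrix(r, k, m, byrow = TRUE)
  h <- matrix(FALSE, k, m) # FALSE = paternal haplotype of the parent
  h[, 1] <- sw[, 1]
  if (m > 1) for (j in 2:m) h[, j] <- xor(h[, j - 1], sw[, j])
  out <- hap_p[parent, , drop = FALSE]
  hm <- hap_m[parent, , drop = FALSE]
  out[h] <- hm[h]
  out
}

#' Gene-dropping threshold for a genome scan
#'
#' Each replicate simulates a null genotype matrix for the phenotyped
#' individuals by [gene_drop()], scans it against the real phenotype,
#' covariates and covariance, and records the genome-wide maximum LRT; the
#' threshold is the empirical `q`-quantile. Because dropped genotypes carry
#' the same pedigree structure as the real ones, this threshold controls the
#' genome-wide type-I error even when the scan's covariance model ignores
#' polygenic variation.
#'
#' @inheritParams permutation_threshold
#' @param ped Pedigree containing the phenotyped individuals.
#' @param map Genetic map.
#' @param ids Phenotyped individual ids, in the order of `y`.
#' @param n_drop Number of gene-dropping replicates.
#' @param founders Founder allele specification, see [gene_drop()].
#' @return A list with `threshold` and `maxdist`.
#' @export
gene_drop_threshold <- function(ped, map, y, ids, X = NULL, Sigma = NULL,
                                n_drop = 1000, q = 0.95, seed = NULL,
                                founders = "two_strain",
                                coding = c("ad", "a")) {
  coding <- match.arg(coding)
  if (n_drop < 2) stop("n_drop must be at least 2")
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  ped <- as_validated_pedigree(ped)
  map <- validate_genemap(map)
  miss <- setdiff(ids, ped$id)
  if (length(miss) > 0) {
    stop("phenotyped id(s) absent from pedigree: ", paste(miss, collapse = ", "))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  w <- whiten_setup(y, X, Sigma, length(y))
  maxima <- vapply(seq_len(n_drop), function(r) {
    G <- gene_drop(ped, map, founders = founders)
    scan_max_pre(w, G[ids, , drop = FALSE], coding)
  }, numeric(1))
  md <- new_maxdist(maxima, "gene_drop", seed)
  list(threshold = quantile.maxdist(md, q), maxdist = md)
}

#' Write a max-statistic distribution to disk
#'
#' Writes the samples as a one-column TSV and the metadata (method,
#' replicate count, seed, reference quantiles) as JSON.
#'
#' @param md A `"maxdist"` object.
#' @param path Output TSV path; metadata goes to `paste0(path, ".json")`
#'   unless `json_path` is given.
#' @param json_path Optional explicit JSON path.
#' @return `md`, invisibly.
#' @export
write_maxdist <- function(md, path, json_path = NULL) {
  readr::write_tsv(tibble::tibble(max_lrt = md$samples), path, progress = FALSE)
  if (is.null(json_path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(
      method = md$method, n_replicates = md$n_replicates,
      seed = md$seed,
      quantiles = as.list(stats::setNames(
        stats::quantile(md$samples, c(0.9, 0.95, 0.99), type = 7, names = FALSE),
        c("q90", "q95", "q99")
      ))
    ),
    json_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(md)
}
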