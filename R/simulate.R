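# Synthetic advanced-intercross-line (AIL) factory.
#
# Two inbred founder strains are crossed (F1) and the line is then bred for
# the requested number of generations by random non-self mating (or sib
# mating). Genotypes come from gene dropping over a marker map; phenotypes
# follow the polygenic model y = X beta + Q gamma + u + e with
# u ~ N(0, sigma2_a AA + sigma2_d DD) and e ~ N(0, sigma2_e I).

#' Build an evenly spaced marker map
#'
#' @param n_chr Number of chromosomes (labelled `"1"`, `"2"`, ...).
#' @param length_cM Chromosome length in cM (recycled).
#' @param n_markers Markers per chromosome, evenly spaced from 0 to
#'   `length_cM` (recycled).
#' @return A genetic map tibble (`marker`, `chr`, `pos`).
#' @export
sim_map <- function(n_chr = 5, length_cM = 60, n_markers = 60) {
  length_cM <- rep(length_cM, length.out = n_chr)
  n_markers <- rep(n_markers, length.out = n_chr)
  dplyr::bind_rows(lapply(seq_len(n_chr), function(ch) {
    pos <- seq(0, length_cM[ch], length.out = n_markers[ch])
    tibble::tibble(
      marker = sprintf("c%d_m%02d", ch, seq_len(n_markers[ch])),
      chr = as.character(ch), pos = pos
    )
  }))
}

#' Simulate an advanced intercross line
#'
#' F0 is two inbred strains (one individual each, strain A coded 0 and
#' strain B coded 2 at every marker); F1 is their cross; later generations
#' are bred by the chosen mating scheme with no selfing. Sexes alternate
#' within each cohort. Genotypes are produced by [gene_drop()] over `map`.
#'
#' @param n_generations Total number of generations including F0 and F1
#'   (so `n_generations = 2` gives F0 + F1 only); at least 2.
#' @param n_per_generation Cohort size from F2 onwards.
#' @param n_f1 F1 cohort size (default `n_per_generation`).
#' @param n_couples Breeding couples per generation from F2 onwards. The
#'   default, one couple per four offspring (mouse-like litter sizes), keeps
#'   a realistic breeder-to-cohort ratio; passing
#'   `min(males, females)` pairs every individual once (maximally diffuse
#'   relatedness), while a small number gives large sibships (strong family
#'   structure).
#' @param mating `"random_nonself"` (default) or `"sib_mating"` (couples are
#'   full-sib pairs where possible).
#' @param map Genetic map (default [sim_map()] defaults).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `ped` (pedigree tibble; generation 0 = F0), `map`,
#'   and `geno` (genotype matrix for all individuals).
#' @export
sim_ail <- function(n_generations = 10, n_per_generation = 200, n_f1 = NULL,
                    n_couples = NULL, mating = c("random_nonself", "sib_mating"),
                    map = sim_map(), seed = NULL) {
  mating <- match.arg(mating)
  if (n_generations < 2) stop("need at least 2 generations (F0 and F1)")
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(n_f1)) n_f1 <- n_per_generation

  id <- c("F0_A", "F0_B")
  sire <- c(NA, NA)
  dam <- c(NA, NA)
  sex <- c("M", "F")
  gen <- c(0L, 0L)
  fam <- c(NA_integer_, NA_integer_) # couple index of one's parents

  add_cohort <- function(g, size, couples) {
    # couples: 2-column matrix of (sire row, dam row)
    pick <- sample.int(nrow(couples), size, replace = TRUE)
    newid <- sprintf("F%d_%03d", g, seq_len(size))
    id <<- c(id, newid)
    sire <<- c(sire, id[couples[pick, 1]])
    dam <<- c(dam, id[couples[pick, 2]])
    sex <<- c(sex, rep(c("M", "F"), length.out = size))
    gen <<- c(gen, rep(g, size))
    fam <<- c(fam, pick)
  }

  add_cohort(1L, n_f1, cbind(1L, 2L))
  if (n_generations > 2) {
    for (g in 2:(n_generations - 1)) {
      rows <- which(gen == g - 1L)
      males <- rows[sex[rows] == "M"]
      females <- rows[sex[rows] == "F"]
      if (length(males) == 0 || length(females) == 0) {
        stop("population too small to avoid selfing in generation ", g)
      }
      nc <- if (is.null(n_couples)) {
        max(2L, min(round(n_per_generation / 4), length(males), length(females)))
      } else {
        n_couples
      }
      if (mating == "sib_mating") {
        # pair brothers with sisters of the same family where possible
        mf <- fam[males][order(fam[males])]
        couples <- cbind(
          males[order(fam[males])][seq_len(nc)],
          females[order(fam[females])][seq_len(nc)]
        )
      } else {
        # harem design: each sire serves ~2 dams, giving both full-sib and
        # half-sib families (the contrast that separates additive from
        # dominance relatedness)
        n_sires <- max(1L, ceiling(nc / 2))
        sires <- sample(males, n_sires, replace = length(males) < n_sires)
        couples <- cbind(
          rep(sires, length.out = nc),
          sample(females, nc, replace = length(females) < nc)
        )
      }
      add_cohort(g, n_per_generation, couples)
    }
  }

  ped <- validate_pedigree(data.frame(
    id = id, sire = sire, dam = dam, sex = sex, generation = gen
  ))
  geno <- gene_drop(ped, map, founders = c(F0_A = "A", F0_B = "B"))
  list(ped = ped, map = validate_genemap(map), geno = geno)
}

#' Simulate phenotypes under the polygenic QTL model
#'
#' Draws \eqn{y = X\beta + Q\gamma + u + \varepsilon} with
#' \eqn{u \sim N(0, \sigma^2_a AA + \sigma^2_d DD)} and
#' \eqn{\varepsilon \sim N(0, \sigma^2_e I)}. QTL effects enter through the
#' codings a = count - 1 and d = 1{heterozygote}.
#'
#' @param ids Phenotyped individual ids (must index `geno` rows and the
#'   matrices).
#' @param matrices A `"genetic_matrices"` list (only `AA` and `DD` are
#'   used), or `NULL` when both genetic variances are zero.
#' @param geno Genotype matrix (rows named by id), needed when `qtl` is
#'   non-empty.
#' @param qtl Tibble/data frame with columns `marker`, `a`, `d`: planted
#'   QTL and their additive/dominance effects.
#' @param sigma2_a,sigma2_d,sigma2_e Variance components (>= 0).
#' @param sigma2_cage Variance of an optional shared-housing (cage) random
#'   effect; individuals are housed `cage_size` to a cage in id order.
#' @param cage_size Individuals per cage.
#' @param beta0 Intercept.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `y`, the diagnostic true polygenic
#'   value `u` and, when `sigma2_cage > 0`, the cage label `cage`.
#' @export
sim_phenotypes <- function(ids, matrices = NULL, geno = NULL, qtl = NULL,
                           sigma2_a = 1, sigma2_d = 0, sigma2_e = 1,
                           sigma2_cage = 0, cage_size = 4,
                           beta0 = 0, seed = NULL) {
  if (any(c(sigma2_a, sigma2_d, sigma2_e, sigma2_cage) < 0)) {
    stop("variances must be non-negative")
  }
  n <- length(ids)
  if (!is.null(seed)) withr::local_seed(seed)
  u <- rep(0, n)
  if (sigma2_a > 0 || sigma2_d > 0) {
    if (is.null(matrices)) stop("genetic matrices are required when genetic variance is positive")
    G <- sigma2_a * matrices$AA[ids, ids] + sigma2_d * matrices$DD[ids, ids]
    G <- (G + t(G)) / 2
    U <- tryCatch(chol(G), error = function(e) {
      message("polygenic covariance not PD; adding 1e-8 jitter")
      chol(G + diag(1e-8, n))
    })
    u <- as.numeric(crossprod(U, stats::rnorm(n)))
  }
  q <- rep(0, n)
  if (!is.null(qtl) && nrow(qtl) > 0) {
    if (is.null(geno)) stop("genotypes are required to plant QTL effects")
    for (k in seq_len(nrow(qtl))) {
      g <- geno[ids, qtl$marker[k]]
      q <- q + qtl$a[k] * (g - 1) + qtl$d[k] * as.numeric(g == 1)
    }
  }
  e <- stats::rnorm(n, sd = sqrt(sigma2_e))
  out <- tibble::tibble(id = ids, y = beta0 + q + u + e, u = u)
  if (sigma2_cage > 0) {
    cage <- (seq_len(n) - 1) %/% cage_size + 1
    out$cage <- cage
    out$y <- out$y + stats::rnorm(max(cage), sd = sqrt(sigma2_cage))[cage]
  }
  out
}

#' Block incidence matrix for a grouping factor
#'
#' Builds the n-by-n 0/1 matrix with 1 where two individuals share a group
#' (cage, litter, batch), for use as a non-genetic variance component in
#' [varcomp_model()].
#'
#' @param group Group label per individual.
#' @return A symmetric 0/1 matrix with unit diagonal.
#' @export
grouping_matrix <- function(group) {
  outer(group, group, `==`) * 1
}
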