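# Small pedigrees and generators shared across tests.

ped_trio <- function() {
  validate_pedigree(data.frame(
    id = c("kid", "pa", "ma"),
    sire = c("pa", NA, NA), dam = c("ma", NA, NA),
    sex = c("M", "M", "F")
  ))
}

# two founders, full sibs x and y
ped_fullsibs <- function() {
  validate_pedigree(data.frame(
    id = c("a", "b", "x", "y"),
    sire = c(NA, NA, "a", "a"), dam = c(NA, NA, "b", "b"),
    sex = c("M", "F", "M", "F")
  ))
}

# shared sire, different dams
ped_halfsibs <- function() {
  validate_pedigree(data.frame(
    id = c("s", "d1", "d2", "x", "y"),
    sire = c(NA, NA, NA, "s", "s"), dam = c(NA, NA, NA, "d1", "d2"),
    sex = c("M", "F", "F", "M", "F")
  ))
}

# z is the offspring of full sibs x and y: f(z) = 1/4
ped_sibmating <- function() {
  validate_pedigree(data.frame(
    id = c("a", "b", "x", "y", "z"),
    sire = c(NA, NA, "a", "a", "x"), dam = c(NA, NA, "b", "b", "y"),
    sex = c("M", "F", "M", "F", "M")
  ))
}

# w is the offspring of half sibs: f(w) = 1/8
ped_halfsib_mating <- function() {
  validate_pedigree(data.frame(
    id = c("s", "d1", "d2", "x", "y", "w"),
    sire = c(NA, NA, NA, "s", "s", "x"), dam = c(NA, NA, NA, "d1", "d2", "y"),
    sex = c("M", "F", "F", "M", "F", "M")
  ))
}

# first cousins c1, c2 (their mothers are full sibs)
ped_cousins <- function() {
  validate_pedigree(data.frame(
    id = c("g1", "g2", "m1", "m2", "f1", "f2", "c1", "c2"),
    sire = c(NA, NA, "g1", "g1", NA, NA, "f1", "f2"),
    dam = c(NA, NA, "g2", "g2", NA, NA, "m1", "m2"),
    sex = c("M", "F", "F", "F", "M", "M", "M", "F")
  ))
}

# random valid pedigree: nf founders then m non-founders with random parents
rand_ped <- function(nf, m, seed) {
  set.seed(seed)
  id <- paste0("i", seq_len(nf + m))
  sire <- dam <- rep(NA_character_, nf + m)
  sexv <- rep(c("M", "F"), length.out = nf)
  for (k in (nf + 1):(nf + m)) {
    males <- which(sexv == "M")
    females <- which(sexv == "F")
    sire[k] <- id[if (length(males) == 1) males else sample(males, 1)]
    dam[k] <- id[if (length(females) == 1) females else sample(females, 1)]
    sexv <- c(sexv, sample(c("M", "F"), 1))
  }
  validate_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sexv))
}

delta_cols <- function(ic) as.matrix(ic[, paste0("d", 1:9)])

ic_pair <- function(ic, i, j) {
  r <- (ic$id1 == i & ic$id2 == j) | (ic$id1 == j & ic$id2 == i)
  unname(unlist(ic[which(r)[1], paste0("d", 1:9)]))
}

# small AIL used by several scan/threshold tests
small_ail <- function(seed = 7, n_generations = 5, n_per_generation = 80,
                      map = sim_map(3, 50, 15), ...) {
  sim_ail(n_generations, n_per_generation, map = map, seed = seed, ...)
}

last_gen_ids <- function(ped) ped$id[ped$generation == max(ped$generation)]

# independent dense multivariate-normal log-density (solve/det route)
dense_mvn_negloglik <- function(y, X, Sigma, beta_hat = NULL) {
  if (is.null(beta_hat)) {
    Si <- solve(Sigma)
    beta_hat <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  }
  r <- y - X %*% beta_hat
  0.5 * (length(y) * log(2 * pi) +
    as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
    as.numeric(t(r) %*% solve(Sigma, r)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
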