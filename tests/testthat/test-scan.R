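test_that("haldane map function has the right endpoints and values", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(100), (1 - exp(-2)) / 2)
  expect_lt(haldane(300), 0.5)
  expect_equal(haldane(1e9), 0.5, tolerance = 1e-9)
  expect_true(all(diff(haldane(seq(0, 200, by = 5))) > 0))
  expect_error(haldane(-1), "non-negative")
})

test_that("map validation enforces names, order and positions", {
  expect_error(validate_genemap(data.frame(marker = "m", chr = 1)), "pos")
  expect_error(
    validate_genemap(data.frame(marker = c("m", "m"), chr = 1, pos = c(0, 1))),
    "duplicate"
  )
  m <- validate_genemap(data.frame(
    marker = c("b", "a"), chr = "1", pos = c(10, 0)
  ))
  expect_equal(m$marker, c("a", "b")) # reordered by position
})

sim_ols_fixture <- function(seed = 101, n = 50, m = 20) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
    dimnames = list(NULL, paste0("m", 1:m))
  )
  X <- cbind(1, rnorm(n))
  y <- 0.4 * (G[, 5] - 1) + X[, 2] * 0.3 + rnorm(n)
  list(y = y, X = X, G = G)
}

test_that("scan with identity covariance equals the OLS likelihood-ratio oracle", {
  fx <- sim_ols_fixture()
  sc <- scan_one(fx$y, fx$G, X = fx$X)
  n <- length(fx$y)
  for (k in seq_len(ncol(fx$G))) {
    a <- fx$G[, k] - 1
    d <- as.numeric(fx$G[, k] == 1)
    rss0 <- sum(resid(lm(fx$y ~ fx$X - 1))^2)
    fit1 <- lm(fx$y ~ fx$X + a + d - 1)
    lrt <- n * log(rss0 / sum(resid(fit1)^2))
    expect_equal(sc$lrt[k], lrt, tolerance = 1e-8)
    expect_equal(sc$add_effect[k], unname(coef(fit1)["a"]), tolerance = 1e-8)
    expect_equal(sc$dom_effect[k], unname(coef(fit1)["d"]), tolerance = 1e-8)
  }
  # additive-only coding against the matching oracle
  sca <- scan_one(fx$y, fx$G, X = fx$X, coding = "a")
  a <- fx$G[, 3] - 1
  rss0 <- sum(resid(lm(fx$y ~ fx$X - 1))^2)
  lrt_a <- n * log(rss0 / sum(resid(lm(fx$y ~ fx$X + a - 1))^2))
  expect_equal(sca$lrt[3], lrt_a, tolerance = 1e-8)
  expect_true(all(sca$df[sca$testable] == 1))
})

test_that("whitening by the Cholesky factor reproduces the identity-covariance scan", {
  fx <- sim_ols_fixture(seed = 7, n = 40, m = 12)
  phi <- kinship_matrix(small_ail(seed = 5, n_generations = 4, n_per_generation = 40)$ped)
  ids <- tail(rownames(phi), 40)
  Sigma <- 1.5 * 2 * phi[ids, ids] + diag(40)
  sc <- scan_one(fx$y, fx$G, X = fx$X, Sigma = Sigma)

  U <- chol(Sigma)
  wh <- function(M) backsolve(U, M, transpose = TRUE)
  A <- fx$G - 1
  D <- (fx$G == 1) * 1
  pre <- structure(
    list(
      add = wh(A), dom = wh(D),
      positions = tibble::tibble(
        marker = colnames(fx$G), chr = NA_character_, pos = NA_real_
      )
    ),
    class = "geno_prob"
  )
  sc_pre <- scan_one(wh(fx$y), pre, X = wh(fx$X))
  expect_equal(sc$lrt, sc_pre$lrt, tolerance = 1e-10)
  expect_equal(sc$add_effect, sc_pre$add_effect, tolerance = 1e-10)
})

test_that("scan statistics are invariant to joint relabeling under iid covariance", {
  fx <- sim_ols_fixture(seed = 3)
  perm <- sample(length(fx$y))
  s1 <- scan_one(fx$y, fx$G, X = fx$X)
  s2 <- scan_one(fx$y[perm], fx$G[perm, ], X = fx$X[perm, ])
  expect_equal(s1$lrt, s2$lrt, tolerance = 1e-10)
})

test_that("monomorphic and missing loci are flagged, others unaffected", {
  fx <- sim_ols_fixture(seed = 11, n = 30, m = 6)
  fx$G[, 2] <- 1 # monomorphic het: a constant, d constant -> untestable
  fx$G[, 4] <- 0 # monomorphic hom
  sc <- scan_one(fx$y, fx$G, X = fx$X)
  expect_false(sc$testable[2])
  expect_false(sc$testable[4])
  expect_true(is.na(sc$lrt[2]))

  # missing genotypes at marker 3 change only marker 3's row
  G2 <- fx$G
  G2[1:5, 3] <- NA
  sc2 <- scan_one(fx$y, G2, X = fx$X)
  expect_equal(sc$lrt[-3], sc2$lrt[-3], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sc$lrt[3], sc2$lrt[3])))
  expect_equal(sc2$n_used[3], 25)

  # the incomplete marker matches the OLS oracle on its observed subset
  obs <- which(!is.na(G2[, 3]))
  a <- G2[obs, 3] - 1
  d <- as.numeric(G2[obs, 3] == 1)
  rss0 <- sum(resid(lm(fx$y[obs] ~ fx$X[obs, ] - 1))^2)
  rss1 <- sum(resid(lm(fx$y[obs] ~ fx$X[obs, ] + a + d - 1))^2)
  expect_equal(sc2$lrt[3], length(obs) * log(rss0 / rss1), tolerance = 1e-8)
})

test_that("LRT, LOD and p are mutually consistent", {
  fx <- sim_ols_fixture(seed = 19)
  sc <- scan_one(fx$y, fx$G, X = fx$X)
  ok <- sc$testable
  expect_equal(sc$lod[ok], sc$lrt[ok] / (2 * log(10)))
  expect_equal(sc$p[ok], pchisq(sc$lrt[ok], sc$df[ok], lower.tail = FALSE))
  expect_true(all(sc$lrt[ok] >= 0))
  expect_true(all(sc$p[ok] > 0 & sc$p[ok] <= 1))
})

test_that("scaling the fixed covariance leaves the scan statistic unchanged", {
  fx <- sim_ols_fixture(seed = 23, n = 30, m = 8)
  Sigma <- diag(30) + 0.3
  s1 <- scan_one(fx$y, fx$G, X = fx$X, Sigma = Sigma)
  s2 <- scan_one(fx$y, fx$G, X = fx$X, Sigma = 7 * Sigma)
  expect_equal(s1$lrt, s2$lrt, tolerance = 1e-10)
})

test_that("genotype probabilities reproduce hand-computed conditionals", {
  map <- data.frame(marker = c("L", "R"), chr = "1", pos = c(0, 20))
  G <- rbind(c(0, 0), c(2, NA), c(NA, NA))
  colnames(G) <- c("L", "R")

  expect_warning(
    gp <- genotype_probabilities(G, map, positions = data.frame(chr = "1", pos = 10)),
    "no typed marker"
  )
  r <- haldane(10)
  # both flanks homozygous 0 at 10 cM each: hand two-locus conditional
  hand <- c((1 - r)^4, 2 * r^2 * (1 - r)^2, r^4)
  hand <- hand / sum(hand)
  expect_equal(gp$prob[1, 1, ], hand, tolerance = 1e-10)
  # one flank typed 2, the other missing: single-flank conditional
  single <- c(r^2, 2 * r * (1 - r), (1 - r)^2)
  expect_equal(gp$prob[2, 1, ], single, tolerance = 1e-10)
  # no typed marker: F2 prior
  expect_equal(gp$prob[3, 1, ], c(0.25, 0.5, 0.25))
  # expected codings integrate the class probabilities
  expect_equal(gp$add[1, 1], hand[3] - hand[1], tolerance = 1e-12)
  expect_equal(gp$dom[1, 1], hand[2], tolerance = 1e-12)

  # at a typed marker the observed genotype has mass one
  gp2 <- genotype_probabilities(G[1:2, ], map, positions = data.frame(chr = "1", pos = 0))
  expect_equal(gp2$prob[2, 1, ], c(0, 0, 1))

  expect_error(
    genotype_probabilities(G, map, positions = data.frame(chr = "9", pos = 1)),
    "unknown chromosome"
  )
  expect_error(
    genotype_probabilities(G, map, positions = data.frame(chr = "1", pos = 30)),
    "outside the marker span"
  )
})

test_that("probabilities sum to one on a simulated chromosome grid", {
  sim <- small_ail(seed = 31, n_generations = 4, n_per_generation = 40,
    map = sim_map(2, 40, 9))
  ids <- last_gen_ids(sim$ped)
  G <- sim$geno[ids, ]
  G[sample(length(G), 60)] <- NA
  gp <- genotype_probabilities(G, sim$map, step = 2.5)
  sums <- apply(gp$prob, c(1, 2), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)
  # typed markers keep their observed genotypes
  mk <- match(sim$map$pos[3], gp$positions$pos[gp$positions$chr == "1"])
  typed <- which(!is.na(G[, 3]))
  expect_equal(
    gp$add[typed, mk], unname(G[typed, 3] - 1),
    tolerance = 1e-12
  )
})
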