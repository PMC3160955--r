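test_that("neg_loglik matches the closed form for the iid model", {
  vm <- varcomp_model(n = 3)
  y <- c(1, 2, 3)
  # ML optimum: beta = mean = 2, sigma2 = mean squared deviation = 2/3
  nll <- neg_loglik(vm, 2 / 3, y)
  expect_equal(as.numeric(nll), 0.5 * (3 * log(2 * pi) + 3 * log(2 / 3) + 3))
  expect_equal(as.numeric(attr(nll, "beta")), 2)

  fit <- fit_ml(vm, y)
  expect_equal(fit$estimates$estimate, 2 / 3, tolerance = 1e-6)
  expect_equal(unname(fit$beta), 2, tolerance = 1e-8)
  expect_equal(fit$convergence$status, "converged")
})

test_that("neg_loglik equals an independent dense multivariate-normal evaluation", {
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    A <- crossprod(matrix(rnorm(n * n), n)) / n # random PSD component
    vm <- varcomp_model(
      K = list(A = A),
      X = cbind(1, rnorm(n)), n = n
    )
    y <- rnorm(n)
    params <- c(runif(1, 0.2, 2), runif(1, 0.2, 2))
    Sigma <- params[1] * A + params[2] * diag(n)
    worst <- max(worst, abs(
      as.numeric(neg_loglik(vm, params, y)) -
        dense_mvn_negloglik(y, vm$X, Sigma)
    ))
  }
  expect_lt(worst, 1e-8)
})

test_that("profiling the fixed effects makes the likelihood shift-invariant", {
  set.seed(7)
  n <- 12
  X <- cbind(1, rnorm(n))
  A <- crossprod(matrix(rnorm(n * n), n)) / n
  vm <- varcomp_model(K = list(A = A), X = X, n = n)
  y <- rnorm(n)
  p <- c(0.7, 1.3)
  expect_equal(
    as.numeric(neg_loglik(vm, p, y)),
    as.numeric(neg_loglik(vm, p, y + X %*% c(3, -2)))
  )
})

test_that("infeasible covariance points are penalized, not fatal", {
  vm <- varcomp_model(K = list(J = matrix(1, 4, 4) - diag(4)), n = 4)
  v <- neg_loglik(vm, c(5, 0.001), y = rnorm(4)) # 5*J + tiny I is indefinite
  expect_true(isTRUE(attr(v, "infeasible")))
  expect_gt(as.numeric(v), 1e9)
})

test_that("two-component fit matches a refined grid search on a balanced toy", {
  # 2 clusters of 3: random-intercept covariance = s2u * block + s2e * I
  block <- kronecker(diag(2), matrix(1, 3, 3))
  set.seed(5)
  y <- as.numeric(crossprod(chol(0.8 * block + 0.5 * diag(6)), rnorm(6)))
  vm <- varcomp_model(K = list(U = block), n = 6)
  fit <- fit_ml(vm, y)

  # independent dense-likelihood grid search with 3 refinement rounds
  X <- matrix(1, 6, 1)
  obj <- function(s2u, s2e) {
    dense_mvn_negloglik(y, X, s2u * block + s2e * diag(6))
  }
  lo <- c(1e-4, 1e-4)
  hi <- c(5, 5)
  for (round in 1:6) {
    gu <- seq(lo[1], hi[1], length.out = 31)
    ge <- seq(lo[2], hi[2], length.out = 31)
    val <- outer(gu, ge, Vectorize(obj))
    ix <- which(val == min(val), arr.ind = TRUE)[1, ]
    step <- c(gu[2] - gu[1], ge[2] - ge[1])
    lo <- pmax(1e-6, c(gu[ix[1]], ge[ix[2]]) - 2 * step)
    hi <- c(gu[ix[1]], ge[ix[2]]) + 2 * step
    best <- c(gu[ix[1]], ge[ix[2]])
  }
  expect_equal(-fit$loglik, obj(best[1], best[2]), tolerance = 1e-6)
  expect_equal(fit$estimates$estimate, best, tolerance = 1e-3)
})

test_that("estimates are scale-equivariant", {
  set.seed(9)
  sim <- small_ail(seed = 9, n_generations = 4, n_per_generation = 60)
  ids <- last_gen_ids(sim$ped)
  gm <- genetic_matrices(sim$ped, ids)
  ph <- sim_phenotypes(ids, gm, sigma2_a = 1, sigma2_d = 0, sigma2_e = 1, seed = 2)
  vm <- varcomp_model(K = list(AA = gm$AA), n = length(ids))
  f1 <- fit_ml(vm, ph$y)
  c_scale <- 3
  f2 <- fit_ml(vm, c_scale * ph$y)
  expect_equal(f2$estimates$estimate, c_scale^2 * f1$estimates$estimate,
    tolerance = 1e-3
  )
  expect_equal(f2$loglik, f1$loglik - length(ids) * log(c_scale), tolerance = 1e-4)
})

test_that("Nelder-Mead and BFGS reach the same optimum", {
  set.seed(13)
  sim <- small_ail(seed = 13, n_generations = 4, n_per_generation = 50)
  ids <- last_gen_ids(sim$ped)
  gm <- genetic_matrices(sim$ped, ids)
  ph <- sim_phenotypes(ids, gm, sigma2_a = 1.5, sigma2_d = 0, sigma2_e = 1, seed = 4)
  vm <- varcomp_model(K = list(AA = gm$AA), n = length(ids))
  f_nm <- fit_ml(vm, ph$y)
  f_bfgs <- fit_ml(vm, ph$y, optimizer = "bfgs")
  expect_equal(f_nm$loglik, f_bfgs$loglik, tolerance = 1e-4)
})

test_that("degenerate designs and shape mismatches are rejected", {
  expect_error(
    varcomp_model(X = cbind(1, c(2, 2, 2)), n = 3),
    "rank deficient"
  )
  expect_error(
    varcomp_model(K = list(A = diag(3)), n = 4),
    "3 x 3|not 4"
  )
  expect_error(neg_loglik(varcomp_model(n = 3), c(1), c(1, 2)), "length")
})

test_that("likelihood-ratio test uses the boundary mixture", {
  set.seed(3)
  sim <- small_ail(seed = 3, n_generations = 4, n_per_generation = 80)
  # phenotype the last two generations: parent-offspring pairs add the
  # relatedness contrast that identifies the additive component
  ids <- sim$ped$id[sim$ped$generation >= max(sim$ped$generation) - 1]
  gm <- genetic_matrices(sim$ped, ids)
  ph <- sim_phenotypes(ids, gm, sigma2_a = 2, sigma2_d = 0, sigma2_e = 0.5, seed = 8)
  full <- fit_ml(varcomp_model(K = list(AA = gm$AA), n = length(ids)), ph$y)
  red <- fit_ml(varcomp_model(n = length(ids)), ph$y)

  same <- lrt_component(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  lrt <- lrt_component(full, red)
  expect_gt(lrt$statistic, 0)
  expect_equal(lrt$p_value, 0.5 * pchisq(lrt$statistic, 1, lower.tail = FALSE))
  plain <- lrt_component(full, red, mixture = FALSE)
  expect_equal(plain$p_value, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_error(lrt_component(red, full), "not nested")
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_ml(varcomp_model(n = 5), c(1, 4, 2, 5, 3))
  td <- tidy(fit)
  expect_true(all(c("term", "type", "estimate") %in% names(td)))
  expect_equal(nrow(td), 2) # one variance + intercept
  gl <- glance(fit)
  expect_equal(gl$nobs, 5)
  expect_equal(gl$AIC, -2 * gl$logLik + 2 * 2)
})

test_that("forward selection behaves on trivial and signal cases", {
  set.seed(17)
  # empty candidate list: residual-only
  y <- rnorm(30)
  sel0 <- select_components(list(), y)
  expect_equal(sel0$estimates$component, "E")

  # clear additive signal: AA enters
  sim <- small_ail(seed = 17, n_generations = 4, n_per_generation = 80)
  ids <- sim$ped$id[sim$ped$generation >= max(sim$ped$generation) - 1]
  gm <- genetic_matrices(sim$ped, ids)
  ph <- sim_phenotypes(ids, gm, sigma2_a = 3, sigma2_d = 0, sigma2_e = 0.5, seed = 6)
  sel <- select_components(list(AA = gm$AA, DD = gm$DD), ph$y)
  trace <- attr(sel, "trace")
  expect_equal(trace$added[2], "AA")
  # likelihood never decreases along the accepted path
  expect_true(all(diff(trace$loglik) >= -1e-8))
})
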