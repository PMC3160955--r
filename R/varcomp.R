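# Variance-component estimation for the polygenic mixed model
#
#   y = X beta + u + e,   u ~ N(0, sum_k sigma2_k K_k),   e ~ N(0, sigma2_e I)
#
# beta is profiled out by generalized least squares at every parameter point,
# so the likelihood is maximized over the variance parameters only.
# Non-negative variances are searched on the log scale; the one covariance
# parameter (the AD component) is searched unconstrained. Positive
# definiteness of the assembled covariance is kept by a penalty rather than
# projection.

#' Specify a variance-component model
#'
#' @param K Named list of n-by-n symmetric relationship/incidence matrices,
#'   one per non-residual component (for the genetic components, see
#'   [genetic_matrices()]). May be empty. A residual identity component is
#'   always appended.
#' @param X Fixed-effect design matrix (defaults to an intercept).
#' @param n Number of individuals (needed only if both `K` and `X` are
#'   missing their dimensions).
#' @param unconstrained Names of components whose parameter is a covariance
#'   and may be negative; defaults to `"AD"` when present.
#' @return A list of class `"varcomp_model"` with elements `K` (including
#'   the residual), `X`, `free_sign`.
#' @export
varcomp_model <- function(K = list(), X = NULL, n = NULL,
                          unconstrained = intersect(names(K), "AD")) {
  if (length(K) > 0 && is.null(names(K))) stop("components in K must be named")
  if ("E" %in% names(K)) stop("the residual component is added automatically")
  if (is.null(n)) {
    n <- if (length(K) > 0) nrow(K[[1]]) else if (!is.null(X)) nrow(X) else {
      stop("cannot infer the number of individuals; supply n")
    }
  }
  for (nm in names(K)) {
    if (!is.matrix(K[[nm]]) || any(dim(K[[nm]]) != n)) {
      stop("component matrix ", nm, " is not ", n, " x ", n)
    }
  }
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X has ", nrow(X), " rows; expected ", n)
  if (qr(X)$rank < ncol(X)) {
    stop(
      "fixed-effect design is rank deficient; check column(s): ",
      paste(colnames(X), collapse = ", ")
    )
  }
  K <- c(K, list(E = diag(n)))
  structure(
    list(K = K, X = X, n = n, free_sign = unconstrained),
    class = "varcomp_model"
  )
}

assemble_sigma <- function(vm, params) {
  Sigma <- matrix(0, vm$n, vm$n)
  for (k in seq_along(vm$K)) Sigma <- Sigma + params[k] * vm$K[[k]]
  Sigma
}

#' Negative profile log-likelihood of a variance-component model
#'
#' Evaluates \eqn{-\ell} of the Gaussian model at the given variance
#' parameters, with the fixed effects replaced by their generalized
#' least-squares estimate \eqn{\hat\beta = (X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1}y}:
#' \deqn{-\ell = \tfrac12 [\, n\log 2\pi + \log|\Sigma| +
#'   (y-X\hat\beta)'\Sigma^{-1}(y-X\hat\beta) \,].}
#' If \eqn{\Sigma} is not positive definite the value is replaced by a large
#' penalty so that simplex searches stay inside the feasible region.
#'
#' @param vm A [varcomp_model()].
#' @param params Numeric vector of variance parameters, one per component of
#'   `vm` (residual last), on the natural scale.
#' @param y Phenotype vector.
#' @return A scalar; attribute `"beta"` carries the GLS fixed-effect
#'   estimates when the point is feasible.
#' @export
neg_loglik <- function(vm, params, y) {
  stopifnot(inherits(vm, "varcomp_model"), length(params) == length(vm$K))
  y <- as.numeric(y)
  if (length(y) != vm$n) stop("y has length ", length(y), "; expected ", vm$n)
  Sigma <- assemble_sigma(vm, params)
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U) || any(diag(U) < 1e-10)) {
    val <- 1e10 * (1 + sum(params^2))
    attr(val, "infeasible") <- TRUE
    return(val)
  }
  yt <- backsolve(U, y, transpose = TRUE)
  Xt <- backsolve(U, vm$X, transpose = TRUE)
  qx <- qr(Xt)
  beta <- qr.coef(qx, yt)
  r <- yt - Xt %*% beta
  val <- 0.5 * (vm$n * log(2 * pi) + 2 * sum(log(diag(U))) + sum(r^2))
  attr(val, "beta") <- beta
  val
}

vc_to_theta <- function(vm, params) {
  th <- params
  pos <- !(names(vm$K) %in% vm$free_sign)
  th[pos] <- log(pmax(params[pos], 1e-12))
  th
}

vc_from_theta <- function(vm, theta) {
  p <- theta
  pos <- !(names(vm$K) %in% vm$free_sign)
  p[pos] <- exp(theta[pos])
  p
}

#' Maximum-likelihood estimation of variance components
#'
#' Maximizes the profile likelihood of [neg_loglik()] over the variance
#' parameters, by Nelder-Mead (default; more robust on these surfaces) or
#' BFGS on the transformed scale (log for variances, raw for covariance
#' parameters). The default initial value splits the phenotypic variance
#' equally across components.
#'
#' @inheritParams neg_loglik
#' @param optimizer `"nelder_mead"` (default) or `"bfgs"`.
#' @param init Optional initial parameter vector (natural scale).
#' @param tol Convergence tolerance on the negative log-likelihood
#'   (`reltol`).
#' @param max_iter Iteration cap.
#' @return An object of class `"varcomp_fit"`: a list with `estimates`
#'   (tibble of component names and variance estimates), `beta`, `loglik`,
#'   `Sigma` (the assembled covariance at the optimum), `convergence`
#'   (iterations and status), `vm`, `y`.
#' @examples
#' fit <- fit_ml(varcomp_model(n = 3), c(1, 2, 3))
#' tidy(fit)
#' @export
fit_ml <- function(vm, y, optimizer = c("nelder_mead", "bfgs"),
                   init = NULL, tol = 1e-8, max_iter = 5000) {
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(vm, "varcomp_model"))
  y <- as.numeric(y)
  if (vm$n <= ncol(vm$X)) stop("need more observations than fixed effects")
  nk <- length(vm$K)
  if (is.null(init)) {
    vy <- stats::var(y) * (vm$n - 1) / vm$n
    init <- rep(vy / nk, nk)
    init[names(vm$K) %in% vm$free_sign] <- 0
  }
  obj <- function(theta) as.numeric(neg_loglik(vm, vc_from_theta(vm, theta), y))
  th0 <- vc_to_theta(vm, init)

  if (nk == 1) {
    # one-parameter model: optim's Nelder-Mead is unreliable in 1D
    opt <- stats::optim(th0, obj,
      method = "Brent", lower = th0 - 30, upper = th0 + 30,
      control = list(maxit = max_iter)
    )
  } else if (optimizer == "nelder_mead") {
    opt <- stats::optim(th0, obj,
      method = "Nelder-Mead",
      control = list(maxit = max_iter, reltol = tol)
    )
  } else {
    opt <- stats::optim(th0, obj,
      method = "BFGS",
      control = list(maxit = max_iter, reltol = tol)
    )
  }
  est <- vc_from_theta(vm, opt$par)
  nll <- neg_loglik(vm, est, y)
  structure(
    list(
      estimates = tibble::tibble(component = names(vm$K), estimate = unname(est)),
      beta = stats::setNames(as.numeric(attr(nll, "beta")), colnames(vm$X)),
      loglik = -as.numeric(nll),
      Sigma = assemble_sigma(vm, est),
      convergence = list(
        iterations = opt$counts[[1]],
        status = if (opt$convergence == 0) "converged" else "max_iter",
        code = opt$convergence,
        optimizer = optimizer
      ),
      vm = vm, y = y
    ),
    class = "varcomp_fit"
  )
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("Variance-component fit (ML, ", x$convergence$optimizer, ")\n", sep = "")
  print(as.data.frame(x$estimates), row.names = FALSE)
  cat("log-likelihood:", format(x$loglik), "  status:", x$convergence$status, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variance-component fit
#'
#' @param x A `"varcomp_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per variance component plus one per fixed
#'   effect.
#' @export
tidy.varcomp_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$estimates, term = paste0("var_", .data$component), type = "variance"),
    tibble::tibble(
      term = names(x$beta), component = NA_character_,
      estimate = unname(x$beta), type = "fixed"
    )
  )[, c("term", "type", "component", "estimate")]
}

#' Glance at a variance-component fit
#'
#' @inheritParams tidy.varcomp_fit
#' @return A one-row tibble with `logLik`, `AIC`, `nobs`, `n_components`,
#'   `convergence`.
#' @export
glance.varcomp_fit <- function(x, ...) {
  k <- nrow(x$estimates) + length(x$beta)
  tibble::tibble(
    logLik = x$loglik, AIC = -2 * x$loglik + 2 * k, nobs = x$vm$n,
    n_components = nrow(x$estimates), convergence = x$convergence$status
  )
}

#' Likelihood-ratio test for variance components
#'
#' Compares two nested variance-component models fitted to the same data.
#' The statistic \eqn{2(\ell_{full}-\ell_{reduced})} is clamped at 0. When a
#' single variance is tested it lies on the boundary of the parameter space
#' under the null, so the default p-value uses the 50:50 mixture
#' \eqn{\chi^2_0:\chi^2_1}; `mixture = FALSE` gives the plain \eqn{\chi^2}
#' p-value with the tested degrees of freedom.
#'
#' @param fit_full,fit_reduced `"varcomp_fit"` objects on the same `y`; the
#'   reduced model's components must be a subset of the full model's.
#' @param mixture Use the boundary-corrected mixture p-value (default).
#' @return A tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
lrt_component <- function(fit_full, fit_reduced, mixture = TRUE) {
  stopifnot(inherits(fit_full, "varcomp_fit"), inherits(fit_reduced, "varcomp_fit"))
  cf <- fit_full$estimates$component
  cr <- fit_reduced$estimates$component
  if (!all(cr %in% cf)) stop("models are not nested: reduced has components not in full")
  df <- length(setdiff(cf, cr))
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  if (mixture && df == 1) {
    p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
    method <- "50:50 chi-square mixture (boundary)"
  } else {
    p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
    method <- paste0("chi-square, df = ", df)
  }
  tibble::tibble(statistic = stat, df = df, p_value = p, method = method)
}

#' Greedy forward selection of variance components
#'
#' Starting from the residual-only model, repeatedly adds the candidate
#' component that most improves the criterion (AIC by default, or a forward
#' LRT at level `alpha`), stopping when no candidate improves. Ties are
#' broken by candidate order. The residual is always included.
#'
#' @param candidates Named list of candidate component matrices.
#' @param y Phenotype vector.
#' @param X Fixed-effect design (default intercept).
#' @param criterion `"AIC"` (default) or `"LRT_forward"`.
#' @param alpha Inclusion level for the forward LRT.
#' @param ... Passed to [fit_ml()].
#' @return The selected `"varcomp_fit"`, with the selection trace (a tibble)
#'   in attribute `"trace"`.
#' @export
select_components <- function(candidates, y, X = NULL,
                              criterion = c("AIC", "LRT_forward"),
                              alpha = 0.05, ...) {
  criterion <- match.arg(criterion)
  chosen <- character(0)
  fit <- fit_ml(varcomp_model(K = list(), X = X, n = length(y)), y, ...)
  crit <- function(f) -2 * f$loglik + 2 * (nrow(f$estimates) + length(f$beta))
  trace <- tibble::tibble(
    step = 0L, added = NA_character_, loglik = fit$loglik, AIC = crit(fit)
  )
  step <- 0L
  while (length(chosen) < length(candidates)) {
    step <- step + 1L
    remaining <- setdiff(names(candidates), chosen)
    fits <- lapply(remaining, function(nm) {
      fit_ml(varcomp_model(K = candidates[c(chosen, nm)], X = X, n = length(y)), y, ...)
    })
    ll <- vapply(fits, function(f) f$loglik, numeric(1))
    best <- which.max(ll) # ties broken by candidate order via which.max
    accept <- if (criterion == "AIC") {
      crit(fits[[best]]) < crit(fit)
    } else {
      lrt_component(fits[[best]], fit)$p_value <= alpha
    }
    if (!accept) break
    chosen <- c(chosen, remaining[best])
    fit <- fits[[best]]
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, added = remaining[best], loglik = fit$loglik, AIC = crit(fit)
    ))
  }
  attr(fit, "trace") <- trace
  fit
}
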