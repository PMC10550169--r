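#' Prior distributions over wiring-rule parameters
#'
#' Constructors for the three prior families used by the wiring-rule
#' simulators: a multivariate Gaussian over the three dense-structural-overlap
#' (DSO) feature exponents, a uniform prior over the shared-subvolume
#' threshold of the neuron-level rule, and a Beta prior over the per-contact
#' synapse probability of the synapse-level rule.
#'
#' Defaults follow the study design: `prior_gaussian()` is
#' N(\[1,1,1\], 0.05 I), `prior_uniform()` is U(0, 100) and `prior_beta()` is
#' Beta(2, 2).
#'
#' @param mean Gaussian mean vector.
#' @param cov Gaussian covariance matrix (positive definite).
#' @param lower,upper Uniform support bounds (`lower < upper`).
#' @param alpha,beta Beta shape parameters (both > 0).
#' @param labels Optional parameter names; sensible rule-specific defaults
#'   are used otherwise.
#' @return An object of class `wr_prior`.
#' @examples
#' p <- prior_gaussian()
#' draws <- sample_prior(p, 100, seed = 1)
#' colMeans(draws)
#' @name priors
NULL

#' @rdname priors
#' @export
prior_gaussian <- function(mean = c(1, 1, 1),
                           cov = diag(0.05, length(mean)),
                           labels = NULL) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  d <- length(mean)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance must be positive definite", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (d == 3L) c("theta_pre", "theta_post", "theta_postAll")
              else paste0("theta_", seq_len(d))
  }
  structure(list(type = "gaussian", dim = d, mean = mean, cov = cov,
                 labels = labels),
            class = "wr_prior")
}

#' @rdname priors
#' @export
prior_uniform <- function(lower = 0, upper = 100, labels = "theta_thres") {
  stopifnot_scalar(lower, "lower"); stopifnot_scalar(upper, "upper")
  if (lower >= upper) stop("'lower' must be < 'upper'", call. = FALSE)
  structure(list(type = "uniform", dim = 1L, lower = lower, upper = upper,
                 labels = labels),
            class = "wr_prior")
}

#' @rdname priors
#' @export
prior_beta <- function(alpha = 2, beta = 2, labels = "theta_prob") {
  stopifnot_scalar(alpha, "alpha"); stopifnot_scalar(beta, "beta")
  if (alpha <= 0 || beta <= 0) stop("'alpha' and 'beta' must be > 0", call. = FALSE)
  structure(list(type = "beta", dim = 1L, alpha = alpha, beta = beta,
                 labels = labels),
            class = "wr_prior")
}

#' @export
print.wr_prior <- function(x, ...) {
  desc <- switch(x$type,
    gaussian = sprintf("Gaussian(mean = [%s], diag cov = [%s])",
                       paste(signif(x$mean, 4), collapse = ", "),
                       paste(signif(diag(x$cov), 4), collapse = ", ")),
    uniform = sprintf("Uniform(%g, %g)", x$lower, x$upper),
    beta = sprintf("Beta(%g, %g)", x$alpha, x$beta))
  cat("Prior over", paste(x$labels, collapse = ", "), "\n ", desc, "\n")
  invisible(x)
}

#' Draw parameter values from a prior
#'
#' @param prior A [prior_gaussian()], [prior_uniform()] or [prior_beta()]
#'   object.
#' @param n Number of i.i.d. draws.
#' @param seed Optional seed; the ambient RNG state is restored afterwards.
#' @return An `n` x `dim` matrix with parameter labels as column names.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "wr_prior"), n >= 1)
  draws <- with_seed(seed, switch(prior$type,
    gaussian = MASS::mvrnorm(n, mu = prior$mean, Sigma = prior$cov),
    uniform = matrix(stats::runif(n, prior$lower, prior$upper), ncol = 1L),
    beta = matrix(stats::rbeta(n, prior$alpha, prior$beta), ncol = 1L)))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- prior$labels
  draws
}

#' Prior log-density
#'
#' @inheritParams sample_prior
#' @param theta Matrix (rows = draws) or vector of parameter values.
#' @return Numeric vector of log-densities (`-Inf` outside the support).
#' @export
prior_log_density <- function(prior, theta) {
  stopifnot(inherits(prior, "wr_prior"))
  theta <- if (is.matrix(theta)) theta else matrix(theta, ncol = prior$dim)
  switch(prior$type,
    gaussian = {
      d <- prior$dim
      ch <- chol(prior$cov)
      u <- backsolve(ch, t(theta) - prior$mean, transpose = TRUE)
      -0.5 * colSums(u^2) - sum(log(diag(ch))) - d / 2 * log(2 * pi)
    },
    uniform = stats::dunif(theta[, 1L], prior$lower, prior$upper, log = TRUE),
    beta = stats::dbeta(theta[, 1L], prior$alpha, prior$beta, log = TRUE))
}

#' Prior support bounds
#'
#' @inheritParams sample_prior
#' @return A list with `lower` and `upper` numeric vectors (infinite for the
#'   Gaussian prior).
#' @export
prior_support <- function(prior) {
  stopifnot(inherits(prior, "wr_prior"))
  switch(prior$type,
    gaussian = list(lower = rep(-Inf, prior$dim), upper = rep(Inf, prior$dim)),
    uniform = list(lower = prior$lower, upper = prior$upper),
    beta = list(lower = 0, upper = 1))
}

#' Marginal prior variances
#' @inheritParams sample_prior
#' @return Numeric vector of per-dimension variances.
#' @export
prior_variance <- function(prior) {
  stopifnot(inherits(prior, "wr_prior"))
  switch(prior$type,
    gaussian = diag(prior$cov),
    uniform = (prior$upper - prior$lower)^2 / 12,
    beta = {
      a <- prior$alpha; b <- prior$beta
      a * b / ((a + b)^2 * (a + b + 1))
    })
}

# Map parameters to an unconstrained space for density estimation: identity
# for the Gaussian prior, scaled logit for bounded supports. Density
# estimation and MCMC run in this space so that posterior draws always
# respect the prior support after back-transformation.
prior_to_unconstrained <- function(prior, theta) {
  theta <- if (is.matrix(theta)) theta else matrix(theta, ncol = prior$dim)
  switch(prior$type,
    gaussian = theta,
    uniform = {
      p <- (theta - prior$lower) / (prior$upper - prior$lower)
      matrix(logit(pmin(pmax(p, 1e-12), 1 - 1e-12)), ncol = 1L)
    },
    beta = matrix(logit(pmin(pmax(theta, 1e-12), 1 - 1e-12)), ncol = 1L))
}

prior_from_unconstrained <- function(prior, z) {
  z <- if (is.matrix(z)) z else matrix(z, ncol = prior$dim)
  out <- switch(prior$type,
    gaussian = z,
    uniform = prior$lower + (prior$upper - prior$lower) * inv_logit(z),
    beta = inv_logit(z))
  colnames(out) <- prior$labels
  out
}

# log |d theta / d z| for the back-transform, per row; used by MCMC targets
# defined in the unconstrained space.
prior_log_jacobian <- function(prior, z) {
  z <- if (is.matrix(z)) z else matrix(z, ncol = prior$dim)
  switch(prior$type,
    gaussian = rep(0, nrow(z)),
    uniform = log(prior$upper - prior$lower) + rowSums(-z - 2 * log1p(exp(-z))),
    beta = rowSums(-z - 2 * log1p(exp(-z))))
}
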