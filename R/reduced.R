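#' Reduced DSO simulator with tractable likelihood
#'
#' A benchmark version of the DSO rule simulator cut down to exactly ten
#' neuron-pair-subvolume combinations, with the summary step omitted: one
#' simulation applies the parametrized rule to the ten feature rows and
#' draws the ten Poisson synapse counts directly. Because the output is the
#' raw count vector, the likelihood is an analytic product of Poisson terms,
#' which makes a high-quality MCMC reference posterior available for
#' benchmarking the neural posterior estimator.
#'
#' The packaged feature table is a synthetic stand-in drawn once from the
#' package's structural-model generator and frozen
#' (`inst/extdata/reduced_features_synthetic.csv`).
#'
#' @param features Data frame with columns `pre`, `post`, `postAll`
#'   (positive), 10 rows by default.
#' @param rate_ceiling Rate clip, see [dso_rate()].
#' @return For `reduced_dso_features()`, the frozen feature table; for
#'   `reduced_simulator()`, a simulator closure `f(theta)` returning the
#'   count vector (see [dso_summary_simulator()] for the closure contract).
#' @export
reduced_dso_features <- function() {
  path <- system.file("extdata", "reduced_features_synthetic.csv",
                      package = "wiresbi", mustWork = TRUE)
  utils::read.csv(path)
}

#' @rdname reduced_dso_features
#' @export
reduced_simulator <- function(features = reduced_dso_features(),
                              rate_ceiling = 1e6) {
  stopifnot(all(c("pre", "post", "postAll") %in% names(features)),
            all(features$pre > 0), all(features$post > 0),
            all(features$postAll > 0))
  X <- cbind(log(features$pre), log(features$post), -log(features$postAll))
  nr <- nrow(features)
  f <- function(theta) {
    lam <- pmin(exp(as.vector(X %*% theta)), rate_ceiling)
    stats::rpois(nr, lam)
  }
  simulator_skeleton(f, nr, 3L, paste0("c", seq_len(nr)))
}

#' Analytic Poisson log-likelihood of the reduced simulator
#'
#' @param theta Length-3 DSO exponents.
#' @param counts Nonnegative integer synapse counts, one per feature row.
#' @param features Feature table as in [reduced_simulator()].
#' @param rate_ceiling Rate clip matching the simulator.
#' @return Scalar log-likelihood.
#' @export
reduced_log_likelihood <- function(theta, counts,
                                   features = reduced_dso_features(),
                                   rate_ceiling = 1e6) {
  stopifnot(length(counts) == nrow(features), all(counts >= 0))
  lam <- dso_rate(features$pre, features$post, features$postAll, theta,
                  rate_ceiling = rate_ceiling)
  sum(stats::dpois(counts, lam, log = TRUE))
}

# One univariate slice-sampling update (stepping out + shrinkage, Neal 2003).
slice_update_1d <- function(x0, log_f, f0 = NULL, w = 1, max_steps = 100L) {
  f0 <- f0 %||% log_f(x0)
  y <- f0 - stats::rexp(1L)
  lo <- x0 - w * stats::runif(1L)
  hi <- lo + w
  steps <- floor(max_steps * stats::runif(1L))
  while (steps > 0L && log_f(lo) > y) { lo <- lo - w; steps <- steps - 1L }
  steps <- max_steps - steps
  while (steps > 0L && log_f(hi) > y) { hi <- hi + w; steps <- steps - 1L }
  repeat {
    x1 <- stats::runif(1L, lo, hi)
    f1 <- log_f(x1)
    if (f1 >= y) return(list(x = x1, f = f1))
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-12) return(list(x = x0, f = f0))
  }
}

# Split-R-hat (Gelman et al.): chains is an iterations x chains matrix.
split_rhat <- function(chains) {
  n <- nrow(chains) %/% 2L
  halves <- cbind(chains[seq_len(n), , drop = FALSE],
                  chains[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2L, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' MCMC reference posterior for the reduced simulator
#'
#' Samples the posterior density (analytic Poisson likelihood times prior)
#' with slice-sampling-within-Gibbs over the unconstrained parameter space,
#' running parallel chains initialized from the prior. Convergence requires
#' split-R-hat below `rhat_max` in every dimension; otherwise a diagnostic
#' error reports the R-hat values. The first half of each chain is discarded
#' as burn-in and the rest pooled and thinned to about `n_samples` draws.
#'
#' @param counts Observed count vector of the reduced simulator.
#' @param prior A [prior_gaussian()] (or other `wr_prior`) over the rule
#'   parameters.
#' @param features Reduced feature table.
#' @param n_chains Parallel chains (default 10).
#' @param n_iter Iterations per chain after burn-in is included.
#' @param n_samples Approximate pooled sample size returned.
#' @param rhat_max Convergence threshold for split-R-hat.
#' @param seed Optional seed.
#' @param log_likelihood Likelihood override, `function(theta) scalar`;
#'   defaults to [reduced_log_likelihood()] with `counts`/`features`.
#' @return A `posterior_samples` matrix (draws x parameters) with the prior
#'   labels as column names and an `rhat` attribute.
#' @export
mcmc_reference_posterior <- function(counts, prior,
                                     features = reduced_dso_features(),
                                     n_chains = 10L, n_iter = 2000L,
                                     n_samples = 10000L, rhat_max = 1.01,
                                     seed = NULL, log_likelihood = NULL) {
  stopifnot(inherits(prior, "wr_prior"))
  d <- prior$dim
  loglik <- log_likelihood %||%
    function(theta) reduced_log_likelihood(theta, counts, features)
  log_target <- function(z) {
    theta <- prior_from_unconstrained(prior, matrix(z, nrow = 1L))
    ll <- loglik(as.numeric(theta))
    if (!is.finite(ll)) return(-Inf)
    ll + prior_log_density(prior, theta) + prior_log_jacobian(prior, z)
  }
  with_seed(seed, {
    inits <- prior_to_unconstrained(prior, sample_prior(prior, n_chains))
    draws <- array(NA_real_, c(n_iter, n_chains, d))
    for (ch in seq_len(n_chains)) {
      z <- inits[ch, ]
      f <- log_target(z)
      for (it in seq_len(n_iter)) {
        for (dd in seq_len(d)) {
          up <- slice_update_1d(z[dd], function(v) {
            zz <- z; zz[dd] <- v; log_target(zz)
          }, w = 1)
          z[dd] <- up$x
        }
        draws[it, ch, ] <- z
      }
    }
    keep <- (n_iter %/% 2L + 1L):n_iter
    rhat <- vapply(seq_len(d), function(dd) split_rhat(draws[keep, , dd]),
                   numeric(1L))
    if (any(rhat > rhat_max)) {
      stop(sprintf("MCMC not converged: split-R-hat = %s (threshold %g)",
                   paste(signif(rhat, 4), collapse = ", "), rhat_max),
           call. = FALSE)
    }
    pooled <- do.call(rbind, lapply(seq_len(n_chains), function(ch) {
      draws[keep, ch, , drop = FALSE][, 1L, ]
    }))
    pooled <- matrix(pooled, ncol = d)
    if (nrow(pooled) > n_samples) {
      pooled <- pooled[round(seq(1L, nrow(pooled), length.out = n_samples)), ,
                       drop = FALSE]
    }
    out <- prior_from_unconstrained(prior, pooled)
    attr(out, "rhat") <- rhat
    class(out) <- c("posterior_samples", class(out))
    out
  })
}

#' Marginal posterior mode (MAP) per parameter
#'
#' The maximum of each one-dimensional posterior marginal, located as the
#' argmax of a Gaussian kernel density estimate evaluated on a 1,000-point
#' grid spanning the sample range.
#'
#' @param samples Matrix of posterior draws (rows) by parameters (columns);
#'   at least 1,000 draws.
#' @return Named numeric vector of per-parameter marginal modes.
#' @export
marginal_map <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1000L) {
    stop("marginal_map needs at least 1,000 samples", call. = FALSE)
  }
  vapply(seq_len(ncol(samples)), function(j) {
    x <- samples[, j]
    if (stats::sd(x) < 1e-12) return(x[1L])
    de <- stats::density(x, n = 1000L, from = min(x), to = max(x))
    de$x[which.max(de$y)]
  }, numeric(1L)) |> stats::setNames(colnames(samples))
}
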