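#' Training configuration for neural posterior estimation
#'
#' Bundles the simulation budget and density-estimator hyperparameters.
#' Defaults follow the study's training regime: batch size 1,000, a 10%
#' validation split and early stopping after 20 epochs without validation
#' improvement, with a two-hidden-layer trunk of 50 units.
#'
#' @param n_simulations Total simulation budget.
#' @param n_components Gaussian mixture components of the conditional
#'   density estimator.
#' @param hidden_units Width of the two hidden layers.
#' @param batch_size Training batch size.
#' @param validation_fraction Fraction of simulations held out for
#'   validation, in (0, 1).
#' @param stop_after_epochs Early-stopping patience in epochs.
#' @param max_epochs Hard cap on training epochs.
#' @param learning_rate Adam learning rate.
#' @param n_rounds Sequential rounds; 1 = amortized single-round NPE.
#' @param seed Seed for the simulation and training substreams.
#' @return An object of class `training_config`.
#' @export
training_config <- function(n_simulations = 10000L, n_components = 1L,
                            hidden_units = 50L, batch_size = 1000L,
                            validation_fraction = 0.1,
                            stop_after_epochs = 20L, max_epochs = 500L,
                            learning_rate = 1e-3, n_rounds = 1L,
                            seed = 1L) {
  stopifnot(n_simulations >= 100L, n_components >= 1L, hidden_units >= 1L,
            batch_size >= 1L, validation_fraction > 0,
            validation_fraction < 1, stop_after_epochs >= 1L,
            max_epochs >= 1L, learning_rate > 0, n_rounds >= 1L)
  structure(as.list(environment()), class = "training_config")
}

run_simulations <- function(simulator, theta) {
  n <- nrow(theta)
  first <- simulator(theta[1L, ])
  x <- matrix(NA_real_, n, length(first))
  colnames(x) <- names(first)
  x[1L, ] <- first
  if (n > 1L) {
    for (i in 2L:n) x[i, ] <- simulator(theta[i, ])
  }
  x
}

drop_nonfinite <- function(theta, x) {
  ok <- apply(is.finite(x), 1L, all) & apply(is.finite(theta), 1L, all)
  if (!all(ok)) {
    warning(sprintf("dropping %d simulation(s) with non-finite output",
                    sum(!ok)), call. = FALSE)
  }
  if (!any(ok)) stop("all simulations produced non-finite output",
                     call. = FALSE)
  list(theta = theta[ok, , drop = FALSE], x = x[ok, , drop = FALSE])
}

#' Neural posterior estimation for wiring-rule simulators
#'
#' Fits an amortized conditional density estimator q(theta | x) from
#' simulated (parameter, data) pairs: parameters are drawn from the prior,
#' the simulator maps each draw to a summary vector, and a mixture-density
#' network is trained by maximum conditional likelihood. Parameters with
#' bounded priors are estimated on an unconstrained (logit) scale, so
#' posterior draws always respect the prior support. Once trained, the
#' estimator yields posterior samples for any observation without
#' retraining.
#'
#' @param simulator A simulator closure (see [dso_summary_simulator()],
#'   [reduced_simulator()] and friends): `f(theta)` returning a fixed-length
#'   finite numeric vector.
#' @param prior A `wr_prior` over the simulator's parameters.
#' @param config A [training_config()].
#' @param observation Optional default observation `x_obs` that
#'   [predict.npe()], [coef.npe()] and [simulate.npe()] condition on.
#' @return An object of class `npe` with `print`, `summary`, `predict`,
#'   `coef`, `plot` and `simulate` methods.
#' @examples
#' sim <- reduced_simulator()
#' prior <- prior_gaussian()
#' fit <- npe(sim, prior, training_config(n_simulations = 500, seed = 1))
#' x_obs <- with_seed(2, sim(c(1, 1, 1)))
#' head(predict(fit, x_obs, n_samples = 100, seed = 3))
#' @export
npe <- function(simulator, prior, config = training_config(),
                observation = NULL) {
  stopifnot(inherits(prior, "wr_prior"),
            inherits(config, "training_config"))
  if (config$n_rounds > 1L) {
    stop("config$n_rounds > 1: use snpe() for sequential estimation",
         call. = FALSE)
  }
  theta <- sample_prior(prior, config$n_simulations,
                        seed = substream_seed(config$seed, "simulate"))
  x <- with_seed(substream_seed(config$seed, "simulate_x"),
                 run_simulations(simulator, theta))
  dat <- drop_nonfinite(theta, x)
  fit <- mdn_train(prior_to_unconstrained(prior, dat$theta), dat$x,
                   n_components = config$n_components,
                   hidden = config$hidden_units,
                   batch_size = config$batch_size,
                   validation_fraction = config$validation_fraction,
                   stop_after_epochs = config$stop_after_epochs,
                   max_epochs = config$max_epochs,
                   learning_rate = config$learning_rate,
                   seed = substream_seed(config$seed, "train"))
  structure(list(mdn = fit, prior = prior, simulator = simulator,
                 config = config, observation = observation,
                 n_train = nrow(dat$x), amortized = TRUE,
                 rounds = 1L),
            class = "npe")
}

#' Sequential neural posterior estimation focused on one observation
#'
#' Trains over several rounds to concentrate the simulation budget on a
#' specific observation: after each round, the prior is truncated to the
#' region containing essentially all posterior mass at `x_obs` (a
#' per-dimension quantile box of posterior draws, intersected with the prior
#' support), and the next round's parameters are drawn from this truncated
#' prior by rejection. All draws accumulated inside the current region are
#' valid truncated-prior draws, so each round retrains on the full retained
#' set. With `n_rounds = 1` this is exactly [npe()].
#'
#' @inheritParams npe
#' @param x_obs The observation to focus on.
#' @return An `npe` object (non-amortized when `n_rounds > 1`: its draws are
#'   only valid conditioned on `x_obs`).
#' @export
snpe <- function(simulator, prior, x_obs, config = training_config()) {
  stopifnot(inherits(prior, "wr_prior"),
            inherits(config, "training_config"))
  rounds <- config$n_rounds
  if (rounds == 1L) {
    cfg1 <- config
    return(npe(simulator, prior, cfg1, observation = x_obs))
  }
  per_round <- config$n_simulations %/% rounds
  d <- prior$dim
  supp <- prior_support(prior)
  box <- rbind(lower = supp$lower, upper = supp$upper)
  theta_all <- NULL; x_all <- NULL
  est <- NULL
  for (r in seq_len(rounds)) {
    seed_r <- substream_seed(config$seed, paste0("round", r))
    theta_r <- with_seed(seed_r, {
      sample_truncated_prior(prior, per_round, box)
    })
    x_r <- with_seed(substream_seed(config$seed, paste0("round_x", r)),
                     run_simulations(simulator, theta_r))
    theta_all <- rbind(theta_all, theta_r)
    x_all <- rbind(x_all, x_r)
    inside <- rowSums(sweep(theta_all, 2L, box["lower", ], "<") |
                      sweep(theta_all, 2L, box["upper", ], ">")) == 0L
    dat <- drop_nonfinite(theta_all[inside, , drop = FALSE],
                          x_all[inside, , drop = FALSE])
    fit <- mdn_train(prior_to_unconstrained(prior, dat$theta), dat$x,
                     n_components = config$n_components,
                     hidden = config$hidden_units,
                     batch_size = config$batch_size,
                     validation_fraction = config$validation_fraction,
                     stop_after_epochs = config$stop_after_epochs,
                     max_epochs = config$max_epochs,
                     learning_rate = config$learning_rate,
                     seed = substream_seed(config$seed, paste0("train", r)))
    est <- structure(list(mdn = fit, prior = prior, simulator = simulator,
                          config = config, observation = x_obs,
                          n_train = nrow(dat$x),
                          amortized = FALSE, rounds = r),
                     class = "npe")
    if (r < rounds) {
      ps <- predict(est, x_obs, n_samples = 5000L,
                    seed = substream_seed(config$seed, paste0("trunc", r)))
      lo <- apply(ps, 2L, stats::quantile, probs = 5e-4)
      hi <- apply(ps, 2L, stats::quantile, probs = 1 - 5e-4)
      pad <- 0.1 * (hi - lo)
      box <- rbind(lower = pmax(supp$lower, lo - pad),
                   upper = pmin(supp$upper, hi + pad))
    }
  }
  est
}

# Rejection sampling from the prior restricted to a box; falls back to
# widening the box if acceptance is pathologically low.
sample_truncated_prior <- function(prior, n, box) {
  out <- matrix(NA_real_, 0L, prior$dim)
  tries <- 0L
  while (nrow(out) < n && tries < 2000L) {
    cand <- sample_prior(prior, max(n, 1000L))
    ok <- rowSums(sweep(cand, 2L, box["lower", ], "<") |
                  sweep(cand, 2L, box["upper", ], ">")) == 0L
    out <- rbind(out, cand[ok, , drop = FALSE])
    tries <- tries + 1L
    if (tries %% 500L == 0L) {
      # acceptance too low: widen the box by 50% around its center
      ctr <- colMeans(box); hw <- (box["upper", ] - box["lower", ]) / 2
      box <- rbind(lower = ctr - 1.5 * hw, upper = ctr + 1.5 * hw)
    }
  }
  if (nrow(out) < n) {
    stop("truncated-prior rejection sampling failed to reach the budget",
         call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' @export
print.npe <- function(x, ...) {
  cat(sprintf("Neural posterior estimator (%s)\n",
              if (x$amortized) "amortized, single round"
              else sprintf("sequential, %d rounds", x$rounds)))
  cat(sprintf("  parameters: %s\n", paste(x$prior$labels, collapse = ", ")))
  cat(sprintf("  trained on %d simulations; validation loss %.4f\n",
              x$n_train, x$mdn$val_loss))
  invisible(x)
}

#' @export
summary.npe <- function(object, n_samples = 5000L, seed = NULL, ...) {
  out <- list(estimator = object)
  if (!is.null(object$observation)) {
    s <- predict(object, n_samples = max(n_samples, 1000L), seed = seed)
    out$posterior_mean <- colMeans(s)
    out$posterior_sd <- apply(s, 2L, stats::sd)
    out$marginal_map <- marginal_map(s)
    out$credible_95 <- apply(s, 2L, stats::quantile,
                             probs = c(0.025, 0.975))
  }
  class(out) <- "summary.npe"
  out
}

#' @export
print.summary.npe <- function(x, ...) {
  print(x$estimator)
  if (!is.null(x$posterior_mean)) {
    tab <- rbind(mean = x$posterior_mean, sd = x$posterior_sd,
                 map = x$marginal_map, x$credible_95)
    cat("Posterior at the stored observation:\n")
    print(signif(tab, 4))
  } else {
    cat("No stored observation; condition with predict(fit, x).\n")
  }
  invisible(x)
}

#' Draw posterior samples from a trained estimator
#'
#' @param object An [npe()] fit.
#' @param x Observation to condition on; defaults to the stored one.
#' @param n_samples Number of posterior draws.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A `posterior_samples` matrix (draws x parameters).
#' @export
predict.npe <- function(object, x = object$observation,
                        n_samples = 1000L, seed = NULL, ...) {
  if (is.null(x)) {
    stop("no observation: pass x or fit with observation =", call. = FALSE)
  }
  if (inherits(x, "data.frame")) x <- as_observation(x)
  z <- mdn_sample(object$mdn, as.numeric(x), n_samples, seed = seed)
  out <- prior_from_unconstrained(object$prior, z)
  attr(out, "x") <- x
  class(out) <- c("posterior_samples", class(out))
  out
}

#' Marginal MAP estimates at the stored observation
#' @param object An [npe()] fit with a stored observation.
#' @param n_samples Posterior draws used for the kernel density estimate.
#' @param seed Optional seed.
#' @param ... Unused.
#' @export
coef.npe <- function(object, n_samples = 10000L, seed = NULL, ...) {
  marginal_map(predict(object, n_samples = max(n_samples, 1000L),
                       seed = seed))
}

#' Posterior predictive simulation
#'
#' Draws parameters from the posterior at the stored (or given) observation
#' and pushes each through the simulator.
#'
#' @param object An [npe()] fit.
#' @param nsim Number of predictive simulations.
#' @param seed Optional seed.
#' @param x Observation to condition on.
#' @param ... Unused.
#' @return Matrix (`nsim` x data dimension) of simulated observations.
#' @export
simulate.npe <- function(object, nsim = 1000L, seed = NULL,
                         x = object$observation, ...) {
  theta <- predict(object, x = x, n_samples = nsim, seed = seed)
  with_seed(if (is.null(seed)) NULL else seed + 1L,
            run_simulations(object$simulator, theta))
}

#' Plot posterior marginals of a trained estimator
#'
#' One kernel density panel per parameter, with the marginal MAP marked.
#'
#' @param x An [npe()] fit with a stored observation (or pass `obs`).
#' @param obs Observation to condition on.
#' @param n_samples Posterior draws.
#' @param seed Optional seed.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.npe <- function(x, obs = x$observation, n_samples = 5000L,
                     seed = NULL, ...) {
  s <- predict(x, x = obs, n_samples = n_samples, seed = seed)
  d <- ncol(s)
  old <- graphics::par(mfrow = c(1L, d))
  on.exit(graphics::par(old))
  mm <- marginal_map(s)
  for (j in seq_len(d)) {
    de <- stats::density(s[, j])
    graphics::plot(de, main = colnames(s)[j], xlab = colnames(s)[j], ...)
    graphics::abline(v = mm[j], col = "steelblue", lty = 2L)
  }
  invisible(s)
}

#' Residuals of the posterior predictive fit
#'
#' Standardized discrepancies between the stored observation and the
#' posterior predictive distribution: `(x_obs - mean(pred)) / sd(pred)` per
#' data dimension (the signed version of the predictive z-distance).
#'
#' @param object An [npe()] fit with a stored observation.
#' @param nsim Predictive simulations used.
#' @param seed Optional seed.
#' @param ... Unused.
#' @export
residuals.npe <- function(object, nsim = 1000L, seed = NULL, ...) {
  if (is.null(object$observation)) {
    stop("no stored observation", call. = FALSE)
  }
  pred <- simulate.npe(object, nsim = nsim, seed = seed)
  x <- object$observation
  if (inherits(x, "data.frame")) x <- as_observation(x)
  (as.numeric(x) - colMeans(pred)) / apply(pred, 2L, stats::sd)
}
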