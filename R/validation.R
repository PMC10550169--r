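#' Classifier two-sample test (C2ST)
#'
#' Measures how distinguishable two sample sets are by the held-out accuracy
#' of a small neural-network classifier (single hidden layer of `hidden`
#' units, 10x the data dimension by default), 5-fold cross-validated on
#' balanced classes. Accuracy near 0.5 means the two distributions are
#' indistinguishable to the classifier; accuracy near 1 means disjoint.
#'
#' @param samples_a,samples_b Matrices with equal numbers of columns.
#' @param seed Optional seed (fold assignment and network init).
#' @param folds Cross-validation folds.
#' @param hidden Hidden units; default `10 * ncol`.
#' @param maxit Training iterations per fold.
#' @return An object of class `c2st_result` with `accuracy`, `n_per_class`,
#'   `folds`, `hidden`.
#' @export
c2st <- function(samples_a, samples_b, seed = NULL, folds = 5L,
                 hidden = NULL, maxit = 200L) {
  a <- as.matrix(samples_a); b <- as.matrix(samples_b)
  if (ncol(a) != ncol(b)) {
    stop("samples_a and samples_b must have the same dimensionality",
         call. = FALSE)
  }
  n <- min(nrow(a), nrow(b))
  if (n < 500L) {
    warning("fewer than 500 samples per class; C2ST accuracy will be noisy",
            call. = FALSE)
  }
  hidden <- hidden %||% max(2L, 10L * ncol(a))
  acc <- with_seed(seed, {
    a <- a[sample.int(nrow(a), n), , drop = FALSE]
    b <- b[sample.int(nrow(b), n), , drop = FALSE]
    xx <- rbind(a, b)
    sc <- zscore_fit(xx)
    xx <- zscore_apply(xx, sc)
    yy <- factor(rep(c("a", "b"), each = n))
    fold <- rep(rep(seq_len(folds), length.out = n), 2L)
    vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- nnet::nnet(xx[tr, , drop = FALSE], class_indicator(yy[tr]),
                        size = hidden, softmax = TRUE, maxit = maxit,
                        decay = 1e-4, trace = FALSE, MaxNWts = 100000L)
      pr <- stats::predict(fit, xx[!tr, , drop = FALSE])
      mean((pr[, "a"] > 0.5) == (yy[!tr] == "a"))
    }, numeric(1L)) |> mean()
  })
  structure(list(accuracy = acc, n_per_class = n, folds = folds,
                 hidden = hidden),
            class = "c2st_result")
}

class_indicator <- function(y) {
  out <- stats::model.matrix(~ y - 1)
  colnames(out) <- levels(y)
  out
}

#' @export
print.c2st_result <- function(x, ...) {
  cat(sprintf("C2ST accuracy: %.3f (%d per class, %d-fold CV, %d hidden units)\n",
              x$accuracy, x$n_per_class, x$folds, x$hidden))
  invisible(x)
}

#' Simulation-based calibration (SBC)
#'
#' Checks that the estimator's posterior uncertainties are well-calibrated on
#' average: for `N` independent runs it draws a ground-truth parameter from
#' the prior, simulates an observation, draws `L` posterior samples at that
#' observation, and records the rank of the ground truth among them. Under a
#' calibrated posterior the ranks are uniform on \{0, ..., L\}; uniformity is
#' scored per parameter with a Kolmogorov-Smirnov test on the (randomized,
#' hence exactly continuous under the null) normalized ranks.
#'
#' @param estimator An amortized [npe()] fit (sequential fits are refused),
#'   or `NULL` when a custom `sampler` is given.
#' @param prior Prior the ground truths are drawn from.
#' @param simulator Simulator closure.
#' @param N Number of SBC runs.
#' @param L Posterior samples per run.
#' @param seed Optional seed.
#' @param sampler Optional override, `function(x, L)` returning an `L` x d
#'   matrix of posterior draws; used to calibrate non-NPE posteriors (e.g.
#'   analytic ones) or deliberately miscalibrated controls.
#' @return An `sbc_result`: `ranks` (N x d), `L`, `ks_p` per parameter, and
#'   the maximum ECDF deviation per parameter.
#' @export
run_sbc <- function(estimator, prior, simulator, N = 200L, L = 500L,
                    seed = NULL, sampler = NULL) {
  if (is.null(sampler)) {
    stopifnot(inherits(estimator, "npe"))
    if (!estimator$amortized) {
      stop("SBC requires an amortized estimator (single-round NPE)",
           call. = FALSE)
    }
    sampler <- function(x, L) predict(estimator, x, n_samples = L)
  }
  d <- prior$dim
  with_seed(seed, {
    ranks <- matrix(NA_integer_, N, d,
                    dimnames = list(NULL, prior$labels))
    for (i in seq_len(N)) {
      th <- sample_prior(prior, 1L)
      x <- simulator(as.numeric(th))
      ps <- sampler(as.numeric(x), L)
      ranks[i, ] <- colSums(sweep(ps, 2L, as.numeric(th), "<"))
    }
    u <- (ranks + matrix(stats::runif(N * d), N, d)) / (L + 1)
    ks_p <- vapply(seq_len(d), function(j) {
      stats::ks.test(u[, j], "punif")$p.value
    }, numeric(1L))
    ecdf_dev <- vapply(seq_len(d), function(j) {
      s <- sort(u[, j])
      max(abs(s - seq_len(N) / N))
    }, numeric(1L))
    structure(list(ranks = ranks, N = N, L = L,
                   ks_p = stats::setNames(ks_p, prior$labels),
                   ecdf_dev = stats::setNames(ecdf_dev, prior$labels)),
              class = "sbc_result")
  })
}

#' @export
print.sbc_result <- function(x, ...) {
  cat(sprintf("SBC: %d runs, %d posterior samples each\n", x$N, x$L))
  cat("  KS uniformity p-values:",
      paste(sprintf("%s = %.3g", names(x$ks_p), x$ks_p), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank-ECDF plot of an SBC result
#' @param x An [run_sbc()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sbc_result <- function(x, ...) {
  d <- ncol(x$ranks)
  old <- graphics::par(mfrow = c(1L, d))
  on.exit(graphics::par(old))
  band <- 1.63 / sqrt(x$N)  # ~99% Kolmogorov band
  for (j in seq_len(d)) {
    u <- sort((x$ranks[, j] + 0.5) / (x$L + 1))
    graphics::plot(u, seq_along(u) / length(u), type = "s",
                   xlab = "normalized rank", ylab = "ECDF",
                   main = colnames(x$ranks)[j], ...)
    graphics::abline(0, 1, col = "grey")
    graphics::abline(band, 1, col = "grey", lty = 2L)
    graphics::abline(-band, 1, col = "grey", lty = 2L)
  }
  invisible(x)
}

#' Prior predictive check
#'
#' Simulates `n` observations with parameters drawn from the prior and
#' checks whether the observed data lies inside the simulated range in every
#' dimension; a coordinate outside the attainable range flags model (or
#' prior) misspecification.
#'
#' @param prior Prior distribution.
#' @param simulator Simulator closure.
#' @param x_obs Observed data vector (or `measured_data`).
#' @param n Number of prior predictive simulations.
#' @param seed Optional seed.
#' @return A `predictive_check` object with the simulated matrix, per
#'   dimension ranges, and the misspecification flag.
#' @export
prior_predictive_check <- function(prior, simulator, x_obs, n = 1000L,
                                   seed = NULL) {
  if (inherits(x_obs, "data.frame")) x_obs <- as_observation(x_obs)
  x_obs <- as.numeric(x_obs)
  sims <- with_seed(seed, {
    theta <- sample_prior(prior, n)
    run_simulations(simulator, theta)
  })
  lo <- apply(sims, 2L, min); hi <- apply(sims, 2L, max)
  inside <- x_obs >= lo & x_obs <= hi
  structure(list(kind = "prior", simulations = sims, x_obs = x_obs,
                 range_lower = lo, range_upper = hi, inside = inside,
                 flagged = !all(inside)),
            class = "predictive_check")
}

#' Posterior predictive check
#'
#' Simulates data with parameters drawn from the posterior and reports the
#' per-dimension z-distance `|mean(pred) - x_obs| / sd(pred)`. A dimension
#' passes when its observation lies within one predictive standard deviation
#' of the predictive mean.
#'
#' @param posterior An [npe()] fit, or a matrix of posterior parameter
#'   draws.
#' @param simulator Simulator closure (defaults to the fit's).
#' @param x_obs Observed data.
#' @param n Predictive simulations.
#' @param seed Optional seed.
#' @return A `predictive_check` with `z` distances, `pass` flags and
#'   `degenerate` flags (zero predictive spread).
#' @export
posterior_predictive_check <- function(posterior, simulator = NULL, x_obs,
                                       n = 1000L, seed = NULL) {
  if (inherits(x_obs, "data.frame")) x_obs <- as_observation(x_obs)
  x_obs <- as.numeric(x_obs)
  if (inherits(posterior, "npe")) {
    simulator <- simulator %||% posterior$simulator
    theta <- predict(posterior, x = x_obs, n_samples = n, seed = seed)
  } else {
    theta <- as.matrix(posterior)
    if (nrow(theta) < n) n <- nrow(theta)
    theta <- theta[seq_len(n), , drop = FALSE]
  }
  if (is.null(simulator)) stop("simulator required", call. = FALSE)
  pred <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                    run_simulations(simulator, theta))
  mu <- colMeans(pred); sdev <- apply(pred, 2L, stats::sd)
  degenerate <- sdev < 1e-12
  z <- abs(mu - x_obs) / ifelse(degenerate, 1, sdev)
  z[degenerate & abs(mu - x_obs) < 1e-12] <- 0
  structure(list(kind = "posterior", simulations = pred, x_obs = x_obs,
                 z = z, pass = z <= 1, degenerate = degenerate),
            class = "predictive_check")
}

#' @export
print.predictive_check <- function(x, ...) {
  if (x$kind == "prior") {
    cat(sprintf("Prior predictive check over %d simulations: %s\n",
                nrow(x$simulations),
                if (x$flagged) "FLAGGED (observation outside simulated range)"
                else "observation inside simulated range"))
  } else {
    cat("Posterior predictive z-distances:\n")
    print(signif(x$z, 3))
    cat(sprintf("  %d of %d dimensions within one predictive SD\n",
                sum(x$pass), length(x$pass)))
  }
  invisible(x)
}

#' Pearson correlation structure of posterior samples
#'
#' @param samples Matrix of posterior draws (>= 2 rows).
#' @return Symmetric correlation matrix; dimensions with zero variance give
#'   `NA` entries and a warning.
#' @export
posterior_correlations <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(samples, 2L, stats::sd)
  if (any(sds < 1e-12)) {
    warning("zero-variance dimension(s): correlation undefined (NA)",
            call. = FALSE)
  }
  suppressWarnings(stats::cor(samples))
}

#' Conditional correlation of a 3-parameter posterior
#'
#' Pearson correlation of the two free parameters under the posterior with
#' the third held at a fixed value. For raw samples the conditional is
#' approximated by a slab `|theta_fix - value| < eps`, with `eps` grown
#' adaptively until at least `min_slab` samples fall inside. For a trained
#' [npe()] estimator the mixture conditional is computed exactly and
#' sampled.
#'
#' @param posterior A matrix of posterior draws with 3 columns, or an
#'   [npe()] fit over 3 parameters.
#' @param fix_dim Index (1-3) of the parameter to hold fixed.
#' @param fix_value Value to condition on.
#' @param x Observation (npe method; defaults to the stored one).
#' @param n Samples drawn from the exact conditional (npe method).
#' @param min_slab Minimum slab occupancy (sample method).
#' @param seed Optional seed.
#' @param ... Passed on.
#' @return Scalar Pearson correlation of the two free parameters.
#' @export
conditional_correlation <- function(posterior, fix_dim, fix_value, ...) {
  UseMethod("conditional_correlation")
}

#' @rdname conditional_correlation
#' @export
conditional_correlation.npe <- function(posterior, fix_dim, fix_value,
                                        x = posterior$observation,
                                        n = 10000L, seed = NULL, ...) {
  if (inherits(x, "data.frame")) x <- as_observation(x)
  z_fix <- prior_to_unconstrained(posterior$prior,
                                  insert_at(rep(1, posterior$prior$dim),
                                            fix_dim, fix_value))[, fix_dim]
  s <- mdn_conditional_sample(posterior$mdn, as.numeric(x), fix_dim, z_fix,
                              n, seed = seed)
  # back-transform free dims to the original scale
  free <- setdiff(seq_len(posterior$prior$dim), fix_dim)
  full <- matrix(z_fix, n, posterior$prior$dim)
  full[, free] <- s
  th <- prior_from_unconstrained(posterior$prior, full)
  stats::cor(th[, free[1L]], th[, free[2L]])
}

insert_at <- function(base, at, value) {
  base[at] <- value
  matrix(base, nrow = 1L)
}

#' @rdname conditional_correlation
#' @export
conditional_correlation.default <- function(posterior, fix_dim, fix_value,
                                            min_slab = 500L, ...) {
  s <- as.matrix(posterior)
  if (ncol(s) != 3L) {
    stop("conditional_correlation needs a 3-parameter posterior",
         call. = FALSE)
  }
  dist <- abs(s[, fix_dim] - fix_value)
  eps <- stats::sd(s[, fix_dim]) / 20
  repeat {
    inside <- dist < eps
    if (sum(inside) >= min_slab) break
    if (eps > diff(range(s[, fix_dim]))) {
      stop(sprintf(
        "only %d samples within the widest slab; need >= %d. Draw more posterior samples.",
        sum(inside), min_slab), call. = FALSE)
    }
    eps <- eps * 1.5
  }
  free <- setdiff(1:3, fix_dim)
  stats::cor(s[inside, free[1L]], s[inside, free[2L]])
}

#' Leave-one-measurement-out prediction
#'
#' For each data dimension d: trains an estimator on simulations with
#' dimension d removed, conditions it on the observation minus d, simulates
#' full data vectors from the resulting posterior, and compares the
#' predicted d-th coordinate against the held-out observation (predictive
#' mean, SD and z-distance). Additionally reports, per dimension, the C2ST
#' accuracy between predictions of the full-data posterior and of the
#' held-out posterior — chance level means the held-out measurement was
#' redundant given the others.
#'
#' @param prior Prior distribution.
#' @param simulator Simulator closure returning the full data vector.
#' @param x_obs Full observed data vector.
#' @param config [training_config()] used for every fit.
#' @param n_pred Predictive simulations per posterior.
#' @return A `loo_result`: data frame `held_out`, `pred_mean`, `pred_sd`,
#'   `z`, `c2st_accuracy`, plus the list of per-dimension fits.
#' @export
leave_one_out_prediction <- function(prior, simulator, x_obs,
                                     config = training_config(),
                                     n_pred = 600L) {
  if (inherits(x_obs, "data.frame")) x_obs <- as_observation(x_obs)
  x_obs <- as.numeric(x_obs)
  D <- length(x_obs)
  if (D < 2L) stop("x_obs needs at least 2 dimensions", call. = FALSE)
  full_fit <- npe(simulator, prior, config, observation = x_obs)
  full_pred <- simulate.npe(full_fit, nsim = n_pred,
                            seed = substream_seed(config$seed, "loo_full"))
  fits <- vector("list", D)
  rows <- vector("list", D)
  for (dd in seq_len(D)) {
    sim_d <- local({
      dd_loc <- dd
      f <- function(theta) simulator(theta)[-dd_loc]
      f
    })
    cfg_d <- config
    cfg_d$seed <- substream_seed(config$seed, paste0("loo", dd))
    fit_d <- npe(sim_d, prior, cfg_d, observation = x_obs[-dd])
    fits[[dd]] <- fit_d
    theta_d <- predict(fit_d, n_samples = n_pred,
                       seed = substream_seed(config$seed, paste0("loo_s", dd)))
    pred_d <- with_seed(substream_seed(config$seed, paste0("loo_p", dd)),
                        run_simulations(simulator, theta_d))
    mu <- mean(pred_d[, dd]); sdev <- stats::sd(pred_d[, dd])
    cs <- c2st(full_pred, pred_d,
               seed = substream_seed(config$seed, paste0("loo_c", dd)))
    rows[[dd]] <- data.frame(held_out = dd, pred_mean = mu, pred_sd = sdev,
                             z = abs(mu - x_obs[dd]) /
                               if (sdev > 1e-12) sdev else 1,
                             c2st_accuracy = cs$accuracy)
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 full_fit = full_fit, x_obs = x_obs),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("Leave-one-measurement-out prediction:\n")
  print(signif(x$table, 3))
  invisible(x)
}
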