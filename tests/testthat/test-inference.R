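test_that("reduced log-likelihood matches a textbook Poisson summation", {
  # single combination with unit features: rate 1 for every theta
  one <- data.frame(pre = 1, post = 1, postAll = 1)
  expect_equal(reduced_log_likelihood(c(2, 0.3, 1.7), counts = 0,
                                      features = one), -1)
  feat <- reduced_dso_features()
  expect_equal(nrow(feat), 10L)
  set.seed(5)
  counts <- rpois(10, 1)
  th <- c(1.1, 0.9, 1.05)
  lam <- feat$pre^th[1] * feat$post^th[2] / feat$postAll^th[3]
  textbook <- sum(counts * log(lam) - lam - lfactorial(counts))
  expect_equal(reduced_log_likelihood(th, counts, feat), textbook)
})

test_that("the likelihood is maximized near the generating parameters", {
  feat <- reduced_dso_features()
  feat_big <- feat * 100          # scale features for a sharp likelihood
  th_star <- c(1.05, 0.95, 1.02)
  lam <- dso_rate(feat_big$pre, feat_big$post, feat_big$postAll, th_star)
  counts <- with_seed(6, rpois(10, lam))
  grid <- seq(0.8, 1.2, by = 0.05)
  best <- c(NA, NA, NA); best_ll <- -Inf
  for (a in grid) for (b in grid) for (cc in grid) {
    ll <- reduced_log_likelihood(c(a, b, cc), counts, feat_big)
    if (ll > best_ll) { best_ll <- ll; best <- c(a, b, cc) }
  }
  # asymptotic MLE spread from the Poisson-GLM Fisher information:
  # I(theta*) = X' diag(lambda) X; the grid MLE must sit within three
  # standard errors of the generating parameters (plus the grid step)
  X <- cbind(log(feat_big$pre), log(feat_big$post), -log(feat_big$postAll))
  se <- sqrt(diag(solve(t(X) %*% (lam * X))))
  expect_true(all(abs(best - th_star) <= 3 * se + 0.05))
})

test_that("NPE is amortized and refuses degenerate simulations", {
  prior <- conjugate_prior()
  sim <- conjugate_simulator()
  fit <- npe(sim, prior, training_config(n_simulations = 3000, seed = 2,
                                         hidden_units = 20,
                                         max_epochs = 100))
  s_a <- predict(fit, x = -2, n_samples = 2000, seed = 3)
  s_b <- predict(fit, x = 2, n_samples = 2000, seed = 3)
  expect_gt(abs(mean(s_b) - mean(s_a)), 1)   # conditioning matters
  # all-non-finite simulators abort
  bad <- wiresbi:::simulator_skeleton(function(theta) NaN, 1L, 1L, "x")
  expect_error(suppressWarnings(
    npe(bad, prior, training_config(n_simulations = 200, seed = 1))),
    "non-finite")
  expect_error(npe(sim, prior, training_config(n_simulations = 200,
                                               n_rounds = 2)),
               "snpe")
})

test_that("posterior samples respect bounded prior supports", {
  m <- generate_structural_model(tiny_config(seed = 22))
  simb <- synapse_summary_simulator(m, n_pairs = 15)
  prib <- prior_beta()
  fitb <- npe(simb, prib, training_config(n_simulations = 1500, seed = 5,
                                          max_epochs = 100))
  ps <- predict(fitb, with_seed(1, simb(0.4)), n_samples = 3000, seed = 2)
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("single-round snpe is identical to npe; multi-round contracts", {
  prior <- conjugate_prior()
  sim <- conjugate_simulator()
  cfg <- training_config(n_simulations = 1500, seed = 4, hidden_units = 20,
                         max_epochs = 60)
  f1 <- snpe(sim, prior, x_obs = 1, cfg)
  f2 <- npe(sim, prior, cfg, observation = 1)
  expect_identical(predict(f1, n_samples = 50, seed = 9),
                   predict(f2, x = 1, n_samples = 50, seed = 9))
  cfg3 <- training_config(n_simulations = 4500, seed = 4, n_rounds = 3,
                          hidden_units = 20, max_epochs = 60)
  f3 <- snpe(sim, prior, x_obs = 1, cfg3)
  expect_false(f3$amortized)
  ps <- predict(f3, n_samples = 4000, seed = 10)
  expect_lt(var(ps[, 1]), prior_variance(prior))
  expect_error(run_sbc(f3, prior, sim, N = 5, L = 10), "amortized")
})

test_that("slice-sampling MCMC reproduces conjugate posteriors", {
  prior <- conjugate_prior()
  # Gaussian likelihood x_obs = 1.2 with unit noise: posterior N(0.6, 1/2)
  ref <- mcmc_reference_posterior(
    counts = NULL, prior, n_iter = 1200, seed = 3,
    log_likelihood = function(theta) dnorm(1.2, theta[1], 1, log = TRUE))
  expect_lt(abs(mean(ref) - 0.6), 0.01 * abs(0.6) + 0.01)
  expect_lt(abs(sd(ref) - sqrt(0.5)), 0.03)
  expect_true(all(attr(ref, "rhat") < 1.01))
  # flat likelihood: posterior is the prior
  flat <- mcmc_reference_posterior(
    counts = NULL, prior, n_iter = 1200, seed = 4,
    log_likelihood = function(theta) 0)
  pr <- sample_prior(prior, 4000, seed = 5)
  cs <- c2st(matrix(flat[sample(nrow(flat), 4000), ], ncol = 1), pr,
             seed = 6)
  expect_lte(cs$accuracy, 0.55)
})

test_that("MCMC on the reduced simulator recovers the generating parameters", {
  prior <- prior_gaussian()
  sim <- reduced_simulator()
  counts <- with_seed(31, sim(c(1, 1, 1)))
  ref <- mcmc_reference_posterior(counts, prior, n_iter = 1200, seed = 7)
  mu <- colMeans(ref); sdev <- apply(ref, 2, sd)
  expect_true(all(abs(mu - 1) <= 3 * sdev))
})

test_that("marginal_map finds modes of known shapes", {
  set.seed(8)
  s <- cbind(rnorm(1e5, 2, sqrt(0.1)))
  expect_lt(abs(marginal_map(s) - 2), 0.05)
  expect_equal(unname(marginal_map(matrix(3.3, 2000, 1))), 3.3)
  mix <- matrix(c(rnorm(90000, 0, 0.1), rnorm(10000, 5, 0.1)), ncol = 1)
  expect_lt(abs(marginal_map(mix) - 0), 0.1)
  expect_error(marginal_map(matrix(1:10)), "1,000")
})
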