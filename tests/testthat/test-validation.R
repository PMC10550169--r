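test_that("C2ST sits at chance for identical distributions and detects separation", {
  set.seed(1)
  pool <- matrix(rnorm(4000), ncol = 2)
  cs <- c2st(pool[1:1000, ], pool[1001:2000, ], seed = 2)
  expect_gte(cs$accuracy, 0.45)
  expect_lte(cs$accuracy, 0.55)
  far <- c2st(matrix(rnorm(1000, -10), ncol = 1),
              matrix(rnorm(1000, 10), ncol = 1), seed = 3)
  expect_gte(far$accuracy, 0.99)
  expect_error(c2st(matrix(1:10, ncol = 1), matrix(1:10, ncol = 2)),
               "dimensionality")
})

test_that("C2ST is symmetric and never far below chance", {
  set.seed(4)
  a <- matrix(rnorm(2000, 0, 1), ncol = 2)
  b <- matrix(rnorm(2000, 0.3, 1.2), ncol = 2)
  c_ab <- c2st(a, b, seed = 5)$accuracy
  c_ba <- c2st(b, a, seed = 5)$accuracy
  expect_lt(abs(c_ab - c_ba), 0.02)
  expect_gte(c_ab, 0.5 - 0.03)
})

test_that("SBC passes for the exact posterior and fails when overconfident", {
  prior <- conjugate_prior()
  sim <- conjugate_simulator()
  ok <- run_sbc(NULL, prior, sim, N = 300, L = 500, seed = 9,
                sampler = conjugate_posterior_sampler)
  expect_true(all(ok$ks_p > 0.01))
  expect_true(all(ok$ranks >= 0 & ok$ranks <= ok$L))
  over <- function(x, L) matrix(rnorm(L, x / 2, 0.5 * sqrt(0.5)), ncol = 1)
  bad <- run_sbc(NULL, prior, sim, N = 300, L = 500, seed = 9,
                 sampler = over)
  expect_true(any(bad$ks_p < 0.01))
  one <- run_sbc(NULL, prior, sim, N = 1, L = 100, seed = 2,
                 sampler = conjugate_posterior_sampler)
  expect_true(one$ranks >= 0 && one$ranks <= 100)
})

test_that("prior predictive checks flag only unattainable observations", {
  prior <- conjugate_prior()
  sim <- conjugate_simulator()
  x_self <- with_seed(3, sim(as.numeric(sample_prior(prior, 1, seed = 2))))
  ck <- prior_predictive_check(prior, sim, x_self, n = 500, seed = 4)
  expect_false(ck$flagged)
  # probability-valued simulator can never reach 2.0
  m <- generate_structural_model(tiny_config(seed = 23))
  simb <- synapse_summary_simulator(m, n_pairs = 15)
  ck2 <- prior_predictive_check(prior_beta(), simb, rep(2.0, 7), n = 100,
                                seed = 5)
  expect_true(ck2$flagged)
  # repeated self-consistency: prior-simulated pseudo-observations land
  # inside the prior predictive range nearly always
  hits <- with_seed(6, vapply(seq_len(100), function(r) {
    xo <- sim(as.numeric(sample_prior(prior, 1)))
    !prior_predictive_check(prior, sim, xo, n = 400)$flagged
  }, logical(1L)))
  expect_gte(mean(hits), 0.95)
})

test_that("posterior predictive z behaves at the two extremes", {
  # deterministic simulator + point-mass posterior at truth: z = 0
  det <- wiresbi:::simulator_skeleton(function(theta) c(theta, theta^2),
                                      2L, 1L, c("a", "b"))
  point <- matrix(2, 1000, 1)
  ck <- posterior_predictive_check(point, det, x_obs = c(2, 4), n = 1000)
  expect_true(all(ck$degenerate))
  expect_equal(unname(ck$z), c(0, 0))
  # prior instead of posterior on an informative problem: some z > 1
  prior <- conjugate_prior()
  siminf <- wiresbi:::simulator_skeleton(
    function(theta) theta + stats::rnorm(1, 0, 0.05), 1L, 1L, "x")
  pr <- sample_prior(prior, 1000, seed = 7)
  ck2 <- posterior_predictive_check(pr, siminf, x_obs = 2.5, n = 1000,
                                    seed = 8)
  expect_true(any(ck2$z > 1))
})

test_that("posterior correlations have the exact structure of their samples", {
  set.seed(9)
  s <- matrix(rnorm(3e4), ncol = 3)
  pc <- posterior_correlations(s)
  expect_equal(diag(pc), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(abs(pc[upper.tri(pc)]) < 4 / sqrt(1e4)))
  xy <- cbind(s[, 1], s[, 1])
  expect_equal(posterior_correlations(xy)[1, 2], 1)
  xmy <- cbind(s[, 1], -s[, 1])
  expect_equal(posterior_correlations(xmy)[1, 2], -1)
  expect_warning(posterior_correlations(cbind(s[, 1], 0)), "zero-variance")
})

test_that("conditional correlations match Gaussian closed forms", {
  S <- matrix(c(1, -0.2, 0.6,
                -0.2, 1, 0.6,
                0.6, 0.6, 1), 3, 3)
  cc_true <- (S[1, 2] - S[1, 3] * S[2, 3]) /
    sqrt((1 - S[1, 3]^2) * (1 - S[2, 3]^2))
  s <- MASS::mvrnorm(2e5, rep(0, 3), S, empirical = TRUE)
  expect_lt(abs(conditional_correlation(s, 3, 0) - cc_true), 0.02)
  # independent dimensions: conditional correlation is zero
  s0 <- matrix(rnorm(3e5), ncol = 3)
  expect_lt(abs(conditional_correlation(s0, 3, 0)), 0.03)
  # a deterministic constraint theta1 + theta2 = const gives -1
  z <- rnorm(5000)
  s1 <- cbind(z, 1 - z, rnorm(5000))
  expect_lt(abs(conditional_correlation(s1, 3, 0) - (-1)), 0.01)
  expect_error(conditional_correlation(matrix(rnorm(200), ncol = 2), 1, 0),
               "3-parameter")
  expect_error(conditional_correlation(matrix(rnorm(300), ncol = 3), 3, 1e6),
               "slab")
})

test_that("leave-one-out predicts redundant dimensions at chance C2ST", {
  prior <- conjugate_prior()
  # two perfectly redundant output dimensions
  simr <- wiresbi:::simulator_skeleton(function(theta) {
    v <- theta + stats::rnorm(1, 0, 0.1); c(v, v)
  }, 2L, 1L, c("a", "b"))
  loo <- leave_one_out_prediction(prior, simr, c(0.5, 0.5),
                                  training_config(n_simulations = 2000,
                                                  seed = 11,
                                                  hidden_units = 20,
                                                  max_epochs = 80),
                                  n_pred = 600)
  expect_equal(nrow(loo$table), 2L)
  expect_equal(length(loo$fits), 2L)
  expect_true(all(loo$table$z < 1))
  expect_true(all(loo$table$c2st_accuracy < 0.58))
  expect_error(leave_one_out_prediction(prior, simr, 0.5), "2 dimensions")
})

test_that("a dimension independent of the parameters keeps its prior spread", {
  prior <- conjugate_prior()
  # dim 1 informative, dim 2 pure noise
  simi <- wiresbi:::simulator_skeleton(function(theta) {
    c(theta + stats::rnorm(1, 0, 0.1), stats::rnorm(1, 0, 1))
  }, 2L, 1L, c("inf", "noise"))
  loo <- leave_one_out_prediction(prior, simi, c(0.3, 0.0),
                                  training_config(n_simulations = 2000,
                                                  seed = 12,
                                                  hidden_units = 20,
                                                  max_epochs = 80),
                                  n_pred = 600)
  # held-out noise dimension is predicted with roughly its marginal SD (1)
  expect_gt(loo$table$pred_sd[2], 0.7)
})
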