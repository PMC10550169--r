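test_that("exhaustive population probabilities match enumeration", {
  cc <- toy_connectome()            # 5 of the 12 pairs connected
  spec <- toy_spec()
  expect_equal(population_connection_probability(cc, spec, n_pairs = 12),
               5 / 12)
  expect_warning(
    p <- population_connection_probability(cc, spec, n_pairs = 50),
    "using all")
  expect_equal(p, 5 / 12)
  # fully connected and empty connectomes
  full <- toy_connectome(connected = as.matrix(expand.grid(i = 1:3, j = 4:7)))
  expect_equal(population_connection_probability(full, spec, 12), 1.0)
  none <- toy_connectome(connected = cbind(i = integer(0), j = integer(0)))
  expect_equal(population_connection_probability(none, spec, 12), 0.0)
})

test_that("pair-sampled estimator is unbiased against the exhaustive fraction", {
  cc <- toy_connectome()
  spec <- toy_spec()
  est <- vapply(seq_len(1e4), function(s) {
    population_connection_probability(cc, spec, n_pairs = 6, seed = s)
  }, numeric(1L))
  # sampling 6 of 12 pairs without replacement: hypergeometric SE
  p <- 5 / 12
  se_mean <- sqrt(p * (1 - p) / 6 * (12 - 6) / (12 - 1)) / sqrt(1e4)
  expect_lt(abs(mean(est) - p), 4 * se_mean)
})

test_that("summaries are ordered, deterministic and match brute force", {
  m <- generate_structural_model(tiny_config(seed = 21))
  cc <- simulate_dso(m, c(1, 1, 1), seed = 3)
  specs <- default_population_specs(m)
  s1 <- summarize_connectome(cc, specs, n_pairs = 10, seed = 7)
  s2 <- summarize_connectome(cc, specs, n_pairs = 10, seed = 7)
  expect_identical(s1, s2)
  expect_equal(s1$label, vapply(specs, `[[`, character(1), "label"))
  # exhaustive summary equals per-population brute-force fractions
  sx <- suppressWarnings(   # "using all pairs" is the point here
    summarize_connectome(cc, specs, n_pairs = 1e9, seed = 1))
  cp <- connected_pairs(cc)
  key <- paste(cp$i, cp$j)
  brute <- vapply(specs, function(sp) {
    pairs <- expand.grid(i = sp$pre_ids, j = sp$post_ids)
    mean(paste(pairs$i, pairs$j) %in% key)
  }, numeric(1L))
  expect_equal(sx$probability, brute)
  expect_error(summarize_connectome(cc, list()), "nonempty")
})

test_that("adding synapses never decreases exhaustive probabilities", {
  base <- cbind(i = c(1, 2), j = c(4, 5))
  more <- rbind(base, cbind(i = 3, j = 6))
  p1 <- population_connection_probability(toy_connectome(base), toy_spec(), 12)
  p2 <- population_connection_probability(toy_connectome(more), toy_spec(), 12)
  expect_gte(p2, p1)
})

test_that("expected measurement SD is the binomial standard error", {
  expect_equal(expected_measurement_sd(0.5, 50), sqrt(0.25 / 50))
  expect_equal(expected_measurement_sd(0, 17), 0)
  expect_equal(expected_measurement_sd(1, 50), 0)
})

test_that("measured data validates its fields", {
  md <- measured_data(c("L4", "L5PT"), c(0.2, 0.4))
  expect_s3_class(md, "measured_data")
  expect_equal(as_observation(md), c(L4 = 0.2, L5PT = 0.4))
  expect_error(measured_data(c("a", "a"), c(0.1, 0.2)), "unique")
  expect_error(measured_data("a", 1.7), "0, 1")
  expect_error(population_spec("x", integer(0), 1:2), "nonempty")
})
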