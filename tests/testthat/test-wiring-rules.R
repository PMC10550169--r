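test_that("dso_rate reproduces hand-computed rates and edge cases", {
  expect_equal(dso_rate(2, 3, 6, c(1, 1, 1)), 1.0)
  expect_equal(dso_rate(0, 5, 10, c(2, 0.3, 1)), 0.0)
  expect_equal(dso_rate(2, 2, 4, c(2, 1, 1)), 2.0)
  expect_equal(dso_rate(5, 0, 0, c(1, 1, 1)), 0.0)  # zero post is fine
  expect_error(dso_rate(2, 3, 0, c(1, 1, 1)), "postAll")
  expect_warning(r <- dso_rate(1e4, 1e4, 1, c(1, 1, 1)), "ceiling")
  expect_equal(r, 1e6)
})

test_that("the log-linear feature matrix is exactly equivalent to the rule", {
  pre <- matrix(1, 1, 1); post <- matrix(1, 1, 1)
  fm1 <- build_feature_matrix(manual_model(pre, post))
  expect_equal(nrow(fm1$X), 1L)
  expect_equal(unname(fm1$X[1, ]), c(0, 0, 0))
  # exp(theta' X) == dso_rate on random features and random theta
  set.seed(42)
  n <- 1000
  feat <- data.frame(pre = sample(1:30, n, TRUE),
                     post = sample(1:30, n, TRUE),
                     postAll = sample(30:500, n, TRUE))
  X <- cbind(log(feat$pre), log(feat$post), -log(feat$postAll))
  thetas <- MASS::mvrnorm(100, c(1, 1, 1), diag(0.05, 3))
  worst <- 0
  for (r in seq_len(nrow(thetas))) {
    th <- thetas[r, ]
    glm_rate <- exp(as.vector(X %*% th))
    direct <- dso_rate(feat$pre, feat$post, feat$postAll, th)
    worst <- max(worst, max(abs(glm_rate - direct) / direct))
  }
  expect_lt(worst, 1e-9)
})

test_that("feature matrix only contains co-occupied combinations", {
  m <- generate_structural_model(tiny_config(seed = 11))
  fm <- build_feature_matrix(m)
  expect_true(all(fm$pre > 0))
  expect_true(all(fm$post > 0))
  # brute-force row count over all (i, j, k)
  occ_pre <- as.matrix(m$pre) > 0
  occ_post <- as.matrix(m$post) > 0
  brute <- sum(colSums(occ_pre) * colSums(occ_post))
  expect_equal(nrow(fm$X), brute)
})

test_that("DSO simulation is deterministic, Poisson-distributed, empty at rate 0", {
  m <- generate_structural_model(tiny_config(seed = 12))
  c1 <- simulate_dso(m, c(1, 1, 1), seed = 5)
  c2 <- simulate_dso(m, c(1, 1, 1), seed = 5)
  expect_identical(c1$synapses, c2$synapses)
  # disjoint model: all rates zero -> empty connectome
  pre <- matrix(c(3, 0), 1); post <- matrix(c(0, 2), 1)
  empty <- simulate_dso(manual_model(pre, post), c(1, 1, 1), seed = 1)
  expect_equal(nrow(empty$synapses), 0L)
  # law of large numbers at constant rate 0.5 over 10^4 combinations:
  # pre = 1, post = 2, and a second postsynaptic neuron raises postAll to 4
  n <- 1e4
  mm <- manual_model(matrix(1, 1, n),
                     rbind(matrix(2, 1, n), matrix(2, 1, n)),
                     grid_dims = c(n, 1, 1))
  expect_equal(unique(mm$postAll), 4)
  cc <- simulate_dso(mm, c(1, 1, 1), seed = 9)
  mean_count <- sum(cc$synapses$count[cc$synapses$j == 2]) / n
  expect_lt(abs(mean_count - 0.5), 4 * sqrt(0.5 / n))
})

test_that("neuron-level threshold rule applies a strict inequality", {
  # one pair sharing exactly 3 subvolumes
  pre <- matrix(c(1, 1, 1, 0), 1); post <- matrix(c(2, 2, 2, 2), 1)
  m <- manual_model(pre, post)
  expect_equal(nrow(simulate_neuron_level(m, 1)$synapses), 1L)   # 3 > 1
  expect_equal(nrow(simulate_neuron_level(m, 3)$synapses), 0L)   # 3 > 3 fails
  # v = 1: strictness means theta_thres = 1 does NOT connect
  pre1 <- matrix(c(1, 0), 1); post1 <- matrix(c(1, 1), 1)
  m1 <- manual_model(pre1, post1)
  expect_equal(nrow(simulate_neuron_level(m1, 1)$synapses), 0L)
  # theta_thres = 0 connects exactly the pairs with v >= 1 (Peters predicate)
  m2 <- generate_structural_model(tiny_config(seed = 13))
  t0 <- simulate_neuron_level(m2, 0)$synapses
  pet <- peters_rule_neuron(m2)$synapses
  expect_equal(t0[order(t0$i, t0$j), ], pet[order(pet$i, pet$j), ],
               ignore_attr = TRUE)
})

test_that("raising the threshold never adds connections", {
  m <- generate_structural_model(tiny_config(seed = 14))
  prev <- Inf
  for (thres in c(0, 1, 2, 5, 10, 50)) {
    n_conn <- nrow(simulate_neuron_level(m, thres)$synapses)
    expect_lte(n_conn, prev)
    prev <- n_conn
  }
})

test_that("synapse-level Bernoulli rule has the right limits and totals", {
  m <- generate_structural_model(tiny_config(seed = 15))
  fm <- build_feature_matrix(m)
  all_on <- simulate_synapse_level(m, 1, seed = 1)
  expect_equal(nrow(all_on$synapses), nrow(fm$X))   # Peters' limit
  expect_equal(nrow(simulate_synapse_level(m, 0, seed = 1)$synapses), 0L)
  pet <- peters_rule_synapse(m)
  expect_equal(sum(pet$synapses$count), nrow(fm$X))
  # binomial expectation on 10^4 co-occupancies
  n <- 1e4
  mm <- manual_model(matrix(1, 1, n), matrix(1, 1, n),
                     grid_dims = c(n, 1, 1))
  cc <- simulate_synapse_level(mm, 0.5, seed = 3)
  expect_lt(abs(sum(cc$synapses$count) - n * 0.5), 4 * sqrt(n * 0.25))
})

test_that("pairwise connection probability is 1 - (1 - p)^m", {
  p <- 0.3
  for (m_cooc in c(1L, 2L, 5L)) {
    mm <- manual_model(matrix(1, 1, m_cooc), matrix(1, 1, m_cooc),
                       grid_dims = c(m_cooc, 1, 1))
    hits <- with_seed(100 + m_cooc, {
      vapply(seq_len(1e4), function(s) {
        nrow(connected_pairs(simulate_synapse_level(mm, p))) > 0
      }, logical(1L))
    })
    expected <- 1 - (1 - p)^m_cooc
    expect_lt(abs(mean(hits) - expected),
              4 * sqrt(expected * (1 - expected) / 1e4))
  }
})

test_that("depth profiles conserve totals and refine consistently", {
  m <- generate_structural_model(tiny_config(seed = 16))
  cc <- simulate_dso(m, c(1, 1, 1), seed = 2)
  depth <- m$grid$dims[3] * m$grid$edge_length
  one <- depth_profile(cc, m, bin_width = depth)
  expect_equal(nrow(one), 1L)
  expect_equal(one$synapses, sum(cc$synapses$count))
  expect_equal(one$boutons, sum(m$pre))
  fine <- depth_profile(cc, m, bin_width = m$grid$edge_length)
  expect_equal(sum(fine$synapses), one$synapses)
  expect_equal(sum(fine$boutons), one$boutons)
  # coarse bins equal summed fine bins
  mid <- depth_profile(cc, m, bin_width = 2 * m$grid$edge_length)
  grp <- rep(seq_len(nrow(mid)), each = 2)[seq_len(nrow(fine))]
  expect_equal(mid$synapses, as.vector(tapply(fine$synapses, grp, sum)))
  expect_error(depth_profile(cc, m, bin_width = 0), "bin_width")
  expect_error(depth_profile(peters_rule_neuron(m), m, 10), "per-subvolume")
})

test_that("Peters' rule dominates sparser Bernoulli rules bin-wise in expectation", {
  m <- generate_structural_model(tiny_config(seed = 17))
  bw <- 2 * m$grid$edge_length
  pet <- depth_profile(peters_rule_synapse(m), m, bw)$synapses
  acc <- 0
  for (r in 1:100) {
    acc <- acc + depth_profile(simulate_synapse_level(m, 0.4, seed = 200 + r),
                               m, bw)$synapses
  }
  expect_true(all(pet >= acc / 100))
})
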