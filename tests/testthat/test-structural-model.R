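test_that("model generation is deterministic given the seed", {
  m1 <- generate_structural_model(tiny_config(seed = 4))
  m2 <- generate_structural_model(tiny_config(seed = 4))
  m3 <- generate_structural_model(tiny_config(seed = 5))
  expect_identical(Matrix::summary(m1$pre), Matrix::summary(m2$pre))
  expect_identical(Matrix::summary(m1$post), Matrix::summary(m2$post))
  expect_identical(m1$postAll, m2$postAll)
  expect_false(identical(Matrix::summary(m1$pre), Matrix::summary(m3$pre)))
})

test_that("invalid configurations are rejected", {
  pops <- default_populations()
  pops$n[2] <- 0
  expect_error(model_config(populations = pops), "at least one neuron")
  pops <- default_populations()
  pops$occupancy[1] <- 1.5
  expect_error(model_config(populations = pops), "occupancy")
  expect_error(model_config(populations = default_populations()[1, ]),
               "postsynaptic")
})

test_that("roles separate the feature maps and postAll matches brute force", {
  m <- generate_structural_model(tiny_config(seed = 2))
  is_pre <- m$neurons$role == "presynaptic"
  expect_equal(sum(m$pre[!is_pre, ]), 0)
  expect_equal(sum(m$post[is_pre, ]), 0)
  # brute-force per-subvolume summation over postsynaptic neurons
  post_dense <- as.matrix(m$post)
  brute <- colSums(post_dense[m$neurons$role == "postsynaptic", , drop = FALSE])
  expect_equal(unname(m$postAll), unname(brute))
  # every stored subvolume id exists in the grid
  K <- prod(m$grid$dims)
  expect_true(all(Matrix::summary(m$pre)$j %in% seq_len(K)))
  expect_true(all(Matrix::summary(m$post)$j %in% seq_len(K)))
})

test_that("forced footprints share exactly the expected subvolume", {
  # 1 presynaptic neuron on subvolumes {1, 2}, 1 postsynaptic on {2, 3}
  pre <- matrix(0, 1, 4); pre[1, c(1, 2)] <- c(2, 3)
  post <- matrix(0, 1, 4); post[1, c(2, 3)] <- c(1, 4)
  m <- manual_model(pre, post)
  expect_equal(shared_subvolumes(m, 1, 2), 1L)
})

test_that("per-subvolume counts match the configured shifted-NB mean", {
  cfg <- tiny_config(seed = 8, n_pre = 60, n_post = 60,
                     grid = c(12, 12, 12), edge = 8)
  m <- generate_structural_model(cfg)
  pops <- cfg$populations
  x <- m$post@x          # postsynaptic counts, all populations share mean 3
  expect_gt(length(x), 1e4)
  mu <- pops$count_mean[2]
  sd1 <- sqrt((mu - 1) + (mu - 1)^2 / pops$count_dispersion[2])
  expect_lt(abs(mean(x) - mu), 3 * sd1 / sqrt(length(x)))
})

test_that("coarsening conserves totals and matches brute-force aggregation", {
  m <- generate_structural_model(tiny_config(seed = 3, grid = c(4, 4, 4)))
  expect_identical(coarsen_grid(m, 1), m)
  m2 <- coarsen_grid(m, 2)
  expect_equal(sum(m2$pre), sum(m$pre))
  expect_equal(sum(m2$post), sum(m$post))
  expect_equal(m2$grid$edge_length, 2 * m$grid$edge_length)
  expect_equal(m2$grid$dims, m$grid$dims %/% 2L)
  # brute-force group-by-sum oracle on the 4^3 grid
  dims <- m$grid$dims
  id0 <- seq_len(prod(dims)) - 1L
  cid <- (id0 %% 4L) %/% 2L +
         2L * ((id0 %/% 4L) %% 4L %/% 2L) +
         4L * (id0 %/% 16L %/% 2L) + 1L
  pre_dense <- as.matrix(m$pre)
  brute <- t(apply(pre_dense, 1L, function(r) tapply(r, cid, sum)))
  expect_equal(unname(as.matrix(m2$pre)), unname(brute))
  expect_error(coarsen_grid(m, 3), "does not divide")
})

test_that("shared_subvolumes matches an exhaustive per-subvolume scan", {
  m <- generate_structural_model(tiny_config(seed = 6, n_pre = 5, n_post = 2,
                                             grid = c(6, 6, 6)))
  pre_ids <- presynaptic_ids(m); post_ids <- postsynaptic_ids(m)
  for (i in pre_ids[1:3]) {
    for (j in post_ids) {
      brute <- sum(as.numeric(m$pre[i, ]) > 0 & as.numeric(m$post[j, ]) > 0)
      expect_equal(shared_subvolumes(m, i, j), brute)
    }
  }
  # disjoint footprints give zero
  pre <- matrix(c(1, 0, 0, 0), 1); post <- matrix(c(0, 0, 2, 0), 1)
  expect_equal(shared_subvolumes(manual_model(pre, post), 1, 2), 0L)
  expect_error(shared_subvolumes(m, max(m$neurons$id) + 1L, post_ids[1]),
               "unknown neuron id")
  expect_error(shared_subvolumes(m, pre_ids[1], pre_ids[2]), "role")
})

test_that("co-occupancy never shrinks when features are aggregated", {
  for (s in 1:5) {
    m <- generate_structural_model(tiny_config(seed = s, n_pre = 4,
                                               n_post = 2, grid = c(4, 4, 4)))
    m2 <- coarsen_grid(m, 2)
    for (i in presynaptic_ids(m)) {
      for (j in postsynaptic_ids(m)) {
        expect_lte(ceiling(shared_subvolumes(m, i, j) / 8),
                   shared_subvolumes(m2, i, j))
      }
    }
  }
})
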