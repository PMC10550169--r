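# Shared fixtures: tiny configs and hand-built structural models whose
# feature maps are fully controlled, so oracles can enumerate by brute force.

tiny_config <- function(seed = 1, n_pre = 5, n_post = 3,
                        grid = c(8, 8, 8), edge = 10) {
  model_config(grid_dims = grid, edge_length = edge,
               populations = default_populations(n_pre = n_pre,
                                                 n_post = n_post),
               seed = seed)
}

# Build a structural_model directly from dense pre/post matrices
# (neurons x subvolumes). Roles are inferred: rows with any pre count are
# presynaptic, the rest postsynaptic.
manual_model <- function(pre, post, grid_dims = NULL, edge_length = 10) {
  stopifnot(ncol(pre) == ncol(post))
  K <- ncol(pre)
  if (is.null(grid_dims)) grid_dims <- c(K, 1L, 1L)
  stopifnot(prod(grid_dims) == K)
  n <- nrow(pre) + nrow(post)
  pre_full <- rbind(pre, matrix(0, nrow(post), K))
  post_full <- rbind(matrix(0, nrow(pre), K), post)
  neurons <- data.frame(
    id = seq_len(n),
    population = c(rep("PRE", nrow(pre)), rep("POST", nrow(post))),
    role = c(rep("presynaptic", nrow(pre)),
             rep("postsynaptic", nrow(post))),
    stringsAsFactors = FALSE)
  structure(list(
    grid = list(dims = as.integer(grid_dims), edge_length = edge_length),
    neurons = neurons,
    pre = methods::as(Matrix::Matrix(pre_full, sparse = TRUE), "CsparseMatrix"),
    post = methods::as(Matrix::Matrix(post_full, sparse = TRUE), "CsparseMatrix"),
    postAll = Matrix::colSums(post_full),
    soma = matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z"))),
    config = NULL), class = "structural_model")
}

# 12-pair toy connectome: 3 presynaptic x 4 postsynaptic neurons, an
# explicit set of connected pairs.
toy_connectome <- function(connected = cbind(i = c(1, 1, 2, 3, 3),
                                             j = c(4, 5, 6, 4, 7))) {
  n <- nrow(connected)
  syn <- data.frame(i = connected[, 1], j = connected[, 2],
                    k = rep(1L, n), count = rep(1L, n))
  structure(list(synapses = syn, level = "synapse", rule = "manual",
                 params = list(), seed = NULL,
                 grid = list(dims = c(1L, 1L, 1L), edge_length = 1),
                 n_neurons = 7L),
            class = "connectome")
}

toy_spec <- function() population_spec("toy", pre_ids = 1:3, post_ids = 4:7)

# Conjugate Gaussian problem used by SBC / MCMC tests:
# theta ~ N(0, 1), x | theta ~ N(theta, 1) => posterior N(x/2, 1/2).
conjugate_prior <- function() prior_gaussian(mean = 0, cov = matrix(1),
                                             labels = "theta")
conjugate_simulator <- function() {
  wiresbi:::simulator_skeleton(function(theta) stats::rnorm(1, theta, 1),
                               1L, 1L, "x")
}
conjugate_posterior_sampler <- function(x, L) {
  matrix(stats::rnorm(L, x / 2, sqrt(0.5)), ncol = 1L)
}
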