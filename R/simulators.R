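#' Fast parameter-to-summary simulators for inference
#'
#' Each factory precomputes the structural quantities of one wiring rule and
#' returns a closure mapping a parameter draw to the simulated observation:
#' the vector of population connection probabilities from `n_pairs` randomly
#' probed pairs per population (fresh pairs each call, as in repeated
#' experiments). The closures use the ambient RNG, so callers control
#' reproducibility with `set.seed()` or the seed arguments of [npe()].
#'
#' For the DSO rule the pairwise connection indicator is drawn exactly: the
#' total synapse count of a pair is Poisson with the summed per-subvolume
#' rate, so the pair connects with probability `1 - exp(-sum_k DSO_ijk)`.
#' This is distributionally identical to sampling every per-subvolume count
#' and thresholding, at a fraction of the cost.
#'
#' @param model A structural model.
#' @param specs Population specs (default [default_population_specs()]).
#' @param n_pairs Pairs probed per population per simulation.
#' @param rate_ceiling DSO rate clip, see [dso_rate()].
#' @return A function `f(theta)` returning a named numeric vector (one entry
#'   per population), with attributes `n_dim` (output length), `param_dim`
#'   and `labels`.
#' @name simulators
NULL

simulator_skeleton <- function(f, n_dim, param_dim, labels) {
  attr(f, "n_dim") <- n_dim
  attr(f, "param_dim") <- param_dim
  attr(f, "labels") <- labels
  class(f) <- c("wr_simulator", "function")
  f
}

# Pair bookkeeping shared by the three rule simulators: global candidate
# pair table plus, per population, the indices of its pairs.
build_pair_index <- function(specs) {
  tabs <- lapply(specs, function(s) {
    expand.grid(i = s$pre_ids, j = s$post_ids, KEEP.OUT.ATTRS = FALSE)
  })
  sizes <- vapply(tabs, nrow, integer(1L))
  pairs <- do.call(rbind, tabs)
  # deduplicate across populations while remembering each population's rows
  key <- paste(pairs$i, pairs$j)
  ukey <- !duplicated(key)
  upairs <- pairs[ukey, , drop = FALSE]
  map <- match(key, key[ukey])
  offs <- c(0L, cumsum(sizes))
  pop_rows <- lapply(seq_along(specs), function(m) {
    map[(offs[m] + 1L):offs[m + 1L]]
  })
  list(pairs = upairs, pop_rows = pop_rows,
       labels = vapply(specs, `[[`, character(1L), "label"))
}

sample_pop_pairs <- function(pop_rows, n_pairs) {
  lapply(pop_rows, function(rows) {
    if (length(rows) <= n_pairs) rows else rows[sample.int(length(rows), n_pairs)]
  })
}

#' @rdname simulators
#' @export
dso_summary_simulator <- function(model, specs = default_population_specs(model),
                                  n_pairs = 50, rate_ceiling = 1e6) {
  stopifnot(inherits(model, "structural_model"))
  fm <- build_feature_matrix(model)
  px <- build_pair_index(specs)
  n_cand <- nrow(px$pairs)
  # map every feature-matrix row to its candidate pair (0 = not a candidate)
  row_pair <- match(paste(fm$pairs$i, fm$pairs$j),
                    paste(px$pairs$i, px$pairs$j))
  keep <- !is.na(row_pair)
  X <- fm$X[keep, , drop = FALSE]
  row_pair <- row_pair[keep]
  # sparse aggregator: candidate pair x feature row
  agg <- Matrix::sparseMatrix(i = row_pair, j = seq_along(row_pair), x = 1,
                              dims = c(n_cand, length(row_pair)))
  f <- function(theta) {
    lam <- exp(as.vector(X %*% theta))
    lam[lam > rate_ceiling] <- rate_ceiling
    lam_pair <- as.vector(agg %*% lam)
    p_conn <- -expm1(-lam_pair)
    sel <- sample_pop_pairs(px$pop_rows, n_pairs)
    vapply(seq_along(sel), function(m) {
      rows <- sel[[m]]
      mean(stats::rbinom(length(rows), 1L, p_conn[rows]))
    }, numeric(1L)) |> stats::setNames(px$labels)
  }
  simulator_skeleton(f, length(specs), 3L, px$labels)
}

#' @rdname simulators
#' @export
neuron_summary_simulator <- function(model,
                                     specs = default_population_specs(model),
                                     n_pairs = 50) {
  stopifnot(inherits(model, "structural_model"))
  px <- build_pair_index(specs)
  v_all <- pairwise_shared_subvolumes(model)
  pre_ids <- presynaptic_ids(model); post_ids <- postsynaptic_ids(model)
  v <- v_all[cbind(match(px$pairs$i, pre_ids), match(px$pairs$j, post_ids))]
  f <- function(theta) {
    sel <- sample_pop_pairs(px$pop_rows, n_pairs)
    vapply(seq_along(sel), function(m) {
      mean(v[sel[[m]]] > theta[1L])
    }, numeric(1L)) |> stats::setNames(px$labels)
  }
  simulator_skeleton(f, length(specs), 1L, px$labels)
}

#' @rdname simulators
#' @export
synapse_summary_simulator <- function(model,
                                      specs = default_population_specs(model),
                                      n_pairs = 50) {
  stopifnot(inherits(model, "structural_model"))
  px <- build_pair_index(specs)
  v_all <- pairwise_shared_subvolumes(model)
  pre_ids <- presynaptic_ids(model); post_ids <- postsynaptic_ids(model)
  # co-occupancy count per candidate pair: a pair with m co-occupied
  # subvolumes connects with probability 1 - (1 - theta_prob)^m
  m_cooc <- v_all[cbind(match(px$pairs$i, pre_ids), match(px$pairs$j, post_ids))]
  f <- function(theta) {
    p_conn <- 1 - (1 - theta[1L])^m_cooc
    sel <- sample_pop_pairs(px$pop_rows, n_pairs)
    vapply(seq_along(sel), function(m) {
      rows <- sel[[m]]
      mean(stats::rbinom(length(rows), 1L, p_conn[rows]))
    }, numeric(1L)) |> stats::setNames(px$labels)
  }
  simulator_skeleton(f, length(specs), 1L, px$labels)
}
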