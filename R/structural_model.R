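#' Configuration for a synthetic structural model
#'
#' Describes a voxelized block of neural tissue: a regular 3D grid of cubic
#' subvolumes and a set of neuron populations whose axonal (presynaptic
#' bouton) or dendritic (postsynaptic target) footprints are scattered over
#' the grid. The generated model is a synapse-free substrate: wiring rules
#' act on its per-(neuron, subvolume) feature counts to produce connectomes.
#'
#' Each population is placed by drawing a soma position uniformly inside the
#' tissue block (restricted to a depth band, emulating cortical layers). A
#' neuron's footprint is a sparse spherical neighborhood: every subvolume
#' whose center lies within `radius` micrometers of the soma belongs to the
#' envelope, and each envelope subvolume is occupied independently with
#' probability `occupancy` (always including the subvolume containing the
#' soma). Sparse occupancy emulates branching arbors, which visit only a
#' fraction of the tissue volume their envelope spans — axons (low
#' `occupancy`, wide `radius`) more so than dendrites. Each occupied
#' subvolume receives a feature count drawn from a shifted negative
#' binomial, `1 + NB(mu = count_mean - 1, size = count_dispersion)`, so that
#' occupancy always implies at least one structure; `count_dispersion = Inf`
#' gives the shifted-Poisson special case.
#'
#' @param grid_dims Integer vector `(nx, ny, nz)` of subvolumes per axis.
#' @param edge_length Subvolume edge length in micrometers.
#' @param populations Data frame with columns `name`, `role`
#'   (`"presynaptic"` or `"postsynaptic"`), `n` (neurons), `radius`
#'   (envelope radius, micrometers), `occupancy` (fraction of envelope
#'   subvolumes occupied, in (0, 1\]), `count_mean` (mean features per
#'   occupied subvolume, > 1), `count_dispersion` (negative-binomial size),
#'   `z_min`, `z_max` (soma depth band as fractions of total depth).
#' @param seed Master seed; model generation, synapse sampling, pair
#'   sampling and training each derive an independent named substream.
#' @return An object of class `model_config`.
#' @seealso [generate_structural_model()]
#' @export
model_config <- function(grid_dims = c(20, 20, 20), edge_length = 5,
                         populations = default_populations(), seed = 1) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L), edge_length > 0)
  req <- c("name", "role", "n", "radius", "occupancy", "count_mean",
           "count_dispersion", "z_min", "z_max")
  if (!all(req %in% names(populations))) {
    stop("populations must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(populations$n <= 0)) {
    stop("every population must contain at least one neuron", call. = FALSE)
  }
  if (!any(populations$role == "presynaptic") ||
      !any(populations$role == "postsynaptic")) {
    stop("need at least one presynaptic and one postsynaptic population",
         call. = FALSE)
  }
  if (any(populations$count_mean <= 1)) {
    stop("count_mean must be > 1 (counts are shifted by 1)", call. = FALSE)
  }
  if (any(populations$occupancy <= 0 | populations$occupancy > 1)) {
    stop("occupancy must lie in (0, 1]", call. = FALSE)
  }
  structure(list(grid_dims = grid_dims, edge_length = edge_length,
                 populations = populations, seed = seed),
            class = "model_config")
}

#' Default population table: one thalamic (VPM-like) presynaptic population
#' and seven cortical postsynaptic populations in layer-specific depth bands.
#'
#' @param n_pre Presynaptic neurons.
#' @param n_post Neurons per postsynaptic population.
#' @return Data frame suitable for [model_config()].
#' @export
default_populations <- function(n_pre = 40, n_post = 23) {
  post <- c("L4", "L4SEP", "L4SP", "L4SS", "L5IT", "L5PT", "L6")
  data.frame(
    name = c("VPM", post),
    role = c("presynaptic", rep("postsynaptic", 7L)),
    n = c(n_pre, rep(n_post, 7L)),
    radius = c(30, rep(25, 7L)),
    occupancy = c(0.07, rep(0.7, 7L)),
    count_mean = c(2, rep(3, 7L)),
    count_dispersion = c(2, rep(2, 7L)),
    z_min = c(0.0, 0.15, 0.20, 0.15, 0.25, 0.45, 0.50, 0.70),
    z_max = c(1.0, 0.50, 0.55, 0.50, 0.55, 0.80, 0.85, 0.98),
    stringsAsFactors = FALSE)
}

# Subvolume centers in micrometers; 0-based grid indices, center of cell
# (ix, iy, iz) at ((ix, iy, iz) + 0.5) * edge_length. Linear subvolume ids
# are 1-based, x fastest.
subvolume_centers <- function(grid_dims, edge_length) {
  nx <- grid_dims[1L]; ny <- grid_dims[2L]; nz <- grid_dims[3L]
  ix <- rep.int(seq_len(nx) - 1L, ny * nz)
  iy <- rep.int(rep(seq_len(ny) - 1L, each = nx), nz)
  iz <- rep(seq_len(nz) - 1L, each = nx * ny)
  cbind(x = (ix + 0.5) * edge_length,
        y = (iy + 0.5) * edge_length,
        z = (iz + 0.5) * edge_length)
}

#' Generate a synthetic structural model
#'
#' Realizes a [model_config()] into sparse per-(neuron, subvolume) feature
#' maps: presynaptic bouton counts for presynaptic-role neurons, postsynaptic
#' target counts for postsynaptic-role neurons, and the per-subvolume total
#' `postAll` (sum of postsynaptic counts over all neurons), which normalizes
#' the dense structural overlap.
#'
#' Generation is deterministic given the config seed (substream `"model"`).
#' The subvolume containing the soma is always part of a neuron's footprint,
#' so every neuron occupies at least one subvolume.
#'
#' @param config A [model_config()].
#' @return An object of class `structural_model`: a list with `grid`
#'   (`dims`, `edge_length`), `neurons` (data frame `id`, `population`,
#'   `role`), sparse matrices `pre` and `post` (neurons x subvolumes),
#'   numeric `postAll`, and `soma` positions.
#' @examples
#' cfg <- model_config(grid_dims = c(8, 8, 8), edge_length = 10,
#'                     populations = default_populations(n_pre = 5, n_post = 3))
#' m <- generate_structural_model(cfg)
#' m
#' @export
generate_structural_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  pops <- config$populations
  n_total <- sum(pops$n)
  centers <- subvolume_centers(config$grid_dims, config$edge_length)
  K <- nrow(centers)
  extent <- config$grid_dims * config$edge_length

  neurons <- data.frame(
    id = seq_len(n_total),
    population = rep(pops$name, pops$n),
    role = rep(pops$role, pops$n),
    stringsAsFactors = FALSE)

  with_seed(substream_seed(config$seed, "model"), {
    trip_i <- vector("list", n_total)
    trip_k <- vector("list", n_total)
    trip_x <- vector("list", n_total)
    soma <- matrix(NA_real_, n_total, 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
    idx <- 0L
    for (p in seq_len(nrow(pops))) {
      for (dummy in seq_len(pops$n[p])) {
        idx <- idx + 1L
        s <- c(stats::runif(1L, 0, extent[1L]),
               stats::runif(1L, 0, extent[2L]),
               stats::runif(1L, pops$z_min[p] * extent[3L],
                            pops$z_max[p] * extent[3L]))
        soma[idx, ] <- s
        d2 <- (centers[, 1L] - s[1L])^2 + (centers[, 2L] - s[2L])^2 +
              (centers[, 3L] - s[3L])^2
        occ <- which(d2 <= pops$radius[p]^2)
        if (pops$occupancy[p] < 1) {
          occ <- occ[stats::runif(length(occ)) < pops$occupancy[p]]
        }
        home <- which.min(d2)
        occ <- union(occ, home)
        counts <- 1L + stats::rnbinom(length(occ),
                                      mu = pops$count_mean[p] - 1,
                                      size = pops$count_dispersion[p])
        trip_i[[idx]] <- rep.int(idx, length(occ))
        trip_k[[idx]] <- occ
        trip_x[[idx]] <- counts
      }
    }
    ii <- unlist(trip_i); kk <- unlist(trip_k); xx <- unlist(trip_x)
  })

  is_pre <- neurons$role == "presynaptic"
  sel_pre <- is_pre[ii]
  pre <- Matrix::sparseMatrix(i = ii[sel_pre], j = kk[sel_pre],
                              x = xx[sel_pre], dims = c(n_total, K))
  post <- Matrix::sparseMatrix(i = ii[!sel_pre], j = kk[!sel_pre],
                               x = xx[!sel_pre], dims = c(n_total, K))
  structure(list(
    grid = list(dims = config$grid_dims, edge_length = config$edge_length),
    neurons = neurons,
    pre = pre,
    post = post,
    postAll = Matrix::colSums(post),
    soma = soma,
    config = config),
    class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat("Synthetic structural model\n")
  cat(sprintf("  grid: %s subvolumes, edge length %g um\n",
              paste(x$grid$dims, collapse = " x "), x$grid$edge_length))
  tab <- table(x$neurons$population)
  cat(sprintf("  neurons: %d (%s)\n", nrow(x$neurons),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  nonzero feature entries: %d pre, %d post\n",
              length(x$pre@x), length(x$post@x)))
  invisible(x)
}

#' Aggregate a structural model to a coarser grid
#'
#' Merges blocks of `factor`^3 subvolumes into single super-subvolumes by
#' summing feature counts, emulating structural features computed at a
#' coarser spatial resolution (larger subvolume edge length). Feature totals
#' are conserved; `postAll` is recomputed on the coarse grid.
#'
#' @param model A [generate_structural_model()] result.
#' @param factor Positive integer dividing each grid dimension.
#' @return A `structural_model` on the coarse grid with
#'   `edge_length * factor`.
#' @export
coarsen_grid <- function(model, factor) {
  stopifnot(inherits(model, "structural_model"))
  factor <- as.integer(factor)
  if (length(factor) != 1L || factor < 1L) {
    stop("'factor' must be a positive integer", call. = FALSE)
  }
  if (factor == 1L) return(model)
  dims <- model$grid$dims
  if (any(dims %% factor != 0L)) {
    stop(sprintf("factor %d does not divide grid dimensions (%s)",
                 factor, paste(dims, collapse = ", ")), call. = FALSE)
  }
  new_dims <- dims %/% factor
  K <- prod(dims)
  # old linear id -> coarse linear id
  id0 <- seq_len(K) - 1L
  ix <- id0 %% dims[1L]
  iy <- (id0 %/% dims[1L]) %% dims[2L]
  iz <- id0 %/% (dims[1L] * dims[2L])
  cid <- (ix %/% factor) +
         new_dims[1L] * (iy %/% factor) +
         new_dims[1L] * new_dims[2L] * (iz %/% factor) + 1L
  agg <- Matrix::sparseMatrix(i = seq_len(K), j = cid, x = 1,
                              dims = c(K, prod(new_dims)))
  pre <- model$pre %*% agg
  post <- model$post %*% agg
  out <- model
  out$grid <- list(dims = new_dims,
                   edge_length = model$grid$edge_length * factor)
  out$pre <- methods::as(pre, "CsparseMatrix")
  out$post <- methods::as(post, "CsparseMatrix")
  out$postAll <- Matrix::colSums(post)
  out
}

#' Number of subvolumes shared by a neuron pair
#'
#' Counts the subvolumes that contain presynaptic structures of neuron `i`
#' and postsynaptic structures of neuron `j` — the proximity feature `v_ij`
#' that the neuron-level threshold rule acts on.
#'
#' @param model A structural model.
#' @param i Presynaptic neuron id.
#' @param j Postsynaptic neuron id.
#' @return Nonnegative integer count of co-occupied subvolumes.
#' @export
shared_subvolumes <- function(model, i, j) {
  stopifnot(inherits(model, "structural_model"))
  check_neuron_role(model, i, "presynaptic")
  check_neuron_role(model, j, "postsynaptic")
  ki <- which(model$pre[i, ] > 0)
  kj <- which(model$post[j, ] > 0)
  length(intersect(ki, kj))
}

check_neuron_role <- function(model, id, role) {
  if (length(id) != 1L || !id %in% model$neurons$id) {
    stop(sprintf("unknown neuron id: %s", paste(id, collapse = ",")),
         call. = FALSE)
  }
  if (model$neurons$role[model$neurons$id == id] != role) {
    stop(sprintf("neuron %d does not have role '%s'", id, role),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Shared-subvolume counts for all (presynaptic x postsynaptic) pairs.
# Returns a dense matrix indexed by the given neuron id vectors.
pairwise_shared_subvolumes <- function(model,
                                       pre_ids = presynaptic_ids(model),
                                       post_ids = postsynaptic_ids(model)) {
  occ_pre <- model$pre[pre_ids, , drop = FALSE]
  occ_pre@x <- rep(1, length(occ_pre@x))
  occ_post <- model$post[post_ids, , drop = FALSE]
  occ_post@x <- rep(1, length(occ_post@x))
  v <- as.matrix(Matrix::tcrossprod(occ_pre, occ_post))
  dimnames(v) <- list(pre_ids, post_ids)
  v
}

#' Neuron ids by synaptic role
#' @param model A structural model.
#' @return Integer vector of neuron ids.
#' @export
presynaptic_ids <- function(model) {
  model$neurons$id[model$neurons$role == "presynaptic"]
}

#' @rdname presynaptic_ids
#' @export
postsynaptic_ids <- function(model) {
  model$neurons$id[model$neurons$role == "postsynaptic"]
}
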