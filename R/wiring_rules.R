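#' Parametrized dense-structural-overlap rate
#'
#' The dense structural overlap (DSO) of a neuron pair (i, j) in subvolume k
#' is the product of the presynaptic bouton count of i and the postsynaptic
#' target count of j, normalized by the total postsynaptic count of all
#' neurons in k. The parametrized rule raises each feature to an exponent:
#' \deqn{DSO_{ijk}(\theta) = pre^{\theta_{pre}} \cdot post^{\theta_{post}} /
#'   postAll^{\theta_{postAll}},}
#' and synapse counts are Poisson with this rate. `theta = c(1, 1, 1)`
#' recovers the unparametrized a-priori rule.
#'
#' Rates are clipped at `rate_ceiling` before Poisson sampling: extreme prior
#' draws can otherwise produce astronomically large rates. A warning is
#' emitted when clipping activates.
#'
#' @param pre,post,postAll Nonnegative feature counts (vectorized).
#' @param theta Numeric length-3 vector `(theta_pre, theta_post,
#'   theta_postAll)`.
#' @param rate_ceiling Upper clip for the returned rate.
#' @return Numeric vector of rates; 0 wherever `pre` or `post` is 0.
#' @examples
#' dso_rate(2, 3, 6, c(1, 1, 1))  # 1
#' @export
dso_rate <- function(pre, post, postAll, theta, rate_ceiling = 1e6) {
  stopifnot(length(theta) == 3L, all(is.finite(theta)))
  n <- max(length(pre), length(post), length(postAll))
  pre <- rep_len(pre, n); post <- rep_len(post, n)
  postAll <- rep_len(postAll, n)
  if (any(postAll == 0 & post > 0)) {
    stop("postAll = 0 with post > 0: inconsistent structural features",
         call. = FALSE)
  }
  r <- numeric(n)
  ok <- pre > 0 & post > 0
  r[ok] <- exp(theta[1L] * log(pre[ok]) + theta[2L] * log(post[ok]) -
               theta[3L] * log(postAll[ok]))
  if (any(r > rate_ceiling)) {
    warning(sprintf("DSO rate ceiling (%g) reached for %d combination(s)",
                    rate_ceiling, sum(r > rate_ceiling)), call. = FALSE)
    r <- pmin(r, rate_ceiling)
  }
  r
}

#' Poisson-GLM feature matrix of a structural model
#'
#' Rewrites the parametrized DSO rule as a Poisson generalized linear model:
#' for every neuron-pair-subvolume combination (i, j, k) with positive pre-
#' and postsynaptic features, the log rate is linear in the parameters,
#' `log DSO_ijk(theta) = theta' X_ijk` with
#' `X_ijk = (log pre_ik, log post_jk, -log postAll_k)`.
#'
#' @param model A structural model.
#' @return An object of class `feature_matrix`: list with `X` (rows =
#'   combinations, columns `log_pre`, `log_post`, `neg_log_postAll`),
#'   `pairs` (data frame `i`, `j`, `k`) and the raw feature columns.
#' @export
build_feature_matrix <- function(model) {
  stopifnot(inherits(model, "structural_model"))
  tp <- Matrix::summary(model$pre)   # columns i (neuron), j (subvolume), x
  tq <- Matrix::summary(model$post)
  if (nrow(tp) == 0L || nrow(tq) == 0L) {
    return(empty_feature_matrix())
  }
  pre_by_k <- split(seq_len(nrow(tp)), tp$j)
  post_by_k <- split(seq_len(nrow(tq)), tq$j)
  common <- intersect(names(pre_by_k), names(post_by_k))
  if (length(common) == 0L) return(empty_feature_matrix())
  rows_p <- vector("list", length(common))
  rows_q <- vector("list", length(common))
  for (m in seq_along(common)) {
    a <- pre_by_k[[common[m]]]
    b <- post_by_k[[common[m]]]
    rows_p[[m]] <- rep(a, each = length(b))
    rows_q[[m]] <- rep.int(b, length(a))
  }
  ip <- unlist(rows_p); iq <- unlist(rows_q)
  pre_x <- tp$x[ip]; post_x <- tq$x[iq]
  k <- tp$j[ip]
  postAll_x <- model$postAll[k]
  X <- cbind(log_pre = log(pre_x), log_post = log(post_x),
             neg_log_postAll = -log(postAll_x))
  structure(list(X = X,
                 pairs = data.frame(i = tp$i[ip], j = tq$i[iq], k = k),
                 pre = pre_x, post = post_x, postAll = postAll_x),
            class = "feature_matrix")
}

empty_feature_matrix <- function() {
  structure(list(X = matrix(numeric(0), 0L, 3L,
                            dimnames = list(NULL, c("log_pre", "log_post",
                                                    "neg_log_postAll"))),
                 pairs = data.frame(i = integer(0), j = integer(0),
                                    k = integer(0)),
                 pre = numeric(0), post = numeric(0), postAll = numeric(0)),
            class = "feature_matrix")
}

# Rates for all feature-matrix rows at theta, with clipping.
feature_matrix_rates <- function(fm, theta, rate_ceiling = 1e6,
                                 warn = TRUE) {
  if (nrow(fm$X) == 0L) return(numeric(0))
  r <- exp(as.vector(fm$X %*% theta))
  if (any(r > rate_ceiling)) {
    if (warn) {
      warning(sprintf("DSO rate ceiling (%g) reached for %d combination(s)",
                      rate_ceiling, sum(r > rate_ceiling)), call. = FALSE)
    }
    r <- pmin(r, rate_ceiling)
  }
  r
}

new_connectome <- function(synapses, level, rule, params, seed, model) {
  structure(list(synapses = synapses, level = level, rule = rule,
                 params = params, seed = seed,
                 grid = model$grid, n_neurons = nrow(model$neurons)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Simulated connectome (%s-level, rule: %s)\n", x$level, x$rule))
  if (x$level == "synapse") {
    cat(sprintf("  %d nonzero (i, j, k) entries, %d synapses, %d connected pairs\n",
                nrow(x$synapses), sum(x$synapses$count),
                nrow(connected_pairs(x))))
  } else {
    cat(sprintf("  %d connected pairs\n", nrow(x$synapses)))
  }
  cat(sprintf("  params: %s\n",
              paste(signif(unlist(x$params), 4), collapse = ", ")))
  invisible(x)
}

#' Simulate a connectome from the parametrized DSO rule
#'
#' Draws independent Poisson synapse counts `c_ijk ~ Poisson(DSO_ijk(theta))`
#' for every neuron-pair-subvolume combination with positive features;
#' combinations with rate zero never appear.
#'
#' @param model A structural model.
#' @param theta Length-3 DSO exponents.
#' @param seed Optional seed (ambient RNG restored).
#' @param rate_ceiling Rate clip, see [dso_rate()].
#' @param fm Optional precomputed [build_feature_matrix()] of `model`.
#' @return A `connectome` object with a sparse `(i, j, k, count)` table.
#' @export
simulate_dso <- function(model, theta, seed = NULL, rate_ceiling = 1e6,
                         fm = NULL) {
  stopifnot(inherits(model, "structural_model"), length(theta) == 3L)
  fm <- fm %||% build_feature_matrix(model)
  lambda <- feature_matrix_rates(fm, theta, rate_ceiling)
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  keep <- counts > 0L
  syn <- cbind(fm$pairs[keep, , drop = FALSE], count = counts[keep])
  rownames(syn) <- NULL
  new_connectome(syn, "synapse", "dso",
                 list(theta = theta), seed, model)
}

#' Simulate the neuron-level shared-subvolume threshold rule
#'
#' Deterministic binary rule: neurons i and j are connected iff the number
#' of subvolumes containing presynaptic structures of i and postsynaptic
#' structures of j strictly exceeds `theta_thres`.
#'
#' @param model A structural model.
#' @param theta_thres Nonnegative real threshold.
#' @return A neuron-level `connectome` with a table of connected `(i, j)`
#'   pairs.
#' @export
simulate_neuron_level <- function(model, theta_thres) {
  stopifnot(inherits(model, "structural_model"), theta_thres >= 0)
  v <- pairwise_shared_subvolumes(model)
  hit <- which(v > theta_thres, arr.ind = TRUE)
  syn <- data.frame(i = presynaptic_ids(model)[hit[, 1L]],
                    j = postsynaptic_ids(model)[hit[, 2L]])
  new_connectome(syn, "neuron", "neuron_threshold",
                 list(theta_thres = theta_thres), NULL, model)
}

#' Simulate the synapse-level Bernoulli proximity rule
#'
#' Whenever a presynaptic structure of neuron i and a postsynaptic structure
#' of neuron j are present in the same subvolume k, a synapse forms there
#' with probability `theta_prob`, independently across combinations.
#'
#' @param model A structural model.
#' @param theta_prob Synapse probability in \[0, 1\].
#' @param seed Optional seed.
#' @return A synapse-level `connectome` with 0/1 counts.
#' @export
simulate_synapse_level <- function(model, theta_prob, seed = NULL) {
  stopifnot(inherits(model, "structural_model"),
            theta_prob >= 0, theta_prob <= 1)
  fm <- build_feature_matrix(model)
  n <- nrow(fm$X)
  draws <- with_seed(seed, stats::rbinom(n, 1L, theta_prob))
  keep <- draws == 1L
  syn <- cbind(fm$pairs[keep, , drop = FALSE],
               count = rep(1L, sum(keep)))
  rownames(syn) <- NULL
  new_connectome(syn, "synapse", "synapse_bernoulli",
                 list(theta_prob = theta_prob), seed, model)
}

#' Peters'-rule connectomes
#'
#' The proximity-only hypothesis: `peters_rule_neuron()` connects every pair
#' sharing at least one subvolume (`v_ij >= 1`); `peters_rule_synapse()`
#' places a synapse at every co-occupied neuron-pair-subvolume combination
#' (the `theta_prob = 1` limit of the Bernoulli rule). Note the neuron-level
#' predicate `v >= 1` differs from the threshold rule at `theta_thres = 1`,
#' whose strict inequality requires `v >= 2`.
#'
#' @param model A structural model.
#' @param seed Unused (the rule is deterministic); kept for interface
#'   symmetry with [simulate_synapse_level()].
#' @return A `connectome` object.
#' @export
peters_rule_neuron <- function(model) {
  stopifnot(inherits(model, "structural_model"))
  v <- pairwise_shared_subvolumes(model)
  hit <- which(v >= 1, arr.ind = TRUE)
  syn <- data.frame(i = presynaptic_ids(model)[hit[, 1L]],
                    j = postsynaptic_ids(model)[hit[, 2L]])
  new_connectome(syn, "neuron", "peters_neuron", list(), NULL, model)
}

#' @rdname peters_rule_neuron
#' @export
peters_rule_synapse <- function(model, seed = NULL) {
  out <- simulate_synapse_level(model, 1, seed = seed)
  out$rule <- "peters_synapse"
  out
}

#' Connected neuron pairs of a connectome
#'
#' A pair (i, j) counts as connected when it is joined by at least one
#' synapse (synapse-level rules) or when its binary connection indicator is
#' set (neuron-level rules).
#'
#' @param connectome A `connectome` object.
#' @return Data frame of distinct connected `(i, j)` pairs.
#' @export
connected_pairs <- function(connectome) {
  stopifnot(inherits(connectome, "connectome"))
  syn <- connectome$synapses
  if (nrow(syn) == 0L) return(data.frame(i = integer(0), j = integer(0)))
  unique(syn[, c("i", "j")])
}

#' Depth profile of synapse counts and available boutons
#'
#' Bins simulated synapse counts and structurally available presynaptic
#' boutons by subvolume depth (grid z coordinate, micrometers), for
#' comparing a wiring rule's synapse placement against the biologically
#' available presynaptic structures across cortical depth.
#'
#' @param connectome A synapse-level `connectome`.
#' @param model The structural model the connectome was simulated from.
#' @param bin_width Depth bin width in micrometers.
#' @return Data frame with `depth_lower`, `depth_upper`, `synapses`,
#'   `boutons`; the two count columns sum to their global totals.
#' @export
depth_profile <- function(connectome, model, bin_width) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(model, "structural_model"))
  if (connectome$level != "synapse") {
    stop("depth_profile requires per-subvolume synapse counts", call. = FALSE)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("'bin_width' must be > 0", call. = FALSE)
  }
  centers <- subvolume_centers(model$grid$dims, model$grid$edge_length)
  z <- centers[, "z"]
  depth_max <- model$grid$dims[3L] * model$grid$edge_length
  nb <- max(1L, as.integer(ceiling(depth_max / bin_width - 1e-9)))
  breaks <- (0:nb) * bin_width
  bin_of <- function(zz) pmin(findInterval(zz, breaks,
                                           rightmost.closed = FALSE), nb)
  synapses <- numeric(nb)
  if (nrow(connectome$synapses) > 0L) {
    sb <- bin_of(z[connectome$synapses$k])
    agg <- tapply(connectome$synapses$count, sb, sum)
    synapses[as.integer(names(agg))] <- agg
  }
  boutons <- numeric(nb)
  btot <- Matrix::colSums(model$pre)
  bagg <- tapply(btot, bin_of(z), sum)
  boutons[as.integer(names(bagg))] <- bagg
  data.frame(depth_lower = breaks[seq_len(nb)],
             depth_upper = breaks[-1L],
             synapses = synapses, boutons = boutons)
}
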