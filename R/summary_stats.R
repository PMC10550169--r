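#' Population specification for connection-probability summaries
#'
#' Names the candidate neuron-pair set of one measured population: all
#' (presynaptic, postsynaptic) pairs between the two id sets. Summary
#' statistics estimate the fraction of such pairs connected by at least one
#' synapse, mimicking paired-recording experiments.
#'
#' @param label Population label (e.g. `"L4"`, `"L5PT"`).
#' @param pre_ids Nonempty vector of presynaptic neuron ids.
#' @param post_ids Nonempty vector of postsynaptic neuron ids.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(label, pre_ids, post_ids) {
  if (length(pre_ids) == 0L || length(post_ids) == 0L) {
    stop("pre_ids and post_ids must be nonempty", call. = FALSE)
  }
  structure(list(label = label, pre_ids = as.integer(pre_ids),
                 post_ids = as.integer(post_ids)),
            class = "population_spec")
}

#' Default population specs of a structural model
#'
#' One spec per postsynaptic population, each paired with the full
#' presynaptic (thalamic) population — the layout of the measured
#' VPM-to-cortex connection probabilities.
#'
#' @param model A structural model.
#' @return List of [population_spec()] objects in population order.
#' @export
default_population_specs <- function(model) {
  stopifnot(inherits(model, "structural_model"))
  pre_ids <- presynaptic_ids(model)
  post_pops <- unique(model$neurons$population[model$neurons$role ==
                                                 "postsynaptic"])
  lapply(post_pops, function(p) {
    population_spec(p, pre_ids,
                    model$neurons$id[model$neurons$population == p])
  })
}

#' Population connection probability of a simulated connectome
#'
#' Draws `n_pairs` distinct neuron pairs uniformly from the population's
#' candidate set (all pairs, with a warning, if fewer exist) and returns the
#' fraction connected by at least one synapse. This mirrors the experimental
#' sampling of around 50 probed pairs per population.
#'
#' @param connectome A `connectome`.
#' @param spec A [population_spec()].
#' @param n_pairs Number of pairs to probe (default 50, the experimental
#'   sample size).
#' @param seed Optional seed for the pair draw.
#' @return Connection probability in \[0, 1\].
#' @export
population_connection_probability <- function(connectome, spec,
                                              n_pairs = 50, seed = NULL) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(spec, "population_spec"))
  n1 <- length(spec$pre_ids); n2 <- length(spec$post_ids)
  total <- n1 * n2
  if (total == 0L) stop("empty neuron-pair set", call. = FALSE)
  if (total <= n_pairs) {
    if (total < n_pairs) {
      warning(sprintf("population '%s' has only %d pairs (< n_pairs = %d); using all",
                      spec$label, total, n_pairs), call. = FALSE)
    }
    idx <- seq_len(total)
  } else {
    idx <- with_seed(seed, sample.int(total, n_pairs))
  }
  ii <- spec$pre_ids[((idx - 1L) %% n1) + 1L]
  jj <- spec$post_ids[((idx - 1L) %/% n1) + 1L]
  cp <- connected_pairs(connectome)
  if (nrow(cp) == 0L) return(0)
  key <- paste(cp$i, cp$j)
  mean(paste(ii, jj) %in% key)
}

#' Summary statistics: per-population connection probabilities
#'
#' Applies [population_connection_probability()] to each population spec in
#' order, producing the labeled probability vector that simulation-based
#' inference conditions on.
#'
#' @param connectome A `connectome`.
#' @param specs Nonempty list of [population_spec()]s.
#' @param n_pairs Pairs probed per population.
#' @param seed Optional seed; the whole summary is deterministic given it.
#' @return An object of class `summary_stats`: data frame `label`,
#'   `probability`, `n_pairs`.
#' @export
summarize_connectome <- function(connectome, specs, n_pairs = 50,
                                 seed = NULL) {
  if (length(specs) == 0L) stop("'specs' must be nonempty", call. = FALSE)
  probs <- with_seed(seed, {
    vapply(specs, function(s) {
      population_connection_probability(connectome, s, n_pairs, seed = NULL)
    }, numeric(1L))
  })
  out <- data.frame(label = vapply(specs, `[[`, character(1L), "label"),
                    probability = probs,
                    n_pairs = vapply(specs, function(s) {
                      min(n_pairs, length(s$pre_ids) * length(s$post_ids))
                    }, numeric(1L)))
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Expected measurement standard deviation
#'
#' Binomial standard error of a connection probability estimated from `n`
#' probed pairs — the spread expected from the experimental sample size.
#'
#' @param p Connection probability in \[0, 1\].
#' @param n Number of probed pairs (default 50).
#' @return `sqrt(p (1 - p) / n)`.
#' @export
expected_measurement_sd <- function(p, n = 50) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  sqrt(p * (1 - p) / n)
}

#' Measured connection-probability data
#'
#' Wraps a labeled vector of population connection probabilities as the
#' observation `x_obs` that inference conditions on, with the per-label
#' experimental sample size used for expected-spread comparisons.
#'
#' @param labels Character vector of unique population labels.
#' @param probabilities Probabilities in \[0, 1\], same length.
#' @param n Experimental pairs per label (scalar or vector; default 50).
#' @return An object of class `measured_data` (also a data frame).
#' @export
measured_data <- function(labels, probabilities, n = 50) {
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length", call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(label = as.character(labels),
                    probability = as.numeric(probabilities),
                    n = rep_len(n, length(labels)))
  class(out) <- c("measured_data", "data.frame")
  out
}

#' Observation vector of measured data or summary statistics
#' @param x A `measured_data` or `summary_stats` object.
#' @return Named numeric vector of probabilities.
#' @export
as_observation <- function(x) {
  stopifnot(is.data.frame(x), all(c("label", "probability") %in% names(x)))
  stats::setNames(x$probability, x$label)
}
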