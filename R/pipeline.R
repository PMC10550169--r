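# Serialization and the end-to-end pipeline driver. All artifacts are plain
# text: sparse feature maps and connectomes as CSV triplet tables with a
# JSON metadata sidecar carrying grid geometry, provenance (config hash,
# seeds, package version) and schema versions; configs as YAML.

#' Read and write measured connection-probability data
#'
#' CSV files have columns `label,probability[,n]`; JSON files hold an array
#' of `{label, probability, n}` records. Probabilities are validated to
#' \[0, 1\] on read.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @param x A [measured_data()] object.
#' @return `read_measured_data()` returns a `measured_data` object.
#' @export
read_measured_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    stop("unsupported format: .", ext, call. = FALSE))
  if (!all(c("label", "probability") %in% names(df))) {
    stop("measured data must have fields 'label' and 'probability'",
         call. = FALSE)
  }
  if (any(df$probability < 0 | df$probability > 1)) {
    bad <- df$label[df$probability < 0 | df$probability > 1][1L]
    stop(sprintf("probability out of [0, 1] for label '%s'", bad),
         call. = FALSE)
  }
  measured_data(df$label, df$probability, n = df$n %||% 50)
}

#' @rdname read_measured_data
#' @export
write_measured_data <- function(x, path) {
  stopifnot(inherits(x, "measured_data"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = utils::write.csv(as.data.frame(x), path, row.names = FALSE),
    json = jsonlite::write_json(as.data.frame(x), path, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA),
    stop("unsupported format: .", ext, call. = FALSE))
  invisible(path)
}

#' Serialize a structural model to a directory of text files
#'
#' Writes sparse pre/post feature maps as `(neuron, subvolume, count)` CSV
#' triplet tables plus `neurons.csv`, `soma.csv` and a `meta.json` sidecar
#' with grid geometry. `read_structural_model()` is the exact inverse
#' (`postAll` is recomputed from the triplets on read).
#'
#' @param model A structural model.
#' @param dir Output directory (created if missing).
#' @return `read_structural_model()` returns a `structural_model`.
#' @export
write_structural_model <- function(model, dir) {
  stopifnot(inherits(model, "structural_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtrip <- function(m, file) {
    tr <- Matrix::summary(m)
    utils::write.csv(data.frame(neuron = tr$i, subvolume = tr$j,
                                count = tr$x),
                     file.path(dir, file), row.names = FALSE)
  }
  wtrip(model$pre, "pre.csv")
  wtrip(model$post, "post.csv")
  utils::write.csv(model$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(model$soma), file.path(dir, "soma.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(schema = "structural_model/1",
                            grid_dims = model$grid$dims,
                            edge_length = model$grid$edge_length,
                            seed = model$config$seed %||% NA),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_structural_model
#' @export
read_structural_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  if (!identical(meta$schema, "structural_model/1")) {
    stop("unrecognized schema field in meta.json", call. = FALSE)
  }
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"),
                             stringsAsFactors = FALSE)
  soma <- as.matrix(utils::read.csv(file.path(dir, "soma.csv")))
  K <- prod(meta$grid_dims)
  rtrip <- function(file) {
    tr <- utils::read.csv(file.path(dir, file))
    Matrix::sparseMatrix(i = tr$neuron, j = tr$subvolume, x = tr$count,
                         dims = c(nrow(neurons), K))
  }
  post <- rtrip("post.csv")
  structure(list(grid = list(dims = as.integer(meta$grid_dims),
                             edge_length = meta$edge_length),
                 neurons = neurons, pre = rtrip("pre.csv"), post = post,
                 postAll = Matrix::colSums(post), soma = soma,
                 config = NULL),
            class = "structural_model")
}

#' Serialize a simulated connectome
#'
#' The synapse table is written as CSV; rule name, parameters, seed and grid
#' geometry travel in a JSON sidecar (`<stem>_meta.json`).
#'
#' @param connectome A `connectome` object.
#' @param path CSV path for the synapse table.
#' @return `read_connectome()` returns a `connectome`.
#' @export
write_connectome <- function(connectome, path) {
  stopifnot(inherits(connectome, "connectome"))
  utils::write.csv(connectome$synapses, path, row.names = FALSE)
  meta <- list(schema = "connectome/1", level = connectome$level,
               rule = connectome$rule, params = connectome$params,
               seed = connectome$seed %||% NA,
               grid_dims = connectome$grid$dims,
               edge_length = connectome$grid$edge_length,
               n_neurons = connectome$n_neurons)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.json")
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  syn <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(sidecar_path(path))
  if (!identical(meta$schema, "connectome/1")) {
    stop("unrecognized schema field in connectome metadata", call. = FALSE)
  }
  structure(list(synapses = syn, level = meta$level, rule = meta$rule,
                 params = meta$params,
                 seed = if (is.null(meta$seed) || is.na(meta$seed)) NULL
                        else meta$seed,
                 grid = list(dims = as.integer(meta$grid_dims),
                             edge_length = meta$edge_length),
                 n_neurons = meta$n_neurons),
            class = "connectome")
}

#' Read and write posterior samples as CSV
#' @param samples A `posterior_samples` matrix (or plain matrix).
#' @param path CSV path.
#' @return `read_posterior_samples()` returns a matrix with parameter
#'   labels as column names.
#' @export
write_posterior_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(unclass(samples)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_samples
#' @export
read_posterior_samples <- function(path) {
  out <- as.matrix(utils::read.csv(path))
  class(out) <- c("posterior_samples", class(out))
  out
}

#' Configuration for the end-to-end inference pipeline
#'
#' Ties together a structural-model config, a wiring rule, its prior, the
#' summary settings and the training budget. Rule and prior must be
#' compatible: the DSO rule takes the 3-dimensional Gaussian prior, the
#' neuron-level rule a uniform prior, the synapse-level rule a Beta prior.
#'
#' @param model A [model_config()].
#' @param rule One of `"dso"`, `"neuron"`, `"synapse"`.
#' @param prior A `wr_prior` matching the rule (defaults per rule).
#' @param n_pairs Pairs probed per population in the summary step.
#' @param training A [training_config()].
#' @param observation Optional [measured_data()] (or path to one); when
#'   absent the pipeline simulates a synthetic observation from a known
#'   prior draw and records it.
#' @param seed Master seed for the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model = model_config(), rule = "dso",
                            prior = NULL, n_pairs = 50,
                            training = training_config(),
                            observation = NULL, seed = 1L) {
  rule <- match.arg(rule, c("dso", "neuron", "synapse"))
  prior <- prior %||% switch(rule,
    dso = prior_gaussian(),
    neuron = prior_uniform(),
    synapse = prior_beta())
  ok <- switch(rule,
    dso = prior$type == "gaussian" && prior$dim == 3L,
    neuron = prior$type == "uniform",
    synapse = prior$type == "beta")
  if (!ok) {
    stop(sprintf("prior (%s, %dd) incompatible with rule '%s'",
                 prior$type, prior$dim, rule), call. = FALSE)
  }
  if (is.character(observation)) observation <- read_measured_data(observation)
  structure(list(model = model, rule = rule, prior = prior,
                 n_pairs = n_pairs, training = training,
                 observation = observation, seed = seed),
            class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Executes the stages model -> simulator -> training -> posterior ->
#' validation, writing every artifact under `out_dir` with provenance (the
#' YAML config hash, seeds, package version). With `resume = TRUE`, stages
#' whose outputs already exist are skipped (the trained posterior is reused
#' if its samples file is present). A stage failure aborts with the stage
#' name; outputs of completed stages persist.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created).
#' @param resume Reuse existing stage outputs.
#' @return A list with the model, fitted [npe()] object, posterior samples,
#'   and validation report (invisibly also written as JSON).
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_pipeline_config(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  model_dir <- file.path(out_dir, "model")
  model <- stage("model", {
    if (resume && file.exists(file.path(model_dir, "meta.json"))) {
      read_structural_model(model_dir)
    } else {
      m <- generate_structural_model(config$model)
      write_structural_model(m, model_dir)
      m
    }
  })

  simulator <- stage("simulator", {
    specs <- default_population_specs(model)
    switch(config$rule,
      dso = dso_summary_simulator(model, specs, n_pairs = config$n_pairs),
      neuron = neuron_summary_simulator(model, specs,
                                        n_pairs = config$n_pairs),
      synapse = synapse_summary_simulator(model, specs,
                                          n_pairs = config$n_pairs))
  })

  obs_path <- file.path(out_dir, "observation.csv")
  x_obs <- stage("observation", {
    if (!is.null(config$observation)) {
      write_measured_data(config$observation, obs_path)
      as_observation(config$observation)
    } else if (resume && file.exists(obs_path)) {
      as_observation(read_measured_data(obs_path))
    } else {
      theta_star <- sample_prior(config$prior, 1L,
                                 seed = substream_seed(config$seed, "obs"))
      xo <- with_seed(substream_seed(config$seed, "obs_x"),
                      simulator(as.numeric(theta_star)))
      write_measured_data(measured_data(names(xo), xo,
                                        n = config$n_pairs), obs_path)
      utils::write.csv(as.data.frame(theta_star),
                       file.path(out_dir, "true_parameters_synthetic.csv"),
                       row.names = FALSE)
      xo
    }
  })

  samples_path <- file.path(out_dir, "posterior_samples.csv")
  inference <- stage("inference", {
    if (resume && file.exists(samples_path)) {
      list(fit = NULL, samples = read_posterior_samples(samples_path))
    } else {
      cfg <- config$training
      cfg$seed <- substream_seed(config$seed, "training")
      fit <- if (cfg$n_rounds > 1L) {
        snpe(simulator, config$prior, x_obs, cfg)
      } else {
        npe(simulator, config$prior, cfg, observation = x_obs)
      }
      s <- predict(fit, n_samples = 10000L,
                   seed = substream_seed(config$seed, "posterior"))
      write_posterior_samples(s, samples_path)
      list(fit = fit, samples = s)
    }
  })
  fit <- inference$fit
  samples <- inference$samples

  report <- stage("validation", {
    ppc <- posterior_predictive_check(samples, simulator, x_obs, n = 1000L,
                                      seed = substream_seed(config$seed,
                                                            "ppc"))
    rep <- list(
      marginal_map = as.list(marginal_map(samples)),
      posterior_sd = as.list(apply(samples, 2L, stats::sd)),
      predictive_z = as.list(stats::setNames(ppc$z, names(x_obs))),
      correlations = if (ncol(samples) > 1L)
        posterior_correlations(samples) else NULL)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    rep
  })

  jsonlite::write_json(
    list(config_hash = cfg_hash, master_seed = config$seed,
         package_version = as.character(utils::packageVersion("wiresbi")),
         timestamp = format(Sys.time(), tz = "UTC"),
         stage_seeds = list(
           model = config$model$seed,
           observation = substream_seed(config$seed, "obs"),
           training = substream_seed(config$seed, "training"),
           posterior = substream_seed(config$seed, "posterior"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(model = model, fit = fit, samples = samples,
                 report = report, out_dir = out_dir))
}

serialize_pipeline_config <- function(config) {
  list(rule = config$rule,
       seed = config$seed,
       n_pairs = config$n_pairs,
       model = list(grid_dims = config$model$grid_dims,
                    edge_length = config$model$edge_length,
                    seed = config$model$seed,
                    populations = config$model$populations),
       prior = config$prior[setdiff(names(config$prior), "labels")],
       training = unclass(config$training),
       observation = if (!is.null(config$observation))
         as.data.frame(config$observation) else NULL)
}
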