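# Internal helpers: seeding, RNG scoping, small numerics.

# Deterministic 31-bit sub-seed derived from a master seed and a stream name,
# so that model generation, simulation, pair sampling and training draw from
# independent named streams.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 2147480009
  # keep everything well below 2^31
  as.integer((abs(as.numeric(master)) %% 1e6) * 2017 + h * 31 + 1) %% 2147480009L
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so reproducible draws never disturb the ambient random
#' stream. `seed = NULL` evaluates `expr` with the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @examples
#' with_seed(1, rnorm(2))
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(z) 1 / (1 + exp(-z))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
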