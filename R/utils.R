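#' Derive a reproducible sub-seed for an operation
#'
#' Random-number streams are per-operation: each stochastic operation draws its
#' seed from the master seed by stable hashing of the operation name and a
#' replicate index, so adding replicates or reordering operations never
#' perturbs other streams.
#'
#' @param master integer master seed.
#' @param op character operation name.
#' @param rep integer replicate index (default 1).
#' @return an integer seed in [0, 2^31 - 2].
#' @export
opSeed <- function(master, op, rep = 1L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(op))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master %% m)
  for (code in utf8ToInt(op)) h <- (h * 31 + code) %% m
  h <- (h * 31 + as.double(rep)) %% m
  as.integer(h)
}

# run code under a local RNG state without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a scalar in [%s, %s]", name, lower, upper), call. = FALSE)
  invisible(x)
}

# type-7 quantile, fixed for reproducibility of simulation thresholds
.quantile7 <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
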