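# Shared MCMC plumbing around rjags. The JAGS `glm` module is loaded for
# block-updating of the log-linear count models, which cuts sampling time
# substantially on these designs.

.mcmcDefaults <- function(mcmc, nChains = 2L, nAdapt = 1000L, nBurn = 1000L,
                          nIter = 5000L, thin = 1L, seed = 1L) {
  def <- list(nChains = nChains, nAdapt = nAdapt, nBurn = nBurn,
              nIter = nIter, thin = thin, seed = seed)
  def[names(mcmc)] <- mcmc
  def
}

.jagsEnv <- new.env(parent = emptyenv())

.ensureGlmModule <- function() {
  if (isTRUE(.jagsEnv$glmLoaded)) return(invisible())
  tryCatch({ rjags::load.module("glm", quiet = TRUE); .jagsEnv$glmLoaded <- TRUE },
           error = function(e) .jagsEnv$glmLoaded <- FALSE)
  invisible()
}

# run a JAGS model and return a draw matrix (chains stacked) with a
# "diagnostics" attribute holding R-hat and effective sizes
.runJags <- function(modelText, data, monitors, mc) {
  .ensureGlmModule()
  inits <- lapply(seq_len(mc$nChains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mc$seed + 104729L * ch) %% 2147483647L))
  jm <- tryCatch(
    rjags::jags.model(textConnection(modelText), data = data, inits = inits,
                      n.chains = mc$nChains, n.adapt = mc$nAdapt, quiet = TRUE),
    error = function(e) stop("JAGS model failed to initialize: ",
                             conditionMessage(e), call. = FALSE))
  if (mc$nBurn > 0) stats::update(jm, n.iter = mc$nBurn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors, n.iter = mc$nIter,
                              thin = mc$thin, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  keep <- apply(draws, 2, function(x) stats::var(x) > 0)
  diag <- data.frame(param = colnames(draws), rhat = NA_real_,
                     neff = as.numeric(coda::effectiveSize(samp)))
  if (mc$nChains >= 2L && any(keep)) {
    gd <- tryCatch(coda::gelman.diag(samp[, keep, drop = FALSE],
                                     autoburnin = FALSE, multivariate = FALSE),
                   error = function(e) NULL)
    if (!is.null(gd)) diag$rhat[keep] <- gd$psrf[, 1]
  }
  attr(draws, "diagnostics") <- diag
  draws
}

#' Posterior-tail two-sided significance for an MCMC-estimated effect
#'
#' MCMCp = max(2 min(#draws > null, #draws < null) / n, 2/n); the floor 2/n
#' reflects the Monte-Carlo resolution of the posterior sample.
#'
#' @param draws numeric vector of posterior draws.
#' @param null null value (default 0).
#' @return the MCMCp value.
#' @export
mcmcP <- function(draws, null = 0) {
  if (length(draws) == 0L) stop("empty draws")
  n <- length(draws)
  max(2 * min(sum(draws > null), sum(draws < null)) / n, 2 / n)
}
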