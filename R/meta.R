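# Random-effects meta-analysis of per-gene omega_A estimates across species,
# with known per-gene measurement error. The observed estimate is modeled as
#   omega_hat_i ~ N(classMean + species effect (+ homolog effect),
#                   se_i^2 + sigma^2_class)
# i.e. the residual gene-level variance sigma^2 is class-specific and the
# bootstrap SE enters as known measurement-error variance.

.metaClass <- function(table, model) {
  switch(model,
    rnai_vs_control = ifelse(table$is_rnai, "RNAi", "control"),
    pathway = as.character(table$pathway),
    pirna_function = as.character(table$pirna_function),
    homolog = as.character(table$pathway),
    homolog_no_pathway = rep("all", nrow(table)),
    stop("unknown model: ", model))
}

#' Fit the measurement-error mixed model of per-gene omega_A
#'
#' @param table an omega table: data.frame with gene_id, species_id,
#'   homolog_id, omega_a, se_omega_a and class labels (is_rnai, pathway,
#'   pirna_function).
#' @param model one of "rnai_vs_control", "pathway", "pirna_function",
#'   "homolog" (pathway fixed effect + homolog random effect), or
#'   "homolog_no_pathway" (homolog random effect only).
#' @param mcmc list of MCMC settings overriding the defaults.
#' @return a \linkS4class{MetaFit}. Draw columns are named
#'   \code{mean_<class>}, \code{sdResid_<class>}, \code{sdSpecies},
#'   \code{sdHomolog} and \code{hom_<id>}.
#' @export
fitMeta <- function(table, model = c("rnai_vs_control", "pathway",
                                     "pirna_function", "homolog",
                                     "homolog_no_pathway"), mcmc = list()) {
  model <- match.arg(model)
  req <- c("gene_id", "species_id", "omega_a", "se_omega_a")
  if (!all(req %in% names(table)))
    stop("omega table must have columns: ", paste(req, collapse = ", "))
  cls <- .metaClass(table, model)
  keep <- !is.na(cls) & !is.na(table$omega_a)
  table <- table[keep, , drop = FALSE]; cls <- cls[keep]
  tabn <- table(cls)
  if (any(tabn < 2L))
    stop("class with fewer than 2 genes: ",
         paste(names(tabn)[tabn < 2L], collapse = ", "))
  se <- table$se_omega_a
  if (any(is.na(se) | se < 0)) stop("se_omega_a must be nonnegative")
  if (any(se == 0)) {
    floorSe <- min(se[se > 0])
    if (!is.finite(floorSe)) stop("all SEs are zero")
    se[se == 0] <- floorSe
  }
  clsF <- factor(cls)
  sp <- factor(table$species_id)
  useSp <- nlevels(sp) > 1L
  useHom <- model %in% c("homolog", "homolog_no_pathway")
  hom <- factor(if (useHom) table$homolog_id else rep("h", nrow(table)))
  if (useHom && any(is.na(table$homolog_id))) stop("homolog model needs homolog_id")

  modelText <- paste0(
    "model{\n",
    " for(i in 1:N){\n",
    "  m[i] <- classMean[cls[i]]", if (useSp) " + u[sp[i]]" else "",
    if (useHom) " + h[hom[i]]" else "", "\n",
    "  y[i] ~ dnorm(m[i], 1/(se2[i] + sig2[cls[i]]))\n }\n",
    " for(c in 1:C){ classMean[c] ~ dnorm(0, 0.0001)\n",
    "  sdR[c] ~ dt(0, 4, 1) T(0,)\n  sig2[c] <- pow(sdR[c], 2) }\n",
    if (useSp) " for(s in 1:S){ u[s] ~ dnorm(0, tauU) }\n sdU ~ dt(0, 4, 1) T(0,)\n tauU <- pow(sdU, -2)\n" else "",
    if (useHom) " for(k in 1:H){ h[k] ~ dnorm(0, tauH) }\n sdH ~ dt(0, 4, 1) T(0,)\n tauH <- pow(sdH, -2)\n" else "",
    "}")
  dat <- list(y = table$omega_a, se2 = se^2, N = nrow(table),
              cls = as.integer(clsF), C = nlevels(clsF))
  if (useSp) { dat$sp <- as.integer(sp); dat$S <- nlevels(sp) }
  if (useHom) { dat$hom <- as.integer(hom); dat$H <- nlevels(hom) }
  monitors <- c("classMean", "sdR", if (useSp) "sdU", if (useHom) c("sdH", "h"))
  mc <- .mcmcDefaults(mcmc, nAdapt = 1000L, nBurn = 1000L, nIter = 4000L)
  draws <- .runJags(modelText, dat, monitors, mc)
  cn <- colnames(draws)
  cn[cn == "classMean"] <- "mean_1"   # scalar monitors drop the index
  cn[cn == "sdR"] <- "sdResid_1"
  cn <- sub("^classMean\\[(\\d+)\\]$", "mean_\\1", cn)
  cn <- sub("^sdR\\[(\\d+)\\]$", "sdResid_\\1", cn)
  for (i in seq_len(nlevels(clsF))) {
    cn[cn == paste0("mean_", i)] <- paste0("mean_", levels(clsF)[i])
    cn[cn == paste0("sdResid_", i)] <- paste0("sdResid_", levels(clsF)[i])
  }
  cn[cn == "sdU"] <- "sdSpecies"; cn[cn == "sdH"] <- "sdHomolog"
  for (i in seq_len(nlevels(hom)))
    cn[cn == sprintf("h[%d]", i)] <- paste0("hom_", levels(hom)[i])
  colnames(draws) <- cn
  table$se_used <- se
  table$class_used <- cls
  new("MetaFit", draws = draws, model = model, table = table,
      classes = levels(clsF))
}

#' Posterior class means and MCMCp contrasts from a meta fit
#'
#' @param fit a \linkS4class{MetaFit}.
#' @return data.frame with class, estimate, ci and MCMCp (vs 0).
#' @export
metaClassMeans <- function(fit) {
  do.call(rbind, lapply(fit@classes, function(cl) {
    dr <- fit@draws[, paste0("mean_", cl)]
    data.frame(class = cl, estimate = mean(dr),
               ciLow = .quantile7(dr, 0.025), ciHigh = .quantile7(dr, 0.975),
               mcmcp = mcmcP(dr), stringsAsFactors = FALSE)
  }))
}

#' Compare residual variances (and coefficients of variation) of two classes
#'
#' Reports the posterior of the residual-variance difference and of the CV
#' (= sqrt(variance) / |class mean|) difference, each with MCMCp. The CV
#' comparison is flagged undefined when either class-mean posterior puts
#' substantial mass on both sides of 0.
#'
#' @param fit a \linkS4class{MetaFit}.
#' @param classA,classB class labels.
#' @return list with variance and CV difference summaries.
#' @export
compareVariances <- function(fit, classA, classB) {
  stopifnot(all(c(classA, classB) %in% fit@classes))
  v <- function(cl) fit@draws[, paste0("sdResid_", cl)]^2
  mu <- function(cl) fit@draws[, paste0("mean_", cl)]
  dv <- v(classA) - v(classB)
  cv <- function(cl) sqrt(v(cl)) / abs(mu(cl))
  dcv <- cv(classA) - cv(classB)
  overlap0 <- function(cl) min(mean(mu(cl) > 0), mean(mu(cl) < 0)) > 0.2
  list(varianceDiff = mean(dv), varianceMcmcp = mcmcP(dv),
       cvDiff = mean(dcv), cvMcmcp = mcmcP(dcv),
       cvUndefined = overlap0(classA) || overlap0(classB),
       varianceA = mean(v(classA)), varianceB = mean(v(classB)))
}

#' Posterior-mean shrinkage predictions for each gene
#'
#' Per draw, the latent gene-level omega_A is the precision-weighted
#' combination of the observed estimate (weight 1/se^2) and the gene's class
#' plus random-effect mean (weight 1/sigma^2_class); the posterior mean over
#' draws is returned. Genes with large SE shrink to their class mean, genes
#' with tiny SE stay at their own estimate.
#'
#' @param fit a \linkS4class{MetaFit}.
#' @return numeric vector of predicted means, one per table row.
#' @export
predictedMeans <- function(fit) {
  tab <- fit@table
  d <- fit@draws
  vapply(seq_len(nrow(tab)), function(i) {
    cl <- tab$class_used[i]
    m <- d[, paste0("mean_", cl)]
    if ("sdSpecies" %in% colnames(d)) {
      # species effects are not monitored individually; conditional mean uses
      # the class-level mean (species effect integrates to zero)
      m <- m
    }
    hc <- paste0("hom_", tab$homolog_id[i])
    if (hc %in% colnames(d)) m <- m + d[, hc]
    s2 <- d[, paste0("sdResid_", cl)]^2
    se2 <- tab$se_used[i]^2
    w <- (1 / se2) / (1 / se2 + 1 / s2)
    mean(w * tab$omega_a[i] + (1 - w) * m)
  }, 0)
}

#' Sequential variance decomposition of per-gene omega_A
#'
#' Sequential (type-I) sums of squares with species entered first, then the
#' gene-class factors (pathway and homolog); the residual is gene-within-
#' species variation. Percentages of the total sum of squares are returned.
#'
#' @param table an omega table (as in \code{\link{fitMeta}}) with pathway
#'   and homolog_id columns.
#' @return list with \code{pctSpecies}, \code{pctGenePlusPathway},
#'   \code{pctResidual} (summing to 100) and the anova table.
#' @export
variancePartition <- function(table) {
  req <- c("species_id", "omega_a")
  stopifnot(all(req %in% names(table)))
  table$homolog_id <- if (is.null(table$homolog_id)) table$gene_id else table$homolog_id
  table$pathway <- if (is.null(table$pathway)) "control" else table$pathway
  fml <- stats::as.formula("omega_a ~ factor(species_id) + factor(pathway) + factor(homolog_id)")
  fit <- stats::lm(fml, data = table)
  if (any(is.na(stats::coef(fit))[seq_len(nlevels(factor(table$species_id)))]))
    stop("rank-deficient design: species effects not estimable")
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  names(ss) <- rownames(an)
  total <- sum(ss)
  pctSpecies <- 100 * ss[["factor(species_id)"]] / total
  pctGene <- 100 * (sum(ss[grep("pathway|homolog", names(ss))])) / total
  pctResid <- 100 * ss[["Residuals"]] / total
  list(pctSpecies = pctSpecies, pctGenePlusPathway = pctGene,
       pctResidual = pctResid, anova = an)
}
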