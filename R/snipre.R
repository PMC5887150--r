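# Cross-species hierarchical Bayesian Poisson model of MK counts. The four
# counts per gene x species (Ps, Pn, Ds, Dn) are modeled as
# y ~ Poisson(exp(eta)) with
#   eta = offset + mu + bN I_N + bD I_D + bND I_N I_D
#         + species terms + pathway terms + gene/homolog deviations
#         + observation-level overdispersion,
# where the offset is log L_N for nonsynonymous rows and log L_S for
# synonymous rows. The nonsynonymous x divergence interaction is the
# "selection effect": positive values indicate adaptive excess, negative
# values constraint. The reference species and the control pathway are fixed
# at zero, so species and pathway effects are contrasts against them.

#' Specification of the hierarchical count model
#'
#' @param species include species fixed effects (and species interactions
#'   with N, D, ND); "auto" includes them when more than one species is
#'   present. The first species level is the reference.
#' @param pathway include pathway x {N, ND} fixed effects ("auto": when more
#'   than one pathway level is present; reference = "control").
#' @param pirnaFunction include piRNA-function x {N, ND} fixed effects
#'   ("auto": when informative labels are present; reference = "none").
#' @param geneRE gene-within-species random deviations on (1, N, D, ND).
#' @param homologRE homolog random deviations on (N, ND) ("auto": when
#'   homolog ids are present).
#' @param overdispersion observation-level log-normal overdispersion.
#' @param referenceSpecies optional reference species id.
#' @param priorSdFixed SD of the normal prior on fixed effects (default 10).
#' @param priorScaleRandom scale of the half-Cauchy prior on random-effect
#'   SDs (default 1).
#' @return a model-spec list.
#' @export
snipreModelSpec <- function(species = "auto", pathway = "auto",
                            pirnaFunction = "auto", geneRE = TRUE,
                            homologRE = "auto", overdispersion = TRUE,
                            referenceSpecies = NULL, priorSdFixed = 10,
                            priorScaleRandom = 1) {
  list(species = species, pathway = pathway, pirnaFunction = pirnaFunction,
       geneRE = geneRE, homologRE = homologRE, overdispersion = overdispersion,
       referenceSpecies = referenceSpecies, priorSdFixed = priorSdFixed,
       priorScaleRandom = priorScaleRandom)
}

.autoOn <- function(flag, cond) isTRUE(flag) || (identical(flag, "auto") && cond)

#' Fit the cross-species hierarchical count model
#'
#' @param records data.frame of MK records (one row per gene x species with
#'   Pn, Ps, Dn, Ds, L_N, L_S and label columns), e.g. from
#'   \code{\link{simMKTable}} or \code{\link{readCountsTable}}.
#' @param spec a \code{\link{snipreModelSpec}}.
#' @param mcmc list of MCMC settings overriding the defaults
#'   (2 chains x 5000 draws after 1000 adaptation + 1000 burn-in).
#' @return a \linkS4class{SnipreFit}.
#' @export
fitSnipre <- function(records, spec = snipreModelSpec(), mcmc = list()) {
  req <- c("gene_id", "species_id", "Pn", "Ps", "Dn", "Ds", "L_N", "L_S")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (any(records$L_N <= 0 | records$L_S <= 0)) stop("invalid offsets: L_N and L_S must be positive")
  sp <- factor(records$species_id)
  if (!is.null(spec$referenceSpecies)) sp <- stats::relevel(sp, spec$referenceSpecies)
  pw <- factor(if (is.null(records$pathway)) rep("control", nrow(records))
               else ifelse(is.na(records$pathway), "control", records$pathway))
  if ("control" %in% levels(pw)) pw <- stats::relevel(pw, "control")
  pf <- factor(if (is.null(records$pirna_function)) rep("none", nrow(records))
               else ifelse(is.na(records$pirna_function), "none", records$pirna_function))
  if ("none" %in% levels(pf)) pf <- stats::relevel(pf, "none")
  gene <- factor(paste(records$species_id, records$gene_id, sep = "/"))
  hasHom <- !is.null(records$homolog_id) && any(!is.na(records$homolog_id))
  hom <- factor(if (hasHom) records$homolog_id else rep("h", nrow(records)))

  useSp <- .autoOn(spec$species, nlevels(sp) > 1L)
  usePw <- .autoOn(spec$pathway, nlevels(pw) > 1L)
  usePf <- .autoOn(spec$pirnaFunction, nlevels(pf) > 1L)
  useHom <- .autoOn(spec$homologRE, hasHom && nlevels(hom) > 1L)
  useGene <- isTRUE(spec$geneRE)
  useOd <- isTRUE(spec$overdispersion)

  R <- nrow(records)
  long <- data.frame(
    y = c(records$Pn, records$Ps, records$Dn, records$Ds),
    IN = rep(c(1, 0, 1, 0), each = R),
    ID = rep(c(0, 0, 1, 1), each = R),
    logL = c(log(records$L_N), log(records$L_S), log(records$L_N), log(records$L_S)),
    sp = rep(as.integer(sp), 4), pw = rep(as.integer(pw), 4),
    pf = rep(as.integer(pf), 4), gene = rep(as.integer(gene), 4),
    hom = rep(as.integer(hom), 4))
  long$INID <- long$IN * long$ID

  tauF <- 1 / spec$priorSdFixed^2
  hc <- sprintf("dt(0, %g, 1) T(0,)", 1 / spec$priorScaleRandom^2)
  eta <- "logL[i] + mu + bN*IN[i] + bD*ID[i] + bND*INID[i]"
  blocks <- character(0)
  if (useSp) {
    eta <- paste0(eta, " + spM[sp[i]] + spN[sp[i]]*IN[i] + spD[sp[i]]*ID[i] + spND[sp[i]]*INID[i]")
    blocks <- c(blocks, sprintf(
      " spM[1] <- 0\n spN[1] <- 0\n spD[1] <- 0\n spND[1] <- 0\n for(s in 2:S){ spM[s] ~ dnorm(0,%g)\n spN[s] ~ dnorm(0,%g)\n spD[s] ~ dnorm(0,%g)\n spND[s] ~ dnorm(0,%g) }",
      tauF, tauF, tauF, tauF))
  }
  if (usePw) {
    eta <- paste0(eta, " + pwN[pw[i]]*IN[i] + pwND[pw[i]]*INID[i]")
    blocks <- c(blocks, sprintf(
      " pwN[1] <- 0\n pwND[1] <- 0\n for(p in 2:P){ pwN[p] ~ dnorm(0,%g)\n pwND[p] ~ dnorm(0,%g) }",
      tauF, tauF))
  }
  if (usePf) {
    eta <- paste0(eta, " + pfN[pf[i]]*IN[i] + pfND[pf[i]]*INID[i]")
    blocks <- c(blocks, sprintf(
      " pfN[1] <- 0\n pfND[1] <- 0\n for(f in 2:F){ pfN[f] ~ dnorm(0,%g)\n pfND[f] ~ dnorm(0,%g) }",
      tauF, tauF))
  }
  if (useGene) {
    eta <- paste0(eta, " + g0[gene[i]] + gN[gene[i]]*IN[i] + gD[gene[i]]*ID[i] + gND[gene[i]]*INID[i]")
    blocks <- c(blocks, paste0(
      " for(g in 1:G){ g0[g] ~ dnorm(0,tauG0)\n gN[g] ~ dnorm(0,tauGN)\n gD[g] ~ dnorm(0,tauGD)\n gND[g] ~ dnorm(0,tauGND) }\n",
      " sdG0 ~ ", hc, "\n sdGN ~ ", hc, "\n sdGD ~ ", hc, "\n sdGND ~ ", hc, "\n",
      " tauG0 <- pow(sdG0,-2)\n tauGN <- pow(sdGN,-2)\n tauGD <- pow(sdGD,-2)\n tauGND <- pow(sdGND,-2)"))
  }
  if (useHom) {
    eta <- paste0(eta, " + hN[hom[i]]*IN[i] + hND[hom[i]]*INID[i]")
    blocks <- c(blocks, paste0(
      " for(h in 1:H){ hN[h] ~ dnorm(0,tauHN)\n hND[h] ~ dnorm(0,tauHND) }\n",
      " sdHN ~ ", hc, "\n sdHND ~ ", hc, "\n tauHN <- pow(sdHN,-2)\n tauHND <- pow(sdHND,-2)"))
  }
  if (useOd) {
    eta <- paste0(eta, " + eps[i]")
    blocks <- c(blocks, paste0(" for(j in 1:Nobs){ eps[j] ~ dnorm(0,tauE) }\n sdE ~ ",
                               hc, "\n tauE <- pow(sdE,-2)"))
  }
  model <- paste0(
    "model{\n for(i in 1:Nobs){ y[i] ~ dpois(lam[i])\n  log(lam[i]) <- ", eta, " }\n",
    sprintf(" mu ~ dnorm(0,%g)\n bN ~ dnorm(0,%g)\n bD ~ dnorm(0,%g)\n bND ~ dnorm(0,%g)\n",
            tauF, tauF, tauF, tauF),
    paste(blocks, collapse = "\n"), "\n}")

  dat <- list(y = long$y, Nobs = nrow(long), logL = long$logL, IN = long$IN,
              ID = long$ID, INID = long$INID)
  if (useSp) { dat$sp <- long$sp; dat$S <- nlevels(sp) }
  if (usePw) { dat$pw <- long$pw; dat$P <- nlevels(pw) }
  if (usePf) { dat$pf <- long$pf; dat$F <- nlevels(pf) }
  if (useGene) { dat$gene <- long$gene; dat$G <- nlevels(gene) }
  if (useHom) { dat$hom <- long$hom; dat$H <- nlevels(hom) }

  monitors <- c("mu", "bN", "bD", "bND",
                if (useSp) c("spND", "spN", "spM", "spD"),
                if (usePw) c("pwN", "pwND"), if (usePf) c("pfN", "pfND"),
                if (useGene) c("gND", "sdG0", "sdGN", "sdGD", "sdGND"),
                if (useHom) c("hND", "sdHN", "sdHND"), if (useOd) "sdE")
  mc <- .mcmcDefaults(mcmc)
  draws <- .runJags(model, dat, monitors, mc)
  diag <- attr(draws, "diagnostics")
  bad <- diag$param[!is.na(diag$rhat) & diag$rhat > 1.05]
  if (length(bad) > 0L)
    warning("R-hat > 1.05 for: ", paste(utils::head(bad, 10), collapse = ", "))
  new("SnipreFit", draws = draws, diagnostics = diag, records = records,
      spec = c(spec, list(useSp = useSp, usePw = usePw, usePf = usePf,
                          useGene = useGene, useHom = useHom, useOd = useOd)),
      levels = list(species = levels(sp), pathway = levels(pw),
                    pirnaFunction = levels(pf), gene = levels(gene),
                    homolog = levels(hom)))
}

# posterior draws of the selection effect for a given unit
.selectionDraws <- function(fit, unit, id) {
  d <- fit@draws
  sp <- fit@spec
  lv <- fit@levels
  col <- function(nm) if (nm %in% colnames(d)) d[, nm] else 0
  meanSpND <- if (sp$useSp) {
    cols <- sprintf("spND[%d]", seq_along(lv$species))
    present <- cols %in% colnames(d)
    # reference species term is fixed at 0 and not monitored
    rowSums(d[, cols[present], drop = FALSE]) / length(lv$species)
  } else 0
  base <- d[, "bND"] + meanSpND
  if (unit == "overall") return(base)
  recs <- fit@records
  if (unit == "species") {
    i <- match(id, lv$species)
    if (is.na(i)) stop("unknown species id: ", id)
    return(d[, "bND"] + if (i == 1L) 0 else col(sprintf("spND[%d]", i)))
  }
  if (unit == "pathway") {
    i <- match(id, lv$pathway)
    if (is.na(i)) stop("unknown pathway: ", id)
    return(base + if (i == 1L) 0 else col(sprintf("pwND[%d]", i)))
  }
  if (unit == "homolog") {
    i <- match(id, lv$homolog)
    if (is.na(i)) stop("unknown homolog id: ", id)
    r <- recs[!is.na(recs$homolog_id) & recs$homolog_id == id, , drop = FALSE][1, ]
    pwi <- match(ifelse(is.na(r$pathway), "control", r$pathway), lv$pathway)
    out <- base + col(sprintf("hND[%d]", i))
    if (sp$usePw && pwi > 1L) out <- out + col(sprintf("pwND[%d]", pwi))
    return(out)
  }
  if (unit == "gene") {
    key <- paste(recs$species_id, recs$gene_id, sep = "/")
    ri <- match(id, key)
    if (is.na(ri)) ri <- which(recs$gene_id == id)[1]
    if (is.na(ri)) stop("unknown gene id: ", id)
    r <- recs[ri, ]
    gi <- match(paste(r$species_id, r$gene_id, sep = "/"), lv$gene)
    spi <- match(r$species_id, lv$species)
    pwi <- match(ifelse(is.na(r$pathway), "control", r$pathway), lv$pathway)
    pfi <- match(ifelse(is.na(r$pirna_function), "none", r$pirna_function), lv$pirnaFunction)
    out <- d[, "bND"]
    if (sp$useSp && spi > 1L) out <- out + col(sprintf("spND[%d]", spi))
    if (sp$usePw && pwi > 1L) out <- out + col(sprintf("pwND[%d]", pwi))
    if (sp$usePf && pfi > 1L) out <- out + col(sprintf("pfND[%d]", pfi))
    if (sp$useHom && !is.na(r$homolog_id))
      out <- out + col(sprintf("hND[%d]", match(r$homolog_id, lv$homolog)))
    if (sp$useGene) out <- out + col(sprintf("gND[%d]", gi))
    return(out)
  }
  stop("unknown unit: ", unit)
}

#' Posterior summary of a unit-level selection effect
#'
#' The unit-level selection effect sums every posterior contribution to the
#' unit's nonsynonymous x divergence coefficient (fixed effects plus the
#' relevant species, pathway, homolog and gene terms). Pathway- and
#' overall-level effects average the species interaction over species.
#'
#' @param fit a \linkS4class{SnipreFit}.
#' @param unit one of "overall", "species", "pathway", "homolog", "gene".
#' @param id unit identifier (not needed for "overall").
#' @return list with \code{estimate} (posterior mean), \code{ci} (central
#'   95\%), \code{mcmcp} and the \code{draws}.
#' @export
selectionEffect <- function(fit, unit = c("overall", "species", "pathway",
                                          "homolog", "gene"), id = NULL) {
  unit <- match.arg(unit)
  dr <- .selectionDraws(fit, unit, id)
  list(estimate = mean(dr),
       ci = c(.quantile7(dr, 0.025), .quantile7(dr, 0.975)),
       mcmcp = mcmcP(dr), draws = dr)
}

#' Fraction of units with significantly positive selection effects
#'
#' A unit counts as positively selected when its MCMCp is below the
#' threshold and its posterior mean selection effect is positive; fractions
#' are reported per gene class (RNAi vs control).
#'
#' @param fit a \linkS4class{SnipreFit}.
#' @param units unit level, currently "gene".
#' @param threshold MCMCp threshold (default 0.05).
#' @return list with \code{fractions} per class and the per-unit table.
#' @export
classifySelected <- function(fit, units = "gene", threshold = 0.05) {
  stopifnot(identical(units, "gene"))
  recs <- fit@records
  key <- paste(recs$species_id, recs$gene_id, sep = "/")
  per <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
    dr <- .selectionDraws(fit, "gene", key[i])
    data.frame(gene_id = recs$gene_id[i], species_id = recs$species_id[i],
               is_rnai = isTRUE(recs$is_rnai[i]), estimate = mean(dr),
               mcmcp = mcmcP(dr), stringsAsFactors = FALSE)
  }))
  per$selected <- per$mcmcp < threshold & per$estimate > 0
  frac <- stats::aggregate(selected ~ is_rnai, data = per, FUN = mean)
  list(fractions = frac, perUnit = per)
}
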