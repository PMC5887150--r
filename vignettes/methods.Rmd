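---
title: "Models and methods in rnaiAdapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rnaiAdapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rnaiAdapt asks a comparative question: do genes of a functional class — here
RNA-interference (RNAi) pathway genes, with miRNA, endo-siRNA, viRNA and
piRNA subpathways — accumulate adaptive amino-acid substitutions faster than
matched control genes, across species? The package implements the full
inference stack for that question on four complementary fronts: MK-style
count contrasts, explicit population-genetic estimation of the adaptive
substitution rate, a hierarchical Bayesian model of the raw counts, and
scans for recent selective sweeps. A synthetic-data module generates every
input with recorded truth, so each stage is testable end to end without
external data.

## MK counts from codon alignments

`tabulateMK()` consumes an in-frame alignment of ingroup haplotypes plus one
outgroup (`CodonAlignment`). Polymorphism is counted within the ingroup:
each segregating position is classified synonymous or nonsynonymous against
the codon consensus background (the consensus is majority-rule, ties broken
by the first-listed sequence, gaps outvoted by bases). Divergence is counted
between the ingroup consensus and the outgroup; codons differing at more
than one position are scored by averaging over minimal mutational pathways,
excluding pathways through stop codons (if every pathway is blocked, all are
used with steps into stops scored nonsynonymous). Site totals $L_N$ and
$L_S$ are NG86-style fractional counts over the nine single-nucleotide
neighbors of each consensus codon; changes to stops are excluded from both
numerator and denominator so each position contributes exactly one site and
$L_N + L_S = 3 \times$ (unmasked codons) to machine precision.

The original analyses this package follows used a codon-model ML method
(yn00) for between-species counts; rnaiAdapt deliberately uses NG86-style
counting instead — it is transparent, exactly testable against the genetic
code, and adequate at the divergence levels involved (1–10%), though
divergence estimates can differ slightly from codon-model ML under strong
base-composition or transition/transversion skew. No multiple-hit
(Jukes–Cantor) correction is applied: counts stay integers and any such
correction belongs downstream.

Two alignment-QC filters mirror the usual manual curation:
`maskDivergentWindows()` masks non-overlapping windows whose divergence
exceeds the mean by more than `sdThreshold` (default 6) standard deviations
across windows, and `trimMisalignedBlocks()` masks codon blocks whose
amino-acid identity to the consensus falls below a threshold — an automated
surrogate for removing misassembled gene ends by eye.

`mkTest()` is the classical contrast: $\alpha_{MK} = 1 - (D_s P_n)/(D_n
P_s)$ with a two-sided Fisher exact test on the 2×2 table. Degenerate
tables ($D_n = 0$ or $P_s = 0$) are flagged, never imputed.

## The paired SFS and the DFE model

`extractSFS()` polarizes each segregating site by parsimony against the
outgroup and records its derived-allele count into the synonymous (neutral)
or nonsynonymous (selected) spectrum. Sites whose outgroup state matches
neither allele are folded (assigned the minor count), and ingroup-invariant
sites — including fixed differences — enter folded invariant classes with
fractional synonymous/nonsynonymous weights from the per-position site
counts. Keeping the invariant mass matters twice: it anchors the per-site
mutation scale in the DFE fit, and a deficit of diversity is the signature
the sweep scan looks for.

`fitDFE()` estimates, in two stages, (1) a two-epoch demography (size ratio
$N_2/N_1$, time $t_2$ since the change in units of the current size) from
the neutral SFS and (2) a gamma distribution of deleterious fitness effects
from the selected SFS conditional on that demography. Expected spectra come
from a discretized Wright–Fisher transition matrix on `nRef` (default 100)
gene copies with mutational influx, hypergeometrically downsampled to the
sample size; the likelihood is product-multinomial over SFS classes
including the monomorphic class. Folding is the default (robust to
mispolarization in real data); unfolded fits are available by flag.

Derived quantities use the relative fixation rate $r(S) = S/(1 - e^{-S})$,
$r(0) = 1$: the nonadaptive rate is $\omega_{na} = \int r(S)\,
\phi(S)\,dS$ over the fitted deleterious DFE, the observed rate is
$\omega_{obs} = (D_n/L_N)/(D_s/L_S)$, and

$$\alpha = 1 - \omega_{na}/\omega_{obs}, \qquad
  \omega_A = \omega_{obs} - \omega_{na},$$

with negative values reported as-is — a class can fix fewer nonsynonymous
changes than its deleterious DFE predicts.

### Numerical choices that matter

* **Scale of $S$.** The gamma DFE is parameterized on the *ancestral*
  population scale: the ancestral-epoch transition matrix uses $S$ and the
  post-change epoch uses $S \cdot N_2/N_1$. With the alternative
  (current-size) convention, a constant-size history leaves $(N_2/N_1,
  t_2)$ on an exactly flat likelihood ridge along which the gamma rescales
  freely and $\omega_{na}$ is arbitrary; ancestral scaling pins the DFE on
  the scale of the epoch in which interspecies divergence accumulated,
  which is also the scale $r(S)$ needs.
* **Shared mutation scale.** A single per-site scale $\theta$ (profiled in
  closed form) multiplies both expected spectra. Giving the selected
  spectrum its own scale makes weakly deleterious mass nearly
  unidentifiable — it barely reshapes the SFS yet lowers $\omega_{na}$ at
  first order — and inflates $\omega_A$ on neutral data several-fold.
* **Demography ties.** When the neutral SFS cannot distinguish demographies
  (flat ridge), near-tied stage-1 optima are re-scored by the joint
  neutral+selected likelihood, with a parsimony tie-break: a constant-size
  candidate is always offered and, within 2 log-likelihood units, the
  smallest size change wins.
* **Continuity in $t_2$.** The forward iteration runs an integer number of
  generations; the occupancy is linearly interpolated between adjacent
  integer counts so the likelihood is continuous in $t_2$ (a requirement
  for the bounded quasi-Newton optimizer, which otherwise stalls on a
  piecewise-constant coordinate).
* **Spectra reuse.** Per-$S$ expected spectra are computed once per
  demography on a 32-point log grid over $|S| \in [10^{-4}, 10^5]$ and
  integrated against the gamma by midpoint mass; doubling the grid changes
  the mixture by well under 1%. Transition matrices are diagonalized and
  cached where cleanly possible (neutral and weak selection — the
  optimizer's hot path), with direct solves and iteration as the fallback
  for near-defective strong-selection matrices.
* **Optimization.** Both stages use L-BFGS-B from 8 fixed log-grid starts.

### A known, quantified limitation

The DFE is deleterious-only (gamma on $S \le 0$, the cited approach's
default). On exactly neutral data, maximum likelihood can absorb sampling
noise only on the deleterious side of the boundary, so $\hat\omega_A$ has a
small positive bias: at $L_N = 10^6$ sites, $n = 20$, $\theta = 0.01$, the
~1% sampling noise of the selected-to-neutral polymorphism ratio is
absorbed as weak deleterious mass with roughly 2.4× leverage on
$\omega_{na}$, giving a mean bias near $+0.01$. The bias shrinks as
$1/\sqrt{L}$ and is irrelevant compared to the effect sizes of interest
(class differences of 0.05 and more), but it is why the neutral-limit
acceptance check averages over the full 20-replicate design.

Class-level machinery: `poolAndEstimate()` sums spectra across genes before
fitting; `bootstrapCI()` resamples genes (class CIs) or sites
(multinomial/Poisson, the per-gene SE variant), refitting the demography
per resample from a warm start with spectra grids memoized on a rounded
demography lattice; `permutationTest()` permutes class labels with the
demography fixed to the combined fit — demography is a property of the
species, not of a gene class — and `lrtSharedVsSeparate()` compares a
shared gamma against class-specific gammas (df = 2) on the same principle.

## The hierarchical count model

`fitSnipre()` reframes the MK contrast as a log-linear model of the four
counts per gene × species, $y \sim \text{Poisson}(e^\eta)$ with

$$\eta = \log L + \mu + \beta_N I_N + \beta_D I_D + \beta_{ND} I_N I_D
        + \text{species} + \text{pathway} + \text{gene} + \text{homolog}
        + \varepsilon,$$

where the offset $\log L$ is $\log L_N$ for nonsynonymous rows and $\log
L_S$ for synonymous rows. The nonsynonymous×divergence coefficient is the
**selection effect**: positive means adaptive excess, negative constraint.
Species enter as fixed effects with interactions on $\{N, D, ND\}$ relative
to a reference species; pathway (reference: control) and piRNA functional
class (reference: none) act on $\{N, ND\}$; genes-within-species carry
random deviations on all four terms and homologs on $\{N, ND\}$;
observation-level log-normal overdispersion mops up extra-Poisson noise.
`selectionEffect()` sums every posterior contribution to a unit's $I_N I_D$
coefficient (pathway- and overall-level effects average the species
interactions); `mcmcP()` is the two-sided posterior-tail measure
$\max(2\min(\#>0, \#<0)/n,\ 2/n)$; `classifySelected()` reports the
fraction of units with MCMCp below threshold and positive posterior mean.

Priors are weakly informative — normal(0, 10²) on fixed effects,
half-Cauchy(1) on random-effect SDs — and the test suite checks posterior
insensitivity to halving/doubling the fixed-effect prior scale. Sampling
uses JAGS with its GLM block samplers; defaults are 2 chains × 5,000 draws
after 1,000 adaptation + 1,000 burn-in, with R-hat > 1.05 flagged. The
original analysis fit this model with MCMCglmm; any general MCMC engine
serves, and the calibration tests (interval coverage under a null
selection effect) are the check that the engine and priors behave.

## Meta-analysis of per-gene omega_A

`fitMeta()` combines per-gene $\hat\omega_A$ estimates across species in a
measurement-error mixed model: marginally
$$\hat\omega_{A,i} \sim N(\beta_{class(i)} + u_{species(i)}
   (+ h_{homolog(i)}),\; se_i^2 + \sigma^2_{class(i)}),$$
with the bootstrap SE entering as known error variance and the residual
gene-level variance class-specific. Model variants follow the analysis
ladder: RNAi vs control, pathway, piRNA functional class, and homolog-level
models with and without the pathway fixed effect. Zero SEs are floored at
the smallest positive SE in the table. `compareVariances()` contrasts
residual variances and coefficients of variation ($\sqrt{\sigma^2}/|\mu|$,
flagged when a class-mean posterior straddles 0), `predictedMeans()` gives
the per-gene precision-weighted shrinkage predictions (large SE → class
mean; tiny SE → own estimate), and `variancePartition()` performs the
sequential (type-I) sums-of-squares decomposition with species entered
first, then pathway + homolog, leaving gene-within-species as the residual.

## Sweep scans

`sweepSpectrum()` is the generative hitchhiking transform, computed exactly
by enumeration: each of $n$ lineages escapes the sweep independently with
probability $p_e$; the escapees plus one merged lineage draw derived states
by hypergeometric downsampling of the background spectrum; the merged
lineage's state is replicated to its $n-k$ descendants. Its limits are the
identities the tests pin down: $p_e = 1$ returns the background, $p_e = 0$
puts all mass on monomorphic classes.

`clrScan()` evaluates, at each grid point, the composite likelihood of all
sites under a sweep centered there — per site $p_e = 1 - e^{-\alpha_s d}$
with $d$ the distance in bp, so larger $\alpha_s$ means weaker hitchhiking
— maximized over a log grid of $\alpha_s$ that always includes the neutral
limit, guaranteeing CLR ≥ 0. Folded-invariant sites contribute the sum of
their two classes; including invariant sites is what gives the scan its
power, since a recent sweep's clearest mark is missing diversity. The
background spectrum defaults to the analyzed region's own site-class
frequencies (folded-invariant mass split equally between the ancestral and
derived monomorphic classes, which the transform's symmetry makes
inconsequential), with a genome-wide spectrum acceptable as input.
Significance comes from `sweepThreshold()`, the type-7 95th percentile of
max-CLR over neutral replicate regions matched for length, sample size and
site density — generated either by the no-recombination coalescent or by
independent-sites draws from a background spectrum (`simNeutralRegion()`,
both modes exposed because the regions scanned are short relative to the
original 200-kb windows and the true simulation settings are a judgment
call). `callSweepRegions()` merges significant grid points within 1 kb into
broad peaks, `sweepEnrichment()` tests whether RNAi genes carry more
sweep-positive calls than their summed length predicts (one-sided exact
binomial; the length-share construction is one reading of the procedure —
the alternative, per-class gene counts, is noted), and
`normalizedClrModel()` fits threshold-normalized per-gene maxima
($\widetilde{CLR} = \max CLR / \text{threshold}$) with a pathway fixed
effect and species random effect, reporting the species share of variance.

`nslScan()` is the haplotype statistic: for site $i$ and a haplotype pair,
$L$ is the length (in segregating sites) of the maximal run containing $i$
over which the pair is identical; raw nSL is
$\ln(SL_{anc}/SL_{der})$ of the pair-averaged run lengths, standardized
within derived-frequency bins of equal occupancy. Runs stop at matrix
edges; sites with fewer than 2 carriers of either allele are skipped. The
implementation is vectorized over pairs and verified against an
$O(n^2m^2)$ brute-force enumeration.

## What the generators emulate — and what they do not

The synthetic-data module draws from exactly the models the analyses
assume: Poisson counts from the log-linear hierarchy (`simMKTable()`),
multinomial spectra from the Wright–Fisher expectations plus Poisson
divergence with a configured $\omega_A$ excess (`simSFSDataset()`), a
standard neutral coalescent without recombination (`simNeutralRegion()`),
per-site draws from the hitchhiking transform (`simSweepRegion()`), and
codon alignments with single-mutation placements, no internal stops,
divergence on the outgroup lineage only and derived alleles always below
half-frequency so the consensus equals the ancestor
(`simCodonAlignment()`). All streams derive from the master seed by stable
hashing of (operation, replicate), so outputs are byte-identical under a
fixed seed and insensitive to reordering.

Defaults are sized to a Drosophila-like setting: $\theta = 0.01$ per site,
gamma DFE with mean $|N_e s| = 50$ and shape 0.4, synonymous divergence
0.05 per site, genes of 200–800 codons with $L_N : L_S \approx 2.2 : 0.8$
per codon, and count-model fixed effects $\mu = -1.5$, $\beta_N = -1.4$,
$\beta_D = 0.5$ (synonymous diversity ~0.2 per site-unit offset, a ~4-fold
nonsynonymous deficit, divergence exceeding polymorphism). What passing
tests show is therefore *internal* correctness — estimators recover the
parameters of their own generative models at realistic sizes. Real data add
everything the generators omit: recombination, linked selection beyond the
single-sweep model, sequencing error and depth filtering, alignment error
beyond the modeled QC filters, base-composition and mutation-rate
heterogeneity, and mispolarization. The folded default in `fitDFE()` and
the QC filters exist for those realities even though the simulations do not
exercise them.

## Problem sizes used by the test suite

The acceptance-style tests run at sizes chosen to finish in minutes on one
CPU: DFE recovery uses 20 replicates at $L_N = 10^6$, $n = 20$ with
60-resample site bootstraps; the count-model calibration uses 40 replicates
of 500 genes with short single chains (the fixed-effect model matches the
all-zero generative configuration, so no latent structure is needed);
meta-analysis recovery uses 20 replicates of 36 genes per class across 3
species; sweep localization uses 20 replicates of 10-kb regions at
$n = 12$; and the hitchhiking transform is checked against a $10^6$-draw
Monte-Carlo oracle. The same machinery scales to the real-data regime
(hundreds of genes, 200-kb scan windows) at proportional cost.
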