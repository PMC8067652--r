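---
title: "Latent variable models, residual networks and context-dependent microbial interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lvmnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Soil microbial communities respond jointly to measured environmental
gradients (elevation, pH, carbon and nitrogen pools, dissolved organic
matter quality, phosphorus, geography) and to each other.  Raw co-occurrence
statistics confound the two: taxa that track the same gradient co-occur
without interacting.  `lvmnet` implements the model-based route to
separating them — a Bayesian negative-binomial generalized linear latent
variable model (GLLVM) — together with the downstream quantities that make
the separation scientifically useful: HPD-interval significance and niche
breadth, variance partitioning across covariate groups, residual
co-occurrence networks with closeness centrality, and covariate-adjusted /
conditional rank correlations that detect shifts between facilitation and
competition along a gradient.

## The model

For counts $y_{ij}$ of taxon $j$ in site $i$:

$$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_j), \qquad
\mathrm{Var}(y_{ij}) = \mu_{ij} + \mu_{ij}^2/\phi_j,$$
$$\log \mu_{ij} = \alpha_i + \beta_{0j} + \mathbf{x}_i^\top \boldsymbol\beta_j
  + \mathbf{z}_i^\top \boldsymbol\lambda_j .$$

* $\alpha_i$ is a per-site (sample) effect that absorbs sequencing depth —
  the model's compositionality correction.
* $\mathbf{x}_i$ holds the standardized covariates (zero mean, unit sample
  SD), so coefficients are comparable across covariates.
* $\mathbf{z}_i \in \mathbb{R}^d$ (default $d = 2$) are latent site scores
  with iid standard-normal priors; $\boldsymbol\lambda_j$ are taxon
  loadings.  The matrix $\Omega = \Lambda\Lambda^\top$, normalized to a
  correlation, is the **residual correlation**: co-occurrence *not*
  attributable to the measured covariates, read as potential biotic
  interaction.

Priors are weakly informative: normal(0, 10²) on intercepts and covariate
coefficients, normal(0, 1.5²) on free loadings (half-normal on the
constrained diagonal), and exponential(0.1) on $1/\phi_j$.

### Identifiability: what we learned the hard way

Two design choices here departed from the obvious construction, both for
identifiability reasons that showed up empirically as multi-chain
disagreement and mis-calibrated intervals:

1. **Row effects are hierarchical, not free fixed effects.**  A free
   per-site effect can absorb *any* site-level pattern shared across taxa.
   In particular, because every $x_{ik}$ is shared by all taxa and sums to
   zero across sites, the transformation
   $\beta_{jk} \to \beta_{jk} + c$ (all $j$),
   $\alpha_i \to \alpha_i - c\,x_{ik}$ leaves the likelihood unchanged —
   a flat ridge that a sum-to-zero constraint does **not** remove.  The same
   holds against common shifts of a loading column paired with
   $-c\,z_{il}$.  We therefore model
   $\alpha_i \sim N(0, \sigma_\alpha^2)$ with $\sigma_\alpha$ estimated
   (half-normal hyperprior): the learned shrinkage closes the ridges while
   still absorbing depth.  Reported draws are additionally projected so
   that $\alpha \perp \mathrm{span}(1, X)$, with the projection folded into
   $\beta_0$ and $\beta$; reported row effects thus satisfy the
   conventional sum-to-zero constraint exactly.
2. **The loading prior is unit-scale (SD 1.5), not SD 10.**  Loadings act
   on unit-variance latent scores; with a very diffuse loading prior the
   posterior drifts along the joint rescaling
   $(\mathbf{z}/c,\; c\boldsymbol\lambda)$ and the factor–covariate
   alignment ridge, inflating every coefficient's posterior width.  With a
   unit-scale prior, simulated 95% HPD coverage sits at its nominal level
   (the acceptance suite checks 90–98% coverage and a 2–9% false-positive
   rate on true zeros).

Rotation and sign of the factors are fixed structurally (upper triangle of
the leading $d \times d$ loading block is zero; diagonals positive).  When
an anchor diagonal sits near zero the column sign remains weakly identified
across chains; residual correlations and variance partitions are invariant
to such flips, so the convergence flag is computed from the
sign-identifiable blocks (alpha, beta0, beta, phi) and the loading R-hats
are reported but not gated on.

### Sampling

The posterior is explored with an adaptive Metropolis-within-Gibbs sampler
written in C++ (scalar random-walk updates, Robbins–Monro adaptation to a
0.44 acceptance rate, frozen after warmup), augmented with
likelihood-invariant moves that traverse the weakly identified directions
(factor location vs. intercepts, factor scale vs. loadings, factor–covariate
alignment vs. coefficients, loading shifts vs. row effects).  Defaults are
4 chains × 1000 draws after 1000 warmup; the test suite uses 2 × 500 (after
800–1000 warmup), which pilot runs show is enough for split-R̂ ≤ 1.1 on the
core blocks at the study scale (43 sites).  Convergence is summarized by
split-R̂ and an autocorrelation-based effective sample size; a fit with more
than 5% of core parameters above R̂ = 1.1 carries a warning flag.

## HPD intervals: significance and niche breadth

`hpd()` returns the minimal-width interval containing the requested
posterior mass (exact sorted-window search).  A coefficient is *positive* /
*negative* when its 95% HPD excludes zero, *non-significant* otherwise.
The interval's width doubles as a niche-breadth proxy: a taxon whose
coefficient for, say, TN is compatible with a wide range of values is read
as tolerant of the TN gradient.

## Variance partitioning

Per posterior draw and taxon, the variance over sites of the summed
within-group linear predictor ($\sum_{k \in g} x_{ik}\beta_{jk}$) is the
group component; the latent component is the variance of
$\mathbf{z}_i^\top\boldsymbol\lambda_j$.  Using the *summed* predictor keeps
within-group covariance (the C&N covariates are strongly correlated by
construction); cross-group covariance is excluded from the numerators, so
proportions are normalized to sum to one and the raw covariance remainder
is recorded separately.  Row effects are excluded — they model depth, not
ecology.  The latent component stays in the denominator, so "explained by
environment" is genuinely below 100%.  Distribution shape across taxa is
summarized by the adjusted Fisher–Pearson skewness
$g_1\sqrt{n(n-1)}/(n-2)$, and "more than 50% explained" uses a strict
inequality.

## Residual networks and closeness

Significance of $\rho_{jk}$ uses the equal-tailed 95% credible interval of
its draws (symmetric on the correlation scale; configurable).  The network
is unweighted and undirected over significant pairs, with the correlation
sign kept as an edge attribute.  Closeness of node $v$ in a component of
size $n_c$ within an $n$-node graph is

$$\mathrm{closeness}(v) = \frac{n_c - 1}{\sum_{u} d(v, u)} \cdot
  \frac{n_c - 1}{n - 1},$$

the component-size–scaled convention that keeps values comparable in
disconnected graphs; isolated taxa get zero (no detected interactions, no
centrality).  The niche test regresses closeness on the per-taxon HPD width
by ordinary least squares (the literature reports variance explained, so an
$r^2$-producing estimator is the right tool); the same regression with the
median significant residual correlation as response is also reported, since
both response choices circulate for this relationship and which one
produced the published 32–47% range is ambiguous.

## Conditional rank correlations and interaction shifts

Overdispersed counts break moment-based partial correlations.  We follow
the semiparametric route: a **cumulative probability model** (CPM) treats
every distinct response value as an ordinal category, so only ranks matter;
its **probability-scale residual**
$\mathrm{PSR}_i = P(Y < y_i \mid Z_i) - P(Y > y_i \mid Z_i)$ lies in
$[-1, 1]$ and, with no covariates, equals twice the mid-rank empirical CDF
minus one.  The covariate-adjusted (partial) Spearman correlation is the
Pearson correlation of the two PSR vectors; the conditional version
replaces the global moments with Gaussian-kernel Nadaraya–Watson smooths
along the modifier (rule-of-thumb bandwidth `bw.nrd0` by default):

$$\hat\rho(m) = \frac{S[\mathrm{PSR}_X \mathrm{PSR}_Y](m)}
 {\sqrt{S[\mathrm{PSR}_X^2](m)\, S[\mathrm{PSR}_Y^2](m)}}.$$

CPMs are fitted by Newton–Raphson exploiting the tridiagonal cutpoint block
of the Hessian (Thomas factorization + a small Schur complement), which
makes the per-fit cost $O(M + nk^2)$ and full CPM refits inside every
bootstrap resample affordable even with hundreds of categories.

A **shift** compares $\hat\rho$ at the 10th and 90th modifier percentiles:
direction is the sign of the difference, significance is a bootstrap 95%
interval of the difference excluding zero (sites resampled, CPMs refitted,
same bandwidth).  Any significant difference counts as a shift — a sign
flip is flagged separately — because published examples include both flips
and pure magnitude changes.  Phylum-level inputs are within-phylum sums of
order counts (preserving the count nature the CPM expects), and when the
modifier is one of elevation / C:N / pH the other two act as the adjustment
set (a modifier cannot adjust itself).  No multiplicity correction is
applied across phylum pairs by default, mirroring the HPD-style usage; a
Benjamini–Hochberg option exists behind a flag.

## The synthetic world

`simulate_environment()` draws covariates from a two-factor (soil
fertility, elevation) correlation structure — always positive semidefinite —
whose fertility factor reproduces the strong TC–TN/TC–DOC/TC–pH correlation
pattern of organic wetland soils, then standardizes; measurement-scale
means and SDs (e.g. elevation 3722 ± 550 m, pH 7.8 ± 0.7, C:N 14 ± 6)
follow a high-plateau wetland gradient.  `make_ground_truth()` defaults to
the study scale: 43 sites, ~80 order-level taxa (60% bacterial),
$d = 2$, sparse coefficients with magnitudes in {0.5, 1, 2}
(20% nonzero), dispersions $\phi_j \in [1, 5]$, intercepts around
$\log 30$, and row-effect SD 0.5 — chosen so desk-scale fits finish in
seconds to minutes.  `inject_conditional_dependence()` re-samples a taxon
pair from a Gaussian copula with NB margins preserved: correlation
`rho_low` in the lower modifier tercile, `rho_high` in the upper, their
mean in the middle (piecewise-constant, hence checkable, ground truth).
`simulate_niche_structure()` builds the specialist/generalist contrast used
by the niche-regression test: abundant, weakly overdispersed,
strongly-loaded specialists versus sparse, noisy, latent-free generalists.

What the generator does *not* emulate: taxonomic realism of abundance
profiles, spatial autocorrelation beyond what the covariate factors induce,
zero-inflation beyond NB, or the real study's taxon-specific parameters.  A
green recovery test therefore establishes that the estimators recover the
*statistical structure* they target, not that any real-data number is
reproduced.

## Numerical choices and degenerate inputs

* Standardization uses the sample SD ($n-1$); constant covariates are a
  hard error, missing cells are a hard error unless mean-imputation is
  explicitly enabled (and then logged).
* Prevalence filtering counts sites with count > 0 and keeps the boundary
  (≥ 5 of 43 sites by default).
* Quartiles in coefficient summaries use the $(n+1)p$ linear-interpolation
  convention (R `type = 6`), recorded in the output metadata; on three
  values it returns the extremes, matching how such summaries are printed
  in the field.
* `hpd()` on constant draws returns a width-zero interval; `prob = 1`
  returns the range.
* The CPM refuses constant responses, non-finite values and n < 10;
  non-convergence (e.g. complete separation) is an error, not a silent
  result.
* Taxa with exactly zero loading vectors in a draw contribute no residual
  correlation for that draw; such draws are excluded with a logged count.
* All stage seeds derive deterministically from one master seed
  (`derive_seed()`, always below $2^{31}$), so pipeline stages can be rerun
  independently yet reproducibly.

## Known limitations

* No model selection over $d$; no zero-inflated families; no phylogenetic
  priors.
* The Metropolis-within-Gibbs sampler is tuned for desk-scale problems
  (tens of sites, up to low hundreds of taxa); very large tables would
  want gradient-based sampling.
* Closeness uses hop distance on the unweighted significant-edge graph; no
  modularity or hub analysis is attempted.
* Real-data headline percentages from gradient studies depend on their raw
  count tables and are out of scope; the package's claims are the recovery
  properties its test suite computes.
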