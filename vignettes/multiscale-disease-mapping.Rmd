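---
title: "Multiscale disease mapping with shared spatial random effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale disease mapping with shared spatial random effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiscaleCAR)
```

## The problem

Public-health surveillance data are often published on nested
administrative geographies: outcome counts for fine units (counties) and,
by aggregation, for the coarse units (public-health districts) they nest
in. Coarse counts are sums of the nested fine counts; coarse covariates
such as median household income are averages. Aggregation smooths away
fine-scale spatial variation — the *scaling effect* — and a covariate that
predicts risk at the fine scale can appear unrelated to risk at the coarse
scale if the two levels are modelled separately. `multiscaleCAR` fits
two-level Bayesian convolution models that either ignore this linkage (the
*independent* multiscale model) or restore it through a shared spatially
structured random effect (the *shared* multiscale model), and quantifies
whether sharing improves fit and prediction.

## The models

At each scale level $k \in \{1,2\}$ (1 = fine, 2 = coarse), unit $i$
contributes a binomial observation

$$y_{ik} \sim \mathrm{Bin}(n_{ik},\, p_{ik}), \qquad
  \mathrm{logit}(p_{ik}) = \beta_{0k} + \beta_{1k} x_{ik} + v_{ik} +
  \varepsilon_{ik},$$

where $x_{ik}$ is the standardized covariate, $v_k$ is correlated
heterogeneity (CH) with an intrinsic CAR prior, and $\varepsilon_k$ is
uncorrelated heterogeneity (UH), $\varepsilon_{ik} \sim N(0,
\sigma_{\varepsilon k}^2)$. The ICAR prior is the improper
pairwise-difference Gaussian: conditionally,

$$v_{ik} \mid v_{-ik} \sim
  N\!\left(\frac{1}{|\partial_i|}\sum_{j \in \partial_i} v_{jk},\;
  \frac{\sigma_{vk}^2}{|\partial_i|}\right),$$

with $\partial_i$ the neighbour set of unit $i$ at level $k$.

- **Independent model**: the two levels are fitted with no common
  parameters — two separate convolution models.
- **Shared model**: the coarse-level CH term also enters every nested
  fine unit's predictor, $\mathrm{logit}(p_{i1}) = \beta_{01} + \beta_{11}
  x_{i1} + v_{i1} + \varepsilon_{i1} + v_{\mathrm{parent}(i),2}$, with
  coefficient 1. Counties inherit their district's spatially structured
  component, linking the scales and letting the fine level recover
  information smoothed away by aggregation. A scaling coefficient on the
  inherited term is a conceivable generalization; the minimal model with
  coefficient 1 is implemented because nothing in the two-level structure
  identifies an extra free scale separately from $\sigma_{v2}$.

Priors: flat on intercepts; $N(0, 1000^2)$ on slopes (a vague proper
normal, the conventional WinBUGS-style choice — the exact variance of a
"non-informative normal" is a free choice and results are insensitive to
it at these data sizes); $\sigma \sim U(0, 100)$ on all four standard
deviations.

### Identifiability and numerical conventions

- **Rank correction.** The ICAR density is improper; its log density is
  implemented as $-\tfrac{1}{2\sigma_v^2}\sum_{i<j,\,j\in\partial_i}(v_i -
  v_j)^2 - (N - c)\log\sigma_v$ with $c$ the number of connected
  components of size $\ge 2$.
- **Islands.** Units with no neighbours get a proper $N(0, \sigma_v^2)$
  prior (equivalently: excluded from the pairwise sum and tied to zero),
  so general maps never crash the sampler. Maps produced by the package's
  generators have no islands.
- **Sum-to-zero centring.** With a flat intercept the ICAR field's level
  is unidentified, so after every sweep each $v_k$ is shifted to mean zero
  and the shift absorbed into the intercept(s) — a posterior-invariant
  move because the improper ICAR density is translation-invariant. The
  move is skipped at a level whose graph has islands (their proper prior
  is not translation-invariant). $\varepsilon_k$ is *not* centred:
  recentring an iid $N(0,\sigma^2)$ field is not posterior-invariant; its
  mean is identified (weakly) through its own prior, and dedicated
  translation moves (below) keep that direction mixing.
- **Covariate standardization** uses the sample standard deviation
  (denominator $N-1$), recorded per level so that slopes can be
  back-transformed to the raw covariate scale. The covariate is stored in
  the units supplied; reports phrase effects "per $1{,}000" when income is
  supplied in thousands of dollars.

## Inference

`run_mcmc()` is Metropolis-within-Gibbs with a compiled (Rcpp) core. One
sweep updates:

1. each $v_{ik}$ by single-site Metropolis with an independence proposal
   drawn from its ICAR full conditional — prior and proposal cancel, so
   the acceptance ratio is the binomial likelihood ratio alone (under the
   shared model a coarse $v_{i2}$ update also carries its children's
   likelihood terms);
2. each $\varepsilon_{ik}$ by single-site random-walk Metropolis;
3. intercept and slope jointly per level by random-walk Metropolis;
4. each $\sigma$ by random walk on $\log\sigma$ with rejection outside
   the uniform prior support (and the log-scale Jacobian);
5. the recentring move described above.

Proposal scales adapt by Robbins–Monro toward 0.44 (single-site) or 0.234
(blocks) during burn-in only, then freeze; the $v$ proposals have no
tunable scale, so their acceptance is data-determined. On top of the
sweep, three families of *posterior-invariant auxiliary moves* traverse
the ridges that single-site updates cross slowly:

- **translations** $\beta_{0k} \mathrel{+}= \delta,\ \varepsilon_k
  \mathrel{-}= \delta$ and $\beta_{1k} \mathrel{+}= \delta,\
  \varepsilon_k \mathrel{-}= \delta x_k$ (and the analogue against
  $v_k$), which leave the linear predictor unchanged so acceptance is a
  prior ratio;
- **swaps** $v_{ik} \mathrel{+}= t,\ \varepsilon_{ik} \mathrel{-}= t$,
  mixing the CH/UH decomposition;
- **rescalings** $(\sigma, \text{field}) \to (c\sigma, c\,\text{field})$,
  whose prior ratio cancels against the Jacobian up to a single $\log c$,
  mixing each standard deviation jointly with its field's magnitude.

All are standard Metropolis moves with exact acceptance ratios, so the
stationary distribution is unchanged; without them the
intercept/field-mean and $\sigma$/field-magnitude directions dominate the
autocorrelation time. Chains start from $\beta = 0$ jittered with
$N(0,1)$ per chain (over-dispersed starts that make the Gelman–Rubin
diagnostic meaningful), $v = \varepsilon = 0$, $\sigma = 1$. The default
protocol is 3 chains of 30,000 iterations with 15,000 burn-in and no
thinning (45,000 retained draws); all randomness derives from one integer
seed and identical seeds give bit-identical draws. Convergence is judged
by the classical potential scale reduction factor; the conventional
warning threshold 1.1 is used.

## Model assessment

Per level: the deviance is $-2$ times the binomial log likelihood
(including the normalizing constant, common to both models);
$\bar D$ is the posterior mean deviance over retained draws; the plug-in
deviance is evaluated at the posterior mean of the *linear predictor*
($\eta$-scale plug-in — stable for hierarchical logit models, avoiding
nonlinearity artifacts of plugging in individual parameters);
$p_D = \bar D - \hat D$; $\mathrm{DIC} = \bar D + p_D$. A DIC difference
of 3 or more is flagged as an improvement. MSPE draws one posterior
predictive replicate $y^{\mathrm{rep}}_i \sim \mathrm{Bin}(n_i,
p_i^{(s)})$ per retained draw and averages $(y^{\mathrm{rep}}_i - y_i)^2$
over draws and units; it is seeded and reproducible. Negative $p_D$ (a
known DIC pathology) is flagged with a warning rather than an error.
Fine-level deviance under the shared model conditions on the full fine
predictor including the inherited $v_2$ term.

## The synthetic-data generator

Real two-level surveillance data (the package's motivating case is
county-level low-birth-weight counts with median household income) are
not redistributable here, so `simulate_dataset()` generates datasets with
the same structure:

- geography: a rook lattice partitioned into rectangular blocks
  (`make_lattice_geography()`), or a deterministic irregular partition of
  a 159-cell planar graph into 18 contiguous districts
  (`make_georgia_like_geography()`) that reproduces the 159-into-18
  nesting arithmetic of a county/district map — it is *synthetic*: scale
  and nesting match, shape does not;
- covariate: $x_{i1} \sim N(40, 10^2)$ (thousands of dollars, the ballpark
  of county median household incomes), optionally with a smooth west–east
  gradient; the coarse covariate is the within-parent mean, and both
  levels are standardized with records kept;
- fields: $v$ drawn exactly from the ICAR prior restricted to the
  sum-to-zero subspace (eigendecomposition of each component's
  Laplacian), $\varepsilon$ iid normal and *uncentred* — centring is an
  inferential device, not part of the generative process;
- outcomes: $y_{i1} \sim \mathrm{Bin}(n_{i1}, \mathrm{logit}^{-1}
  \eta_{i1})$ with $\eta$ from the chosen model; trials are
  $\mathrm{Pois}(500)$ by default; **coarse outcomes are produced by
  aggregation** ($y_2, n_2$ = within-parent sums), exactly how nested
  administrative data arise — the coarse-level model is therefore an
  approximating model, as it is for real aggregated data.

Default generating parameters are the shared-model conditions of the
motivating analysis: $\beta_{01} = \beta_{02} = -2.2$ (a baseline risk
near 8%), $\beta_{11} = -0.1$, $\beta_{12} = -0.06$, $\sigma_{v1} =
0.06$, $\sigma_{\varepsilon 1} = 0.12$, $\sigma_{v2} = 0.32$,
$\sigma_{\varepsilon 2} = 0.04$: a dominant district-scale spatial field
with modest extra county-level variation. The within-district dispersion
of the covariate is a free knob (`x_sd`), as no published value pins it.

What the generator does *not* emulate: real county adjacency geometry,
heterogeneous county sizes (births per county in real data span orders of
magnitude; the default is a tight Poisson around 500), covariate
measurement error, and any non-binomial overdispersion. Passing recovery
tests therefore demonstrates correctness of the machinery under the
model's own assumptions, not robustness to real-data violations of them.

## The recovery experiment and what it shows

`recovery_experiment()` is the package's acceptance surface: it simulates
under the shared model at desk scale — a 12×12 lattice in 9 blocks of
4×4 (144 fine units, near the 159/18 scale but divisible), ~500 trials
per unit, 3 chains × 3,000 iterations per fit, 20 replicates — fits both
models, and scores interval coverage, convergence, DIC/MSPE preference,
and surface roughness. These problem sizes are the package's chosen
desk-scale defaults; the full 30,000-iteration protocol behaves the same
but slower. Typical results (recomputed by `scripts/acceptance.R`): 95%
interval coverage of $\beta_{11}$ at or above its nominal level, all
$\hat R < 1.1$, and fine-level DIC preferring the shared model in
essentially all replicates.

Two directions deserve honest discussion because they are *not*
reproduced under these generating conditions:

- **Fine-level MSPE.** Posterior-predictive replicate MSPE measured
  against the *observed* outcomes systematically favours the independent
  model by 1–2%. Decomposing MSPE as $\mathbb{E}[n p(1-p)] +
  n^2\mathrm{Var}(p) + (\mathbb{E}[np] - y)^2$ shows the shared model has
  lower parameter variance but a larger fit term: its fine-level field is
  disciplined by the joint fit, while the independent model's
  unconstrained county field interpolates the observed counts more
  closely — and MSPE against observed data does not charge for that
  flexibility, whereas DIC does. The package reports both quantities and
  leaves the comparison to the reader.
- **Surface roughness.** Under these conditions the shared model's
  fine-level risk surface contains the sharp district steps it inherits
  from $v_2$, while the independent model renders district-scale
  structure through a smooth county ICAR field, so the shared surface is
  not reliably the smoother one. Roughness
  $\sum_{i \sim j}(\hat p_i - \hat p_j)^2$ is computed and logged per
  replicate.

## Other design choices

- Coarse adjacency in real-data mode is always read from a file, never
  derived from fine adjacency (district adjacency is treated as given);
  the generators derive it explicitly as "blocks sharing a fine edge",
  and both conventions are supported.
- Unit order is the file order of first appearance and is the canonical
  index order everywhere downstream.
- Asymmetric adjacency input is refused with the offending pairs listed,
  never silently symmetrized.
- The headline odds ratio is the point back-transformation
  $\exp(\bar\beta_1 / \mathrm{sd}_x)$ of the posterior-mean slope,
  matching the conventional reporting arithmetic; the posterior mean and
  interval of the draw-wise transform $\exp(\beta_1/\mathrm{sd}_x)$ are
  reported alongside as the Bayesian-coherent alternative.
- Risk surfaces report the posterior *mean* of $\mathrm{logit}^{-1}\eta$
  (the median is a defensible alternative; the mean is used throughout).
- Rounding conventions: 3 decimals for odds ratios, 2 for posterior
  summaries, 1 for percent changes.

## Limitations

Two scale levels only; binomial outcomes with a logit link only; no
proper-CAR (Leroux/BYM2) variants; no spatio-temporal extension; no
misaligned (non-nested) multiscale structures; no map rendering —
per-unit CSV output is the interface to mapping tools.
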