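---
title: "Immigrant genetic groups and the quantitative genetics of extra-pair paternity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immigrant genetic groups and the quantitative genetics of extra-pair paternity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In socially monogamous birds, some offspring in a brood are sired by males
other than the social mate. The fraction of extra-pair offspring (EPO) in a
brood is an *emergent* binomial trait: it is jointly shaped by the female's
latent liability for extra-pair reproduction and her social male's latent
liability for paternity loss. Island populations that receive occasional
immigrants add a second layer: immigrants import genes whose mean effects may
differ from the local population, shifting means, variances, and the
cross-sex covariance of the genetic values that selection acts on.

`gganimal` implements the full analysis chain for this problem on pedigreed
populations:

1. **Genetic-group pedigree machinery.** Individuals with unknown parents get
   *phantom parents*. Phantom parents of flagged immigrants form the
   immigrant genetic group; all other phantom parents form the founder group.
   The expected fraction of individual $i$'s genome descending from the
   immigrant group, $q_i$, follows the halving recursion
   $q_i = (q_{\mathrm{dam}} + q_{\mathrm{sire}})/2$ with phantom slots
   contributing 1 (immigrant group) or 0 (founder group). The machinery
   generalizes to $k$ groups whose coefficients sum to one; with two groups
   the founder coefficient is simply $1 - q_i$.
2. **A Bayesian cross-sex genetic-groups animal model** for the brood-level
   binomial trait on the latent logit scale.
3. **Draw-wise derived quantities**: variances and covariance of *total
   additive genetic values* $u_i = a_i + g\,q_i$, total variances of the
   joint trait, cross-sex correlations, heritabilities, and phenotypic-scale
   back-transformations.
4. **A synthetic island-population generator** with known truth, so the whole
   chain is validated end-to-end by parameter recovery.

## The model

For brood $k$ with female $f(k)$, social male $m(k)$, year $t(k)$ and male
age $x_k$, the number of extra-pair offspring is

$$y_k \sim \mathrm{Binomial}\!\left(n_k,\ \mathrm{logit}^{-1}(\eta_k)\right),$$

$$\eta_k = \beta_0 + \beta_t (t(k) - t_0) + \beta_x x_k
  + g_f\, q_{f(k)} + g_m\, q_{m(k)}
  + a_{f(k)}^{(f)} + a_{m(k)}^{(m)}
  + p_{f(k)} + p_{m(k)} + c_{k} + y_{t(k)} + e_k,$$

where $(a^{(f)}, a^{(m)})$ are bivariate additive genetic effects with
covariance $\mathbf G \otimes \mathbf A$ ($\mathbf A$ the numerator
relationship matrix from the pruned pedigree), $p$ are permanent individual
effects, $c$ a social-pair effect, $y_t$ a year effect, and $e_k$ a
brood-level residual giving additive latent overdispersion. The group
effects $g_f, g_m$ are fixed regressions on the immigrant group coefficients
of the two pair members: $g$ is the difference in mean breeding value
between the immigrant and founder phantom groups, and breeding values $a$
are deviations from the group means.

Derived quantities are computed **draw-wise** over the retained posterior
(never by applying formulas to posterior means, because the transforms are
nonlinear):

$$\mathrm{Var}(u_f) = \mathrm{Var}(a_f) + g_f^2\,\mathrm{Var}(q), \qquad
  \mathrm{cov}(u_f, u_m) = \mathrm{cov}(a_f, a_m) + g_f\, g_m\,\mathrm{Var}(q),$$

$$\mathrm{Var}(a_T) = \mathrm{Var}(a_f) + 2\,\mathrm{cov}(a_f,a_m) + \mathrm{Var}(a_m),$$

and analogously $\mathrm{Var}(u_T)$ from the $u$-scale quantities. The
identity
$\mathrm{Var}(u_T) - \mathrm{Var}(a_T) = (g_f + g_m)^2 \mathrm{Var}(q) \ge 0$
holds algebraically for every draw and is asserted at run time:
immigration can only increase the total additive genetic variance of the
joint trait, whatever the signs of the group effects. $\mathrm{Var}(q)$ is a
plug-in constant computed across the phenotyped individuals of both sexes
pooled (a per-sex option exists via the `phenotyped` argument of
`compute_q()`, but the pooled default matches the way the derived algebra
treats $q$ as a single covariate).

## Sampling scheme

The sampler is a blocked Gibbs scheme with Polya-Gamma augmentation of the
binomial likelihood: given latent $\omega_k \sim \mathrm{PG}(n_k, \eta_k)$,
all location effects (fixed effects, both sexes' animal effects over the
whole pedigree, permanent, pair, year, and brood-residual effects — several
thousand coefficients) are drawn in **one joint sparse Gaussian update**
using a supernodal Cholesky factorization whose symbolic analysis is reused
across iterations. $\mathbf G$ is then drawn from its conditional
inverse-Wishart using the $\mathbf A^{-1}$-weighted quadratic form of the
animal effects, and each scalar variance from its conditional inverse-gamma.
The PG sampler itself is the Devroye-style alternating-series rejection
sampler (implemented in C++, driven by R's RNG so runs are exactly
reproducible under a seed); it is validated in the test suite against the
analytic PG mean and variance and, through the Gibbs sampler, against
closed-form conjugate posteriors.

A Gaussian-response reduction (`family = "gaussian"`, optionally with blocks
removed via `include_random`) exists purely for validation: with an
identity link and known residual variance the intercept posterior has a
conjugate closed form that the sampler must reproduce.

Numerical safeguards: a non-positive-definite scale in the inverse-Wishart
draw gets a `1e-8` ridge rather than a silent `NaN`; $\omega$ is floored at
`1e-10`; a drift in the sparsity pattern of the joint precision (possible
only if a covariance draw is exactly zero) triggers a fresh symbolic
analysis instead of trusting a stale factor.

## Priors and chain settings

The exact prior specification behind the motivating analyses is not fully
published, so the defaults here are the package's own conventional choices,
all configurable through `default_priors()`:

* fixed effects: independent $N(0, 10^8)$;
* $\mathbf G$: inverse-Wishart with $\nu = 2$ and identity scale;
* scalar variances: inverse-gamma with shape $\nu/2$ and rate $\nu V/2$,
  $\nu = 1$, $V = 1$.

These priors are proper and weakly informative at the latent-logit scale of
the data, but they are not innocuous for variance components whose true
value is far below 1: the prior median of the scalar-variance prior is
about 2.2, so permanent-individual and pair variances simulated at 0.1 are
typically estimated around 0.3–0.6 with wide intervals. The recovery
experiments therefore score coverage on the parameters the data genuinely
inform (the group effects, fixed regressions, the genetic (co)variances and
the residual), and prior-sensitivity runs can be done by passing smaller
inverse-gamma $\nu$ (e.g. `default_priors(nu = 0.002)` approximates the
common near-flat choice).

Chains default to 13,000 iterations, 3,000 burn-in, thinning by 5 (2,000
retained draws). Variance components in latent-scale binomial animal models
mix slowly; `fit_mcmc()` computes the lag-1 autocorrelation of every
retained parameter and **warns** when any exceeds 0.05 — it never silently
accepts an under-thinned chain. `thin_fit()` applies further thinning. The
analysis drivers use 30,000 iterations thinned by 10; fully clearing the
0.05 bar for the genetic variances can require chain lengths in the
hundreds of thousands, which is a documented cost of the conventional
single-site variance updates rather than a correctness issue (posterior
means from replicate seeds agree within Monte-Carlo error; see the
pipeline tests).

## The synthetic island population

`sim_config()` encodes the study conditions the pipeline is validated under,
emulating a multi-decade island study of a songbird with frequent extra-pair
paternity:

* 25 breeding seasons; 10 founder pairs; carrying capacity 25 social pairs;
  annual adult survival 0.5; about one immigrant per year (Poisson), each
  parentless, flagged, entering as a 1-year-old;
* per pair-year, broods truncated-Poisson with mean 2 capped at 3; brood
  sizes uniform on 1–4 (the motivating system reports up to three broods of
  1–4 offspring; the exact distributions are unpublished, so these are
  deliberate, documented placeholders);
* latent-scale truth: intercept $-0.67$, $g_f = -1.17$, $g_m = -1.55$,
  year slope $0.05$, male-age slope $-0.19$, $\mathrm{Var}(a_f) = 1.26$,
  $\mathrm{Var}(a_m) = 0.47$, $\mathrm{cov}(a_f,a_m) = -0.37$, residual
  variance $3.58$; permanent-individual, pair, and year variances are set
  to 0.1 each (reported only as "small" in the motivating study);
* breeding values follow the infinitesimal model: parentless individuals
  draw $N(0, \mathbf G)$ (immigrant group-mean shifts are carried entirely
  by $g\,q$, matching the identifiability convention that $a$ is a
  deviation from the group mean), and offspring draw the parental midpoint
  plus a Mendelian deviation with covariance
  $\tfrac12 \mathbf G (1 - (F_{dam} + F_{sire})/2)$;
* social pairing is random among available adults — no assortment by
  breeding value, mirroring the fitted model's assumptions.

A deliberate feature: the generator couples the pedigree to the phenotypes.
Extra-pair offspring receive a random *other* paired male as genetic sire,
so who appears as a sire depends on the simulated trait values — as it does
in a real genetically-profiled population. This realism means replicate
recovery is slightly harsher than a textbook simulation in which the
pedigree is exogenous: the decoupled check (fresh breeding values and
phenotypes over a fixed pedigree, `simulate_breeding_values()` +
`simulate_phenotypes()`) recovers all parameters cleanly, while coupled
replicates occasionally shift the cross-sex covariance estimate upward.
What passing tests show, therefore, is that the estimator works under the
stated generative conditions; they do not certify the model against
features of real data the generator omits (parentage-assignment error,
nonrandom extra-pair sire choice, survival-trait correlations, assortative
pairing).

At these defaults one dataset contains roughly 1,200 broods produced by
about 320 phenotyped females and 310 phenotyped males; pruning to
phenotyped individuals and their ancestors leaves a pedigree of ~650 with
20 founders plus immigrants, mean pairwise kinship ~0.05, and a mean
immigrant genome fraction among phenotyped birds of ~0.2–0.4 depending on
how many immigrants happened to breed.

## Numerical and design choices

* **A-inverse** is built directly by Henderson's rules with Meuwissen-Luo
  inbreeding coefficients (exact, sparse); the dense tabular A exists only
  as a brute-force oracle (`make_A()`), and the tests require
  $\mathbf A^{-1} \mathbf A = \mathbf I$ to $10^{-8}$ on random pedigrees.
* **Gene dropping** (`gene_drop_q()`) is an independent Monte-Carlo check on
  the deterministic q recursion, not part of the estimation path.
* **Topological order** is computed internally (Kahn's algorithm); input row
  order is never trusted; cycles and sex conflicts are validation errors
  naming the offending individuals.
* **Immigrant status** comes from an explicit flag column; `cutoff_year`
  only filters which immigrants count as "recent" (arrival-date-based group
  definitions cannot be inferred from pedigree shape).
* **Posterior modes** use a Gaussian kernel density with Silverman's
  bandwidth; **HPD intervals** are the shortest window over sorted draws
  (cross-checked against `coda::HPDinterval` in the tests).
* **Heritabilities** divide the focal additive variance by the sum of all
  estimated variance components, without the logit link variance
  $\pi^2/3$; `include_link_variance = TRUE` adds it for users following the
  latent-scale convention that includes it.
* **Back-transformation** to the phenotypic scale integrates over the
  brood-level residual only, by Gauss-Hermite quadrature (30 nodes;
  validated against $10^6$-draw Monte-Carlo integration to $10^{-3}$ across
  $\eta \in [-3,3]$, $\sigma^2 \in [0,5]$). `integrate_over = "all"` also
  marginalizes the genetic, permanent, pair, and year variances; which
  marginalization is "the" population rate is a modelling choice, so the
  default is the minimal one and the report states it.
* **Degenerate inputs**: broods with zero offspring are rejected at
  validation; an individual appearing in both sex roles is an error; broods
  referencing unknown individuals are errors naming the ids.

## Problem sizes used by the checks

The per-commit test suite and the acceptance script validate at reduced
problem sizes chosen to keep a full run in minutes on one CPU: pedigree
oracles on 50 random pedigrees up to 300 individuals with a 100,000-replicate
gene-dropping check; sampler validation on fixtures of tens of observations;
a four-replicate recovery experiment at roughly 300 broods per replicate
with 4,000-iteration chains; and one end-to-end fit of ~500 broods with a
12,000-iteration chain. The full 20-replicate experiment at ~1,200 broods
per replicate with 20,000-iteration chains is `analysis/05_recovery.R`, the
long-running tier. Single study-scale fits (~1,250 broods, pedigree ~630,
30,000 iterations) complete in roughly ten minutes.

## Known limitations

* Two genetic groups (founder, immigrant); no geographic substructure of
  immigrant sources.
* The genetic (co)variances are assumed equal across groups; group-specific
  $\mathbf G$ is out of scope.
* No dominance, maternal, or genomic (marker-based) relatedness components;
  REML/frequentist fitting is not provided.
* The brood-level residual is the chosen overdispersion convention; a
  per-offspring latent residual is a plausible alternative the package does
  not implement.
* Variance-component mixing is slow at the study scale; honest use requires
  attending to the autocorrelation warning rather than suppressing it.
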