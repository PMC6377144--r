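# isoforage

Stable-isotope trophic analysis of an omnivorous crab at mangrove/upland
transition zones — feeding selectivity, δ15N trophic position,
mixing-polygon feasibility, and concentration-dependent Bayesian diet
reconstruction, as one tested R pipeline.

## Who this is for

Trophic ecologists who have (a) multi-choice feeding-trial mass records
with paired consumer-free controls and (b) dual-tracer (δ13C, δ15N)
isotope tables for a consumer and its candidate food sources, and who
want the full analysis chain — selectivity indices, baseline-referenced
trophic position with habitat tests, an a priori polygon feasibility
check, and a Bayesian mixing model — with every estimator unit-tested
against independent oracles. A synthetic-data generator with known truth
makes the whole chain verifiable without field data.

## The statistics at the core

* **Manly–Chesson selectivity for depleting prey**:
  α<sub>i</sub> = ln p<sub>i</sub> / Σ<sub>j</sub> ln p<sub>j</sub>,
  where p<sub>i</sub> is the proportion of prey i remaining (mass for
  counts), after regression-estimated initial dry mass and multiplicative
  autogenic correction from controls. 1/m = random feeding; fully
  consumed prey have an undefined index and are flagged, not fudged.
  Friedman + Nemenyi rank tests across crabs.
* **Trophic position**: TP = λ + (δ15N<sub>consumer</sub> −
  δ15N<sub>baseline</sub>)/Δδ15N with a site-specific detritivorous-snail
  baseline, λ = 2, Δδ15N = +5.2 ± 0.28‰; nested ANOVA (habitat fixed,
  site nested) and per-site Tukey/Welch contrasts.
* **Mixing polygon**: Monte-Carlo convex hulls of TEF-corrected source
  draws; per-consumer inclusion probability; consumers below α = 0.05
  lie outside the 95% mixing region.
* **Mixing model**: X<sub>jt</sub> ~ N(Σ w<sub>kt</sub>(μ<sub>kt</sub> +
  f<sub>t</sub>), Σ w<sub>kt</sub>²(σ<sub>kt</sub>² + σ<sub>ft</sub>²) +
  τ<sub>t</sub>²) with concentration weights w<sub>kt</sub> ∝
  p<sub>k</sub>c<sub>kt</sub>; Dirichlet(1) prior per site simplex,
  half-Cauchy(5) on residual sds; adaptive Metropolis on ILR coordinates;
  split-Rhat and ESS diagnostics. Natural and disturbed populations are
  fitted separately (unequal source menus) and compared on shared
  sources.

See `vignettes/isoforage-methods.Rmd` for assumptions, defaults and
numerical choices.

## Worked example

```r
library(isoforage)

# Selectivity on a worked depletion vector: 5 prey, one depleted to 50%,
# the rest to 90% remaining
manly_alpha(rep(1, 5), consumed = 1 - c(0.9, 0.5, 0.9, 0.9, 0.9))
#> Manly-Chesson selectivity ( 5 prey with defined index)
#>    prey   p consumed   alpha defined
#> 1 prey1 0.9      0.1 0.09453    TRUE
#> 2 prey2 0.5      0.5 0.62189    TRUE
#> 3 prey3 0.9      0.1 0.09453    TRUE
#> 4 prey4 0.9      0.1 0.09453    TRUE
#> 5 prey5 0.9      0.1 0.09453    TRUE
```

The preferred prey takes α = 0.622 against 0.095 for the others
(random feeding would be 0.2 each); defined α sum to 1.

End-to-end on the default synthetic scenario (demo-scale MCMC; expect
Rhat warnings at this chain length — the report surfaces them):

```r
cfg <- analysis_config(
  mcmc    = list(chains = 2, iterations = 2000, burn_in = 1000,
                 thin = 5, seed = 1),
  polygon = list(n_iterations = 300, seed = 1))
manifest <- run_all(cfg, out_dir = "demo_out")
cat(make_report(manifest))
```

Output actually printed by the code above (excerpt):

```
## Feeding selectivity (Manly-Chesson alpha)
- Friedman chi-squared = 144 (df = 4), p = 3.89e-30
- Mean alpha ranking:
  1. Iva (0.478)
  2. Avicennia (0.361)
  3. Grass (0.054)
...
## Trophic position
- treatment: F = 97.32, p = 6.41e-10
- Per-site pairwise tests:
  - S1: natural 2.38 vs disturbed 2.85, p = 0.000209
...
## Mixing-polygon feasibility
- 0 of 30 consumers flagged outside the mixing region
```

Reading it: the generator's preferred leaf wins the selectivity ranking,
trophic position is significantly elevated at disturbed locations at
every site (the scenario's truth is 2.8 vs 2.4), and every consumer is
explicable by its source polygon, licensing the mixing model. Posterior
proportion tables and draws land in `demo_out/*.csv`.

A command-line wrapper mirrors the stages:

```sh
Rscript inst/cli/isoforage simulate --seed 1 --out data_dir
Rscript inst/cli/isoforage run-all  --seed 1 --out results_dir
```

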