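# parawarm

Analysis of how experimental warming and cooling reshape a host–parasitoid
trophic network: parasitoid developmental success, host suppression, host
developmental success, parasitoid diet breadth, and phylogenetic
specialization, from vial-level rearing counts.

The package is written for entomologists and community ecologists running
fully factorial no-choice rearing experiments — every host species crossed
with every parasitoid species at several constant temperatures, with
unparasitized control vials — and for anyone who wants a tested, seeded
re-implementation of this analysis style on their own or simulated data.

## What it computes

With `P` and `H` the parasitoid and host adults emerging from a parasitized
vial and `H_C` the mean host emergence in that cell's control vials
(per-vial adjusted to `max(H_C, H, P)`):

* **parasitism success** `= P / H_C` and **degree of infestation**
  `= 1 − H / H_C`, per vial;
* **Bayesian multilevel binomial models** (JAGS) with
  `logit(p) = β_temp + a_host + b_host,temp + c_par + d_par,temp + g_host`,
  where `g ~ MVN(0, σ_g² C̃)` uses the depth-normalized host-phylogeny
  variance–covariance matrix; temperature contrasts are reported as median
  odds ratios with 95% HPD intervals, and the phylogenetic term is assessed
  against the non-phylogenetic variant by PSIS-LOO;
* **fundamental diet breadth** per parasitoid × temperature as phylogenetic
  Hill diversity of order `q = 1`,
  `D = exp(−Σ_i (L_i/T) a_i ln a_i)` over tree branches, computed over
  seven replicate "diversity sets", with OLS marginal-mean temperature
  contrasts and a replicate-order randomization sensitivity analysis;
* **DSI\*** phylogenetic specialization in `[−1, 1]` — abundance-weighted
  mean pairwise patristic distance of used hosts against a Monte Carlo null
  resampled from host availability (0 = random diet, 1 = monophagy,
  negative = overdispersed).

A seeded synthetic-experiment generator (`simulate_experiment()`) emulates
the 7-host × 4-parasitoid × 3-temperature vial design (50 eggs/vial,
7–10 replicates, controls per cell) with the inference model's own linear
predictor, so every stage is testable end to end without external data.

## Worked example

```r
library(parawarm)

tree   <- example_host_tree()          # synthetic 7-host time tree, depth 47 Myr
design <- experiment_design()          # 7 hosts x 4 parasitoids x 20/24/28 C
vials  <- simulate_experiment(design, true_params(design), tree, seed = 42)

outcomes <- treatment_outcomes(vials)  # per-vial indices + baseline adjustment
larval   <- subset(model_observations(outcomes, "parasitism"),
                   parasitoid != "Trichopria")

fit <- fit_glmm(larval, tree,
                model_spec("parasitism", "larval", include_phylo = TRUE,
                           mcmc = list(chains = 4, warmup = 500,
                                       draws_per_chain = 500)),
                seed = 42)
contrast_odds_ratios(fit)
#>   comparison median_or hpd_low hpd_high significant
#> 1      20/24     1.800   1.672   1.9278        TRUE
#> 2      28/24     0.062   0.048   0.0766        TRUE
```

Warming collapses larval parasitism success in this simulated experiment:
the odds of a potential host yielding a parasitoid at 28 °C are ~16× lower
than at ambient (OR 0.062, HPD excluding 1). The cooling contrast reflects
this dataset's realized species-level variation around the generator's mild
cooling effect — with only seven hosts and three parasitoids, the direction
of small pooled contrasts varies between datasets while the warming
collapse never does.

```r
sets    <- assign_sets(subset(vials, parasitoid != "CONTROL"))
breadth <- fit_breadth_lm(set_diversity(sets, tree, q = 1))
breadth$contrasts
#>    parasitoid comparison estimate    se  p_value
#> 1     Asobara      20/24   0.0150 0.203 9.41e-01
#> 2     Asobara      28/24  -1.9981 0.203 6.26e-15
#> 3    Ganaspis      20/24   0.1341 0.203 5.10e-01
#> 4    Ganaspis      28/24  -1.8586 0.203 1.15e-13
#> 5 Leptopilina      20/24   0.0218 0.203 9.15e-01
#> 6 Leptopilina      28/24  -2.2711 0.203 2.36e-17
#> 7  Trichopria      20/24   0.0115 0.203 9.55e-01
#> 8  Trichopria      28/24  -2.6202 0.211 1.80e-19
```

Every parasitoid loses roughly two effective host species of diet breadth
under warming, while cooling changes nothing — the same asymmetry the
design was built to detect. `dsi_panel(vials, tree)` then scores each
parasitoid's phylogenetic specialization against the hosts actually
available at that temperature.

The whole analysis — simulation or CSV input, metrics, all five Bayesian
models, LOO comparison, breadth, availability, randomization, DSI* — runs
from one seeded configuration via `run_pipeline(run_config(...))`, which
writes tidy CSV outputs plus a checksum manifest, and `render_summary()`
turns a report into the tables behind the usual figures. See the methods
vignette (`vignettes/temperature-parasitism-methods.Rmd`) for the models,
priors, numerical choices and limitations.

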