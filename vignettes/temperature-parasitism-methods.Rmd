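---
title: "Models and methods: temperature effects on host-parasitoid interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: temperature effects on host-parasitoid interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parawarm)
```

# The experiment this package analyses

`parawarm` analyses fully factorial no-choice rearing experiments in which
each of several host species (here, a guild of rainforest drosophilids) is
exposed to each of several parasitoid wasp species at several constant
temperatures. One *vial* holds a fixed number of host eggs (50 by default);
parasitized vials receive adult female parasitoids for a bounded exposure
window, control vials do not. The raw outcome per vial is a pair of counts:
`H` adult hosts and `P` adult parasitoids that eventually emerged. The
scientific questions are (i) how warming and cooling change the success of
parasitoid development and the suppression of hosts, (ii) whether hosts and
parasitoids are differentially affected, (iii) whether warming narrows the
diversity of hosts a parasitoid can use (fundamental diet breadth), and
(iv) whether parasitoid diets are phylogenetically specialized relative to
what is available.

# Per-vial interaction indices

Let `Hc` be the mean adult emergence across the unparasitized control vials
of the same host x temperature cell. The two indices are

* parasitism success `= P / Hc` — the fraction of potential hosts converted
  into parasitoids, and
* degree of infestation `= 1 - H / Hc` — the fraction of potential adult
  hosts that failed to emerge under parasitoid exposure.

Because `Hc` is a control-cell *mean*, an individual vial's `H` or `P` can
exceed it. Per vial we replace `Hc` by `max(Hc, H, P)`, the best available
estimate of how many flies that vial could have produced; this single rule
keeps both indices inside `[0, 1]` without any post-hoc truncation. A vial
with adjusted baseline zero has undefined indices and is excluded with a
logged count (biologically: the interaction is not measurable at that
temperature because nothing emerges even without parasitoids).

For the Bayesian models the binomial trials must be integers while `Hc` is a
mean, so trials are `round(Hc_adj)` (round half up), rounded exactly once at
model entry; the indices themselves are computed from the unrounded value.
The adjustment is applied before rounding. Outcomes are `P` (parasitism
success) and `round(Hc_adj) - H` (degree of infestation).

# The Bayesian multilevel binomial models

Each vial contributes one binomial observation `y_j ~ Binomial(n_j, p_j)`
with

```
logit(p_j) = beta[temp(j)] + a[host(j)] + b[host(j), temp(j)]
             + c[par(j)] + d[par(j), temp(j)] + g[host(j)]
```

Temperature is index-coded (one `beta` per temperature; contrasts are formed
after fitting, so the coding cannot affect results). `a, c` are normal
random intercepts for host and parasitoid; `b, d` are *categorical*
temperature random slopes, allowing every species its own temperature
response; `g` is a host effect correlated by the phylogeny,
`g ~ MVN(0, sd_g^2 * C)` where `C` is the host tree's variance-covariance
matrix divided by tree depth. Normalizing `C` to unit diagonal keeps `sd_g`
on the same scale as the other standard deviations and identifiable from
them. The phylogenetic effect enters once per host species; replication
across vials is carried by the binomial likelihood. Larval parasitoids are
pooled into one model with parasitoid terms; the pupal parasitoid (a single
species) and the host-development model (control vials, trials = eggs) drop
the parasitoid terms.

Priors are pinned, weakly informative, and configurable: `Normal(0, 5)` for
the fixed temperature effects and `half-Student-t(3, 0, 2.5)` for every
standard deviation. These are the conventional defaults for logit-scale
multilevel models; pinning them makes runs reproducible.

## Sampling and diagnostics

Models are sampled with JAGS (Gibbs sampling), with one RNG seed per chain
derived from the run seed, so a fixed seed reproduces a fit bit for bit.
The reporting default is 8 chains x 1250 retained draws after 1000 warmup
iterations (10,000 posterior samples); tests and quick runs scale this down
through `model_spec(mcmc = ...)`.

With categorical random slopes, the raw `beta[t]` are additively confounded
with the slope means `mean(b[, t])` and `mean(d[, t])`: only their sum is
identified by data, and a Gibbs sampler moves along the confounded direction
slowly. The package therefore:

* reports all temperature contrasts on the *level-averaged margin*
  `beta[t] + mean_s(b[s, t]) + mean_k(d[k, t])` — the estimated-marginal-mean
  on the link scale, which is the identified functional and mixes rapidly
  (measured split R-hat ~1.00 where the raw `beta` reach R-hat ~3);
* polices convergence on these margins (flag at R-hat > 1.05, strict mode
  errors), and reports the variance hyperparameters' R-hat separately.
  `sd_g` and `sd_c` (7 host and 3 parasitoid levels) have heavy-tailed,
  slowly mixing posteriors; their point summaries are still usable but
  should be read together with the effective sample size.

An alternative marginalization that conditions all random effects at zero is
available (`contrast_odds_ratios(marginal = "zero")`); the two differ only
by realized slope-mean differences and coincide as the number of levels
grows. There is no divergent-transition diagnostic under Gibbs; R-hat and
ESS carry that role here.

## Contrasts and model comparison

Per posterior draw, the odds ratio of temperature `t` versus ambient is
`exp(margin_t - margin_ambient)`; we report `exp(median log-OR)` (so that
swapping the baseline inverts the OR exactly) with a 95% highest posterior
density interval, and call a contrast significant when the interval excludes
1. Per-species contrasts add the species' own random slopes before
exponentiating.

Phylogenetic dependence is assessed by refitting without `g` and comparing
expected log pointwise predictive density via PSIS-LOO (Pareto-smoothed
importance sampling, implemented in the package: Zhang-Stephens profile
likelihood fit of a generalized Pareto to the importance-ratio tail, with
the usual shrinkage of the tail-shape estimate). Points with tail shape
k > 0.7 are flagged; models are "not significantly different" when
`|elpd difference| < 2 SE`.

# Diet breadth as phylogenetic Hill diversity

Replicate vials are bundled into *diversity sets*: set `k` contains
replicate `k` of every host for a given parasitoid x temperature (the
chronological order in which replicates were prepared; 7 sets by default,
surplus replicates unused). Within a set, the abundance of each host is the
number of parasitoid adults reared from it, and diet breadth is the
phylogenetic Hill number of order `q = 1`:

```
D = exp( - sum_i (L_i / T) a_i log a_i )
```

summing over tree branches `i` with length `L_i` and descendant relative
abundance `a_i > 0`, where `T = sum_i L_i a_i` is the abundance-weighted
mean root-to-tip depth (equal to tree depth on an ultrametric tree). This
"effective species" form reduces *exactly* to the ordinary Hill number on a
star phylogeny, which is the package's relatedness-free variant
(`star_tree()`). Counts of individuals are the abundance unit; sets with no
reared parasitoids have undefined breadth and are excluded from modelling
with a logged count (diet breadth is unmeasurable where a parasitoid barely
survives).

Per-set breadth is modelled by OLS with temperature, parasitoid and their
interaction; marginal means and ambient-vs-cooling / ambient-vs-warming
contrasts come from `emmeans` with raw (unadjusted) p-values. On a balanced
table the marginal means equal raw cell means. Available host diversity is
the same computation on control-vial survivor counts, grouped into the same
set structure, modelled with temperature only.

Because the chronological set assignment is arbitrary, a sensitivity
analysis reshuffles the replicate order within every cell (1000 shuffles in
a full run) and reports how often the shuffled contrasts agree with the
chronological ones in sign and significance.

# DSI*: phylogenetic specialization relative to availability

For each parasitoid x temperature, the observed statistic is the
abundance-weighted mean pairwise patristic distance (MPD) among used hosts.
The null resamples the same number of interaction records from host
availability (control survivor counts at that temperature), `n_null = 999`
times by default. The index rescales `null_mean - observed`:

* positive side divided by `null_mean - mpd_min`, with `mpd_min = 0` (a
  single-host diet), so a monophagous diet scores exactly 1;
* negative side divided by `mpd_max - null_mean`, with `mpd_max` the largest
  patristic distance among available hosts — an abundance-weighted MPD is a
  convex combination of pairwise distances, so this bound is attained by an
  even two-host diet at maximal distance.

Zero means the diet is random with respect to availability. Cells with
fewer than two records, or availability concentrated on fewer than two
hosts, are reported as undefined with a reason code, never imputed as zero
(zero is a substantive claim). Fixing the seed fixes the null exactly.

A known limitation: for very small diets (tens of records) the asymmetric
rescaling gives the index a small negative finite-sample bias (about -0.06
at 30 records under a random diet in our checks); it shrinks roughly with
the square root of the record count and is negligible for the cell sizes at
which the index is meaningfully estimable.

# The synthetic experiment generator

Downstream stages are exercised end to end by a seeded generator that
emulates the design: 7 hosts x 4 parasitoids (three larval, one pupal) x
temperatures 20/24/28 °C, 50 eggs per vial, 10 replicate vials per
parasitized cell, 7 controls per host x temperature. Control vials draw
`H ~ Binomial(eggs, survival)`. In parasitized vials the number of
surviving larvae is binomial, and each survivor independently yields a
parasitoid with probability `pi` — whose logit is assembled from *exactly*
the inference model's linear predictor, making parameter recovery
well-posed — or, failing that, escapes as an adult host with conditional
probability `eta` or dies. This three-outcome attack model guarantees
`H + P <= eggs` for every parameter value; an absolute escape probability
would instead create an infeasible region (`pi + eta > 1`) reachable by
tail draws of the random effects, which is why the conditional form is
used.

Default effect sizes reproduce the magnitudes this experimental system is
known for: strong loss of parasitoid success under warming (log odds ratio
`log(0.037)` against ambient), mild loss under cooling (`log(0.828)`);
ambient parasitism logit -0.5 and ambient egg-to-adult survival 0.75 are
realistic for drosophilid rearing at benign temperatures; host survival
shifts by `log(0.928)` under cooling and, under warming, by host-specific
amounts spread from 0 down to `2 log(0.198)` (mean `log(0.198)`) — hosts
respond heterogeneously to warming, some crashing and some barely affected,
which is also what makes *available* host diversity itself decline with
warming. Random-effect scales default to 0.5 (intercepts), 0.3 (temperature
slopes) and 0.5 (phylogenetic), giving visible but not overwhelming
species-level variation. Randomness is seeded per vial by a counter-derived
stream, so extending a design never perturbs existing cells.

What the generator does *not* emulate: overdispersion beyond the binomial,
development-time phenology, multiparasitism and competition, encapsulation
physiology, body mass, or drift in egg viability across replicates. Passing
tests therefore demonstrate the correctness and calibration of the analysis
machinery under the assumed data-generating structure, not the biological
conclusions themselves on real data.

# Numerical choices and degenerate inputs

* Ultrametricity tolerance: relative `1e-6` on root-to-tip depth (published
  time trees carry rounding error). Polytomies are accepted.
* Tip labels match data tables by exact string after whitespace trimming; a
  mismatch is a hard error, never a silent drop.
* The example seven-host tree (`example_host_tree()`) is synthetic, with a
  47-Myr deepest split matching the depth scale of the drosophilid host
  clade; it is not an estimate for any real species.
* `round half up` for binomial trials (base R's `round()` is banker's
  rounding).
* A diversity table with zero residual variance (e.g. all values equal)
  yields contrast p-value 1 for zero contrasts rather than NaN.
* Hill diversity of an all-zero abundance vector, DSI* of a sub-2-record
  diet, and a missing control cell are explicit, labelled failures - never
  silently imputed values.

# Problem sizes

The test suite exercises the stages at sizes chosen to keep a full run on a
single CPU within a coffee break: simulation designs of 7 hosts x 3-4
parasitoids x 3 temperatures with 4-10 replicates; MCMC at 2-4 chains x
400-500 retained draws for recovery and cross-validation checks (5-10
seeds); 200 replicate-order shuffles; 200 simulated diets for the DSI* null
check. The acceptance script runs the full default design with the
reporting MCMC budget (8 x 1250). These sizes are the package's own choice
of desk-scale defaults; all of them are configuration, not constants.
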