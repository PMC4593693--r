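---
title: "Estimating edge-weight uncertainty in animal social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating edge-weight uncertainty in animal social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcred)
```

## The problem

Animal social networks are usually built from repeated binary observations
of dyads: in each sampling unit (an observation period, or an observed
group such as a foraging flock) a pair of individuals is recorded together
(1) or apart (0). The estimand for each dyad is its association rate
$\theta_{ij}$ — the probability of being together in a sampling unit — and
field datasets are often small enough that the uncertainty around
$\hat\theta_{ij}$ matters as much as the estimate itself. The standard
point estimate is the simple ratio index (SRI), $d/s$, where $d$ counts the
units with the dyad together and $s$ the units in which the dyad was
sampled at all. netcred provides a Bayesian treatment of $\theta_{ij}$
alongside two frequentist comparators, propagates edge uncertainty to node
metrics, and includes the simulation machinery needed to check whether the
reported intervals mean what they claim.

## The Bayesian edge model

Each observation of a dyad is Bernoulli($\theta$), so $d \mid s, \theta
\sim \mathrm{Binomial}(s, \theta)$. With a conjugate
$\mathrm{Beta}(a, b)$ prior the posterior is available in closed form,

$$ \theta \mid d, s \;\sim\; \mathrm{Beta}(a + d,\; b + s - d), $$

and updating is exact, order-independent, and cheap
(`posterior_update()`). The reported point estimate is the posterior mode
— the most probable edge weight — with documented boundary conventions: 0
when only $\alpha \le 1$, 1 when only $\beta \le 1$, and the posterior
mean when both shapes are at most 1 (no interior peak exists; a warning is
emitted). Uncertainty is summarised by the equal-tailed credible interval,
the central region holding `level` (default 95%) of the posterior mass,
computed from beta quantiles (`credible_interval()`).

Equal-tailed rather than highest-posterior-density intervals are a
deliberate choice: they are deterministic, invariant to quantile-solver
details, cheap for thousands of dyads, and conservative relative to HPD
for skewed betas. The interval type is recorded in the output metadata so
downstream consumers know which convention they are reading.

### The empirical-Bayes prior

The prior should describe the distribution of edge weights across the
network. Lacking prior studies, `fit_empirical_prior()` estimates
$(a, b)$ from all observed dyads by type-II maximum likelihood: the
unknown $\theta$ of each dyad is integrated out, giving the beta-binomial
marginal, and (dropping binomial coefficients, which are constant in the
parameters)

$$ (\hat a, \hat b) \;=\; \arg\max_{a,b} \sum_{\text{dyads},\, s>0}
   \Big[ \ln B(a + d,\, b + s - d) - \ln B(a, b) \Big]. $$

Numerically the search runs over $(\ln a, \ln b)$ with a Nelder–Mead
simplex from a method-of-moments start, convergence tolerance $10^{-8}$ on
the objective, and box bounds $a, b \in [10^{-3}, 10^{3}]$. Two degenerate
regimes clamp to the bounds with a warning: data with no overdispersion
(all proportions equal) drive the fit along a ridge toward infinite
concentration, and all-zero or all-one data are attracted to the lower
boundary. Dyads with $s = 0$ carry no likelihood and are excluded from the
fit; they keep the bare prior and an `unsampled` flag.

Using all the data to set the prior is not strictly Bayesian — it is the
usual empirical-Bayes approximation to a hierarchical model. For users who
prefer a clean separation, `holdout_split()` partitions the sampling units
so the prior can be fitted on one subset and the posterior updated with
the remainder; this costs data and is off by default.

## Frequentist comparators

**Bootstrap SRI (b-SRI).** `bootstrap_networks()` resamples whole sampling
units with replacement to the original size and recomputes the entire SRI
network per resample (default 100 replicates); `bootstrap_edge_interval()`
then takes percentile intervals (2.5%/97.5% by default, linear
interpolation between order statistics — `stats::quantile()` type 7, noted
in the metadata since with 100 replicates the interpolation rule can move
an endpoint by one order statistic). Whole units are resampled — never
individual dyad observations — so each network snapshot stays intact. The
bootstrap's known failure mode is built in by construction: with one
sampling unit every resample is identical and every interval has width
exactly zero.

**Clopper–Pearson.** `clopper_pearson_interval()` gives the exact
small-sample binomial interval via inverted tail probabilities, in beta
form $[\,q_{\alpha/2}(d, s-d+1),\; q_{1-\alpha/2}(d+1, s-d)\,]$ with the
closed-form endpoints 0 at $d=0$ and 1 at $d=s$. It is exact but
conservative: realised coverage is at least nominal, so its
false-negative rate sits well below 2.5%.

## Node-level uncertainty

Replicate networks — posterior draws (`draw_posterior_networks()`) or
bootstrap resamples (`as_replicate_networks()`) — are pushed through
weighted node metrics and summarised per node by percentile intervals
(`metric_uncertainty()`, default 100 replicates). The metrics are strength
(`weighted_degree()`), eigenvector centrality (leading eigenvector,
rescaled to max 1), and weighted betweenness. Betweenness needs a
weight-to-distance transform, which the metric's usual definition leaves
open for association networks; we use edge length $1/w$ so that strong
associations make short paths, drop zero-weight edges, split tied shortest
paths fractionally, and report raw (unnormalised) pair counts — only rank
orderings are ever compared, and normalisation cancels. Eigenvector
centrality on a disconnected network (possible for bootstrap replicates)
is computed on the largest component with zeros elsewhere and a
diagnostic warning; posterior-draw networks are almost surely complete, so
this path is rarely taken there.

## The synthetic generator

`generate_true_network()` builds ground-truth networks with two features
of real association data: individual variation in sociality and community
structure. Each individual's gregariousness score is
$\mathrm{Poisson}(\lambda = 3) + 0.05$ (the offset prevents isolates),
normalised by the network maximum; individuals are assigned uniformly at
random to one of 5 cliques (empty cliques are allowed — assignment is
genuinely independent); and the true weight of a dyad is the product of
the two gregariousness scores times 0.9 (same clique), 0.1 (different
cliques), or 0.5 when clique structure is disabled.
`sample_observations()` draws each dyad independently as
Bernoulli(weight) in each of $S$ periods. RNG order is fixed and
documented (nodes, then dyads in row-major $i<j$ order, then periods), so
seeds are portable.

What the generator does *not* emulate matters for interpreting green
tests: there are no observation errors or identity mistakes, no
observability bias between individuals, no temporal autocorrelation or
spatially driven co-occurrence, and every dyad is sampled in every period
($s = S$). Partial sampling enters only through group-by-individual
input, where $s$ varies by construction. Calibration results on this
generator therefore speak to estimator behaviour under clean sampling,
not to robustness against detection error.

One property of the generator deserves emphasis: the true edge weights —
products of normalised Poisson scores times a two-valued block probability
— are **not** beta distributed, and bimodally so with cliques. The fitted
beta prior is thus deliberately misspecified relative to the truth, as it
would be in the field. The package's own calibration study shows the
consequence: false-negative rates land near the nominal 2.5% while
false-positive rates fall below it (the fitted $a < 1$ pushes lower
quantiles of never-together dyads toward 0, so the truth is rarely below
the interval). Under a prior-matched simulation — truth actually drawn
from a beta — the same code attains nominal coverage to Monte-Carlo
precision, which is how we separate "model misspecification, behaving
conservatively" from "implementation error".

## Evaluation framework

`run_simulation_study()` wires the loop together: generate truth, sample
$S$ periods, estimate with each method, and score (i) mean absolute edge
error over dyads, (ii) Spearman rank correlation with average ranks for
ties (constant vectors have no ordering; the correlation is returned as
`NA` with a warning), and (iii) interval reliability, where a false
positive is a true weight strictly below the interval and a false negative
strictly above — each should be ~2.5% for calibrated 95% intervals.
Edge-level rates are pooled over the dyads of a replicate and then
averaged across replicates; `summarize_study()` reports medians with 2.5
and 97.5 percentiles across replicates. Node-level (degree) scoring runs
for the Bayesian and bootstrap methods only — Clopper–Pearson yields no
replicate-network ensemble.

`subsample_stability()` addresses the practical question — "have I
sampled enough?" — without access to the truth: re-estimate the network
from the first $S$ sampling units for increasing $S$ (cumulative prefix by
default, matching data that accumulate in observation order; seeded random
subsets without replacement are the alternative), and watch each dyad's
interval funnel and the mean weighted degree settle. The Bayesian curve
starts at an $S=0$ point carrying the bare fitted prior, so the funnel
begins from the full prior interval. The fitted prior is held fixed across
grid points (it summarises the complete dataset; refitting per prefix
would conflate prior drift with posterior narrowing).
`is_stabilized()` flags whether the last two grid points overlap in
interval and differ by less than 5% in point estimate — a labelled
reporting heuristic, not a test.

## Problem sizes and tolerances

Default study dimensions follow the calibration design: 100 replicate
networks (50 in the routine test suite), $N = 15$ nodes with cliques, 100
bootstrap/posterior replicates per ensemble, $S$ grids around 10–50.
Large-sample checks in the tests use $S = 10^5$ with 3-binomial-SE
tolerances, and Monte-Carlo assertions state their own standard-error
bands. Quantile computations delegate to `stats::qbeta`, verified in the
suite against bisection on the regularised incomplete beta to $10^{-8}$.

## Known limitations

* Edges are updated independently; triadic dependence in who-associates-
  with-whom is ignored by the Bayesian model (the bootstrap partially
  retains it because whole units are resampled).
* No observation-error or detectability model: a single sighting together
  sets the posterior mass at $\theta = 0$ to zero.
* Empirical-Bayes intervals are only as calibrated as the beta family's
  fit to the real edge-weight distribution; expect conservative
  false-positive rates when many dyads truly never associate.
* Node-level intervals (degree and beyond) inherit edge-level
  approximations and are not guaranteed nominal; treat them as honest
  summaries of the replicate ensemble rather than exact confidence sets.
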