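---
title: "Estimating and comparing binary symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing binary symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingnet)
```

## The model

isingnet analyses cohorts of binary (present/absent) diagnostic criteria —
here the nine DSM-5 depressive symptoms — as *symptom networks*: nodes are
symptoms and edges are conditional dependence relations between pairs of
symptoms controlling for all the others. For binary data the natural
probabilistic model is the Ising model, a pairwise Markov random field

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} w_{ij} x_i x_j\Big),
  \qquad x \in \{0,1\}^p,$$

with node thresholds $\tau_i$ (log-odds of endorsement when everything else
is absent) and symmetric edge weights $w_{ij}$ (pairwise interactions on the
log-odds scale). We use the $\{0,1\}$ coding throughout, not $\{-1,+1\}$,
because it matches the logistic-regression parameterization of the
estimator: the simulator, the estimator and the conditional distributions
then share one scale.

## Estimation: eLASSO

The network is estimated nodewise. Each symptom is regressed on all the
others by L1-penalized logistic regression over a path of 100 log-spaced
penalties running from the nodewise maximal penalty (the smallest value with
an all-zero solution) down to 0.01 times it. The penalty is chosen per node
by minimizing the extended BIC

$$\mathrm{EBIC}(\lambda) = -2\,\ell(\hat\beta_\lambda)
   + k\,\log n + 2\gamma k \log(p-1),$$

where $k$ counts nonzero coefficients and $\gamma$ (default 0.25, the
established eLASSO default) controls the extra sparsity pressure. EBIC ties
are broken toward the sparser model, and at equal size toward the heavier
penalty. The two directed coefficients of a pair are merged by the AND rule
by default (an edge exists only if both regressions keep it; its weight is
the average), with the OR rule available.

Two numerical points deserve mention, since the permutation and bootstrap
procedures below refit the whole network tens of thousands of times:

* All computations run on *collapsed* data: with $p$ binary variables there
  are at most $2^p$ distinct response patterns, so the likelihood can be
  computed exactly from pattern counts. A permutation of group labels only
  redistributes counts between two vectors.
* The penalized path is solved by IRLS with Gram-matrix bookkeeping and an
  active-set Newton inner step (exact solutions of tiny linear systems), to
  coefficient tolerance $10^{-5}$ by default — well below the statistical
  noise of any weight at these sample sizes. Coefficients within an order
  of magnitude of the tolerance are reported as exact zeros, which keeps
  the selected model size a stable function of the data (at the top of the
  path a coordinate sits exactly on the soft-threshold boundary, where
  summation-order noise would otherwise decide whether it counts).
  The path stops early once a
  node's fit approaches its saturated likelihood or a coefficient passes 30
  in absolute value: beyond that point the problem is (quasi-)separated,
  the MLE drifts toward infinite log-odds, and no information criterion
  selects such models. The solver is validated against glmnet in the test
  suite, which is the independent reference for the same penalized path.

Symptoms endorsed by (almost) everyone are a real feature of diagnosed
cohorts — sadness approaches universal endorsement among depressed women —
so zero-variance nodes are retained in the network without edges (with a
warning) rather than dropped.

The Pearson correlation matrix (equal to the phi coefficient for binary
data) is computed alongside as a descriptive output; it is *not* the
network. The Fruchterman–Reingold layout (via igraph, attraction
proportional to $|w_{ij}|$, deterministic given a seed) provides plotting
coordinates.

## Centrality and small-world structure

Four standard local metrics are computed per node, raw and z-standardized
across nodes (sample SD, for bit-reproducibility): Strength
$\sum_j |w_{ij}|$; Expected Influence $\sum_j w_{ij}$; Closeness, the
inverse mean geodesic distance with edge length $1/|w_{ij}|$ (the qgraph
convention); and Betweenness, fractional geodesic counts at the same edge
lengths. On disconnected networks — regularized networks do disconnect —
closeness is computed within the node's component and scaled by
(reachable $-$ 1)/($p-1$); isolated nodes get closeness 0.

The global small-world index compares the binarized network's clustering
coefficient $C$ and mean shortest path length $L$ with the averages over
1000 Erdős–Rényi $G(n,m)$ graphs with matched node and edge counts:
$\sigma = (C/\langle C_r\rangle)\,/\,(L/\langle L_r\rangle)$, with the
usual reading that $\sigma > 1$ indicates a small world. The reference
model is a deliberate choice: the source analysis does not name its
reference ensemble, and matched-$G(n,m)$ is the simplest defensible one.
On a 9-node network single-graph $\sigma$ values are noisy (roughly
$\pm 0.2$); the acceptance checks therefore test the *mean* of $\sigma$
over matched random graphs, which is close to 1 by construction.

## Stability: the case-dropping bootstrap

For each drop proportion $q$ in $\{0.05, 0.10, \dots, 0.75\}$ (the
conventional grid, capped at 0.75) and each of `n_boot` replicates, a
subsample of $\lceil n(1-q)\rceil$ participants is drawn without
replacement, the network refit, and the Pearson correlation between
subsample and full-sample centralities recorded — on raw values, because
z-scoring inside a replicate removes scale information. The CS-coefficient
of a metric is the largest $q$ at which at least 95% of replicates reach
correlation 0.70. Metrics that are constant on the full sample (an empty
network, or all-zero betweenness) have no defined correlation; the
bootstrap refuses them, and the pipeline skips them with a warning.

## Comparison: permutation test of network invariance

Two groups' networks are compared with the permutation network-comparison
test. With networks fit per group under identical estimator settings,

$$M = \max_{i<j} |w^{(a)}_{ij} - w^{(b)}_{ij}|, \qquad
  S = \Big|\sum_{i<j}|w^{(a)}_{ij}| - \sum_{i<j}|w^{(b)}_{ij}|\Big|,$$

are the structure-invariance and global-strength-invariance statistics. The
null distribution reassigns pooled participants to groups (preserving group
sizes) and refits; p-values use the add-one correction
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$, so they are never
exactly zero. Internally the permutation redistributes pattern counts over
the sorted pooled state table and always draws the smaller group, which
makes the test exactly symmetric in its two arguments, including the
p-values. Per-edge permutation p-values are available but off by default;
only the global tests are headline outputs. A centrality-invariance test is
deliberately not provided.

## Severity-adjusted frequency comparison

Raw endorsement frequencies confound group differences with overall
severity, so each symptom is compared between groups by multiple logistic
regression of symptom presence on a group indicator plus the participant's
total symptom count, reported as an odds ratio with 95% Wald interval and
two-sided Wald p-value (no multiplicity correction; one OR per symptom).
By default the count covariate *excludes* the modeled symptom — including
it builds a deterministic component into the regressor — but both variants
are exposed. Under separation (a symptom absent in one group) the fit
falls back to Firth's bias-reduced penalized likelihood, implemented
in-package, with a warning.

## The synthetic cohort generator

The restricted cohort behind the motivating analysis cannot be shipped, so
the package carries a generator that samples *exactly* from small Ising
models: for $p \le 20$ the state distribution is enumerated (log-sum-exp
normalized) and rows are drawn from it; conditioning on the DSM-5
diagnostic event — at least five symptoms including sadness or anhedonia —
restricts and renormalizes the enumerated distribution rather than
rejecting samples. Beyond the enumeration guard a Gibbs sampler (burn-in
1000, thinning 10 by default) takes over; for small $p$ the two samplers
are cross-checked by goodness-of-fit in the test suite.

Two bundled 9-symptom parameter sets (`example_parameters("mde")`,
`"ppd"`) give the demo cohorts their shape. They are *synthetic*: a sparse
signed edge structure mirroring the qualitative pattern reported for the
two clinical groups (e.g. a strong negative sadness–anhedonia edge and a
suicidal-ideation hub in the postpartum-like network), with thresholds
calibrated by fixed-point iteration on exact enumeration so that the
*DSM-conditioned* marginals match the reported qualitative ordering —
fatigue/sadness/anhedonia most frequent, in the 0.83–0.99 range. The
conditioned scale was chosen because published frequencies describe
diagnosed patients; the raw (unconditioned) mode remains available. These
fixtures make demo output qualitatively comparable to a real two-group
analysis without claiming any published number.

What the generator does not emulate: item-level measurement error,
longitudinal dependence, covariate structure (age, parity, history), or
missing data. Passing tests therefore demonstrate correctness of the
*methods* under a known sparse Ising truth at realistic sizes, not that
real depression cohorts satisfy an Ising model.

One property of diagnostic conditioning deserves emphasis: restricting a
cohort to qualifying profiles (at least five symptoms, one cardinal) is a
non-product truncation, so the conditioned data are no longer Ising
distributed, and selection-induced dependence can mask a planted pairwise
difference between two groups. In our experiments a single edge differing
by 1.5 between two otherwise identical conditioned generators was detected
far less often than the same contrast between unconditioned generators at
the same sample sizes. The power study in the validation suite therefore
uses unconditioned cohorts; the calibration study, which only needs
exchangeability, runs on the conditioned study-like cohorts.

## Study sizes used in the checks

The validation suite exercises the pipeline at the cohort scale of the
motivating study (two groups of 871 and 486 under the diagnostic
constraint) for the end-to-end determinism and reporting runs, and at
n = 500–8000 per group for the frequentist checks: sampler exactness
(chi-square against enumeration at n = 100,000 across 20 seeds), edge
recovery and RMSE decay over n ∈ {500, 2000, 8000}, permutation-test
calibration (200 simulations of 200 permutations) and power (100
simulations of 80 permutations, one edge differing by 1.5),
CS-coefficient growth over n ∈ {300, 1000, 5000} with the 250-replicate
fast bootstrap, and coverage of the adjusted odds ratios (100
simulations). Permutation counts inside the simulation studies (80–200)
trade Monte-Carlo resolution for running hundreds of full refit loops —
granularity 1/81 is ample for a 0.05-level decision; single analyses
default to 1000 permutations.

## Worked example

```{r example, eval = FALSE}
cohort <- demo_cohort(seed = 11)
net <- fit_ising(cohort$MDE)
net
centrality_table(net)
small_world(net, seed = 1)
nct(cohort$MDE, cohort$PPD, n_perm = 1000, seed = 1)
```

## Known limitations

* Edge weights are penalized estimates: shrunk toward zero, so recovered
  weights are biased low even when the support is exact.
* The small-world index on 9 nodes is noisy; its value should be read
  qualitatively.
* The CS-coefficient is reported on the grid only; 0 means "below 0.05",
  not "zero stability".
* No latent-variable modeling, bridge centrality, node predictability,
  directed networks, or missing-data handling.
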