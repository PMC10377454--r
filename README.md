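# isingnet

Symptom-network analysis for binary diagnostic criteria: regularized Ising
network estimation, centrality and small-world inference, bootstrap
stability, and permutation-based comparison of two groups' networks — the
workflow used to contrast depressive-symptom networks between clinical
groups such as women with postpartum depression (PPD) and women with a
non-perinatal major depressive episode (MDE).

## Who this is for

Researchers with participants × symptoms matrices of 0/1 indicators (e.g.
the nine DSM-5 MDE criteria) and a two-group question: do the groups differ
in how often each symptom occurs once severity is controlled, and do they
differ in how symptoms hang together?

## What it computes

* **Ising network (eLASSO).** Each symptom is regressed on all others by
  L1-penalized logistic regression over a 100-value penalty path; the
  penalty is selected per node by extended BIC,
  `EBIC = -2 loglik + k log n + 2 γ k log(p-1)` (γ = 0.25 by default), and
  directed coefficient pairs are merged by the AND rule into a symmetric
  signed weight matrix with node thresholds. Pearson (phi) correlations and
  Fruchterman–Reingold coordinates come along as descriptive outputs.
* **Centrality.** Strength `Σ|w|`, Expected Influence `Σw`, Closeness and
  Betweenness on edge lengths `1/|w|`, raw and z-standardized.
* **Small-world index.** `σ = (C/C_rand)/(L/L_rand)` against
  edge-count-matched Erdős–Rényi graphs; σ > 1 reads "small world".
* **Stability.** Case-dropping bootstrap and the CS-coefficient: the
  largest fraction of participants droppable while subsample centralities
  correlate ≥ 0.70 with the full sample in ≥ 95% of replicates.
* **Group comparison (NCT).** Permutation test of network structure
  invariance `M = max |w_a - w_b|` and global strength invariance
  `S = |Σ|w_a| - Σ|w_b||`.
* **Adjusted frequencies.** Per-symptom logistic regression of presence on
  group + total symptom count, reported as odds ratios with 95% Wald CIs
  (Firth fallback under separation).
* **Synthetic cohorts.** Exact (enumeration-based) and Gibbs samplers for
  small Ising models, with optional conditioning on the DSM-5 rule
  (≥ 5 symptoms, at least one of sadness/anhedonia), plus two bundled
  synthetic 9-symptom parameter sets so the whole pipeline runs without any
  restricted data.

## Worked example

```r
library(isingnet)

cohort <- demo_cohort(seed = 11)        # synthetic MDE-like and PPD-like groups
net <- fit_ising(cohort$PPD)
net
#> Regularized Ising network: 9 nodes, 7 edges (gamma = 0.25, AND rule, n = 486)
#>   strongest edges: fatigue--suicidal_ideations -2.90; concentration--suicidal_ideations 1.53; sleep--suicidal_ideations 1.26

r <- nct(cohort$MDE, cohort$PPD, n_perm = 1000, seed = 1)
r
#> Network comparison test (1000 permutations)
#>   structure invariance  M = 2.900, p = 0.001
#>   global strength       S = 2.911, p = 0.128  (5.05 vs 7.96)
```

The fitted network recovers the planted structure of the synthetic
PPD-like generator, a suicidal-ideations hub with strong sleep,
concentration and (negative) fatigue connections. `M` is the largest
absolute edge-weight difference between the two groups' networks and `S`
the difference of their summed absolute edge weights; here the structure
test rejects — the two synthetic generators genuinely differ in their
strongest edges — while the global-strength difference is not significant
at these sample sizes. Centralities, stability curves and the
severity-adjusted odds-ratio table come from `centrality_table()`,
`case_drop_bootstrap()` and `adjusted_comparison()`; `run_pipeline()` wires
all stages together and writes tidy CSV/JSON outputs plus a manifest. A
thin command-line wrapper with per-stage subcommands ships in `inst/cli/`.

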