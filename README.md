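# cultrates

Do the cultural traits that change most in one world region also change
most in another? `cultrates` implements a phylogenetic comparative pipeline
for that question: discrete cross-cultural characters (marriage payments,
settlement patterns, roofing materials, ...) are mapped onto Bayesian
posterior samples of language phylogenies for two unrelated language
families; per-trait amounts of change are estimated independently in each
family; and the per-trait estimates are compared across families with
controls for the confounds that could fake a correlation.

It is aimed at cultural-evolution and cultural-phylogenetics researchers
who have (i) tree samples per family (newick or NEXUS, branch lengths in
units of linguistic change), (ii) a society × variable trait matrix with an
explicit missing-data code, and (iii) a codebook giving each variable's
category count, an ecological/social class label, and optional recodes.

## The method

For each trait variable and each family, societies without a code are
pruned from every tree (path lengths preserved), and the amount of change
is estimated two ways:

* **Maximum parsimony (MP)** — the minimum number of changes explaining the
  tip states: a Sankoff dynamic programme with unit costs over observed
  states, polytomy-safe and rooting-invariant; averaged over the tree
  sample ("Pars").
* **Stochastic character mapping (SCM)** — fit the symmetric k-state Mk
  model's instantaneous rate by maximum likelihood (Felsenstein pruning;
  closed-form transition probabilities
  `P_same = 1/k + (k-1)/k·e^(−krt)`), then draw 20 endpoint-conditioned
  character histories per tree at the fitted rate (rejection sampling with
  an exact uniformization fallback) and count their changes ("SCM").

Cross-family statistics: Pearson/Spearman correlations of the per-trait
counts; a partial correlation controlling per-family coverage N and the
codebook category count Cats; per-family residual counts (OLS of count on N
and Cats, "Res"); a pooled t-test and R² contrasting ecological vs social
traits on those residuals; and the per-family Spearman agreement between MP
and SCM counts. A synthetic generator produces paired families with known
shared true rates so the whole pipeline is testable end to end without any
external deposit.

## Worked example

```r
library(cultrates)

ds <- generate_paired_families(synthetic_spec(seed = 42))  # default study
sum_a <- summarize_trait_changes(ds$samples$A, ds$traits$A,
                                 n_maps = 20, seed = derive_seed(42, 1))
sum_b <- summarize_trait_changes(ds$samples$B, ds$traits$B,
                                 n_maps = 20, seed = derive_seed(42, 2))
run_comparison(sum_a, sum_b, method = "pars")
```

prints (a few minutes of compute):

```
Cross-family comparison of per-trait change counts (PARS)
  families: A vs B  (28 traits)
  Pearson r  = 0.834  (p = 3.53e-08)
  Spearman rho = 0.818  (p = 1.03e-07)
  partial r  = 0.819  (controls N_A, N_B, Cats; df = 23, p = 5.46e-07)
  eco/social family_a: t(26) = 4.52, p = 0.000119, R^2 = 0.44
  MP~SCM rank rho family_a: 0.951 (p = 9.42e-15)
  eco/social family_b: t(26) = 5.13, p = 2.39e-05, R^2 = 0.503
  MP~SCM rank rho family_b: 0.951 (p = 9.17e-15)
```

The partial r says the 28 traits' change counts line up across the two
independently simulated families even after coverage and category-count
controls — as they should, since the generator gave both families the same
true rate per trait. The positive t with p < 0.05 says the (slow-rate)
ecological traits changed significantly less than the social ones in both
families, with the class explaining ~44–50% of the residual variance; and
the MP-vs-SCM rank correlations near 0.95 say the two estimators order the
traits almost identically.

File-based runs use `run_config()` + `run_pipeline()` (per-family summary
CSVs, a combined residual-sorted trait table, a statistics CSV, and a
self-describing report); `inst/scripts/cultrates-cli.R` wraps these as
`simulate` / `count` / `compare` / `all` subcommands.

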