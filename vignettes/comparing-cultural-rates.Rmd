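---
title: "Comparing relative rates of cultural trait evolution across language families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing relative rates of cultural trait evolution across language families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultrates)
```

## The question and the measure

Do the cultural traits that change most in one world region also change most
in another? `cultrates` operationalises this as a comparison of per-trait
*amounts of inferred change* on language phylogenies. For each discrete
cross-cultural variable (marriage payments, settlement patterns, roofing
materials, ...) and each of two unrelated language families, the package
estimates how often the trait changed over the family's history, then asks
whether the per-trait counts are correlated across families after removing
known confounds. Because branch lengths on lexically inferred language trees
are in units of linguistic change rather than years, all statements are about
*relative* rates among traits within a family, never absolute rates per unit
time.

Two estimators of change are used deliberately, because they make different
assumptions:

* **Maximum parsimony (MP).** The minimum number of state changes that can
  explain the tip data — a Sankoff-style post-order dynamic programme with
  unit costs over the observed states (`fitch_score()`), handling polytomies
  natively so no arbitrary resolution or tie-break ever enters a
  deterministic statistic. Only the score is computed, never an ancestral
  reconstruction, so reconstruction ambiguity is irrelevant.
* **Stochastic character mapping (SCM).** A two-step likelihood approach:
  fit the instantaneous rate of a symmetric k-state Markov (Mk) model by
  maximum likelihood (`fit_mk_rate()`), then simulate complete character
  histories conditional on the tip data at that rate
  (`sample_stochastic_map()`) and read change counts off the sampled
  histories. Twenty maps per tree is the default (`n_maps = 20`).

Each trait is analysed over a *posterior sample* of trees, not a single
tree; the per-trait statistic is the mean count over trees (and maps). Trees
are used as read: the symmetric Mk likelihood with its stationary (uniform)
root prior and unordered parsimony are both invariant to root placement, so
no rerooting is attempted (and the test suite asserts both invariances).

## The Mk model and its numerical treatment

The Mk generator has every off-diagonal rate equal to `r`, so over a branch
of length `t`

$$P_\text{same}(t) = \tfrac1k + \tfrac{k-1}{k}e^{-krt}, \qquad
  P_\text{diff}(t) = \tfrac1k - \tfrac1k e^{-krt},$$

which the package uses in closed form everywhere (the tests compare it
against a numerical matrix exponential). Choices that matter:

* **Single symmetric rate.** No ordering of the category codes is assumed —
  cross-cultural category codes are nominal — and the equal-rates model is
  the canonical default for stochastic mapping. All-rates-different models
  are out of scope.
* **State space = observed states.** The likelihood's `k` is the number of
  distinct states actually observed after pruning, not the codebook's
  category count: unobserved categories would make the likelihood depend on
  how finely a coder chose to split a variable. The codebook count ("Cats")
  enters the analysis only as a statistical covariate.
* **Rate per (trait, tree).** Each tree in a posterior sample has its own
  branch-length scale, so the rate is fitted separately on every tree and
  the 20 maps for that tree are drawn at that tree's ML rate.
* **Optimisation.** 1-D search on the log-rate over `[1e-8, 1e3]` per unit
  branch length, tolerance `1e-8`. Constant characters (and any fit pinned
  to a bound) are flagged `"boundary"`; constant traits contribute zero
  changes rather than an estimate.
* **Underflow.** Pruning partials are rescaled per edge (and per node below
  `1e-280`), with the scale accumulated in log space.

Branch paths conditioned on their endpoint states are drawn by forward
rejection sampling (first jump from a truncated exponential when the
endpoints differ), capped at 1000 attempts, falling back to a
uniformization sampler. With uniformization rate `mu = k r` the embedded
jump chain of the symmetric Mk model is uniform over all k states, so the
fallback is exact and simple: draw the number of virtual jumps from its
conditional distribution, place them as uniform order statistics, fill
intermediate states i.i.d. uniform, and discard self-transitions (virtual
events are never counted as changes). The tests verify that the two
samplers agree in distribution and that every sampled history carries at
least the parsimony minimum number of changes.

Reproducibility is by construction: one master seed; every (trait, tree,
map) triple derives its own substream via `derive_seed()`, so results do
not depend on evaluation order, and a parsimony-only run never touches the
RNG.

## Missing data, covariates, and the comparative statistics

Cross-cultural databases code "missing" when the ethnography does not
support a judgement; coverage therefore varies trait by trait (a variable
may be coded for only half the societies in a family). Missing data are
handled *only* by pruning: for each trait, uncoded societies are removed
from every tree (path lengths between remaining tips preserved,
unifurcations collapsed) before any counting. A missing tip is never
treated as a free wildcard state — the two conventions differ in how much
branch length the trait is exposed to, and removal matches how the counts
are interpreted.

Two confounds could produce a spurious cross-family correlation in raw
counts: traits coded for more societies can change more often (coverage N),
and traits divided into more categories can change more often (Cats). The
package therefore reports:

* Pearson and Spearman correlations of the raw per-trait counts across the
  families;
* a partial correlation controlling jointly for N in family A, N in family
  B, and Cats (Cats enters once — it is a property of the variable, not of
  a family; entering it twice would be rank-deficient);
* per-family *residual* counts — OLS residuals of the count on that
  family's N and on Cats, from two separate regressions — which are the
  tabulated "Res" values and the input to the class contrast. The two
  adjustment paths (joint partial correlation vs per-family residuals) are
  distinct by design and both are implemented.

The ecological-vs-social contrast is a pooled-variance two-sample t-test on
the residuals (df = number of traits − 2; Welch available behind a flag),
with effect size reported as the R² of an OLS regression of the residuals
on the binary class indicator; for a binary predictor R² = t²/(t² + df),
an identity the tests check numerically. All p-values are two-tailed and
uncorrected; a fully rank-based mirror of the whole analysis is available
via `nonparametric = TRUE`.

## What the synthetic generator emulates — and what it does not

`generate_paired_families()` builds the study's data shape with known
ground truth: two families of 100 and 112 societies (the default sizes),
a pseudo-posterior of 10 trees per family, and 28 traits whose *true* rates
are drawn log-uniformly over a 20-fold range and shared between the
families — the rate-parallelism hypothesis made true by construction.
Category counts are uniform on 2–10 and per-trait, per-family missingness
uniform on 0–50%, mirroring the heterogeneity of real codings. By default
the 10 slowest traits carry the "eco" label, so the class contrast has a
real signal to find; `eco_rule = "random"` removes that structure. Ten
trees per sample (rather than the 100 a full posterior would carry) keeps
a default run to a few minutes; the mean over trees converges quickly and
nothing downstream depends on the sample size beyond averaging.

Trees are unit-depth pure-birth (Yule) trees — rates are "per tree depth" —
with no attempt to mimic the shape of real language phylogenies, since only
relative rates among traits matter. The pseudo-posterior default is
`tree_mode = "perturb"`: one topology per family whose branch lengths are
jittered ±20% per tree. This mimics the essential property of a real
Bayesian posterior — its trees are all *supported by the data* and
correlated with one another. The alternative `"independent"` mode (every
tree an independent Yule draw) is kept for stress-testing, but is not a
credible posterior stand-in: traits are generated on one tree, so
independent topologies are actively contradicted by the data, and the ML
rate for fast traits escapes to the search bound, saturating the stochastic
maps. Other realities the generator does not emulate: horizontal
transmission/borrowing between societies, coder bias correlated across
families, and non-random (ethnographer-driven) missingness — `missing_mode
= "clustered"` offers only a crude phylogenetically clumped variant to
stress the pruning path. Passing the synthetic acceptance checks therefore
shows the estimators and statistics recover a known signal under the
model's own assumptions, not that those assumptions hold for real
ethnographic data.

## Worked example

A reduced instance (two families of 30 and 36 societies, 12 traits, 5-tree
samples, 5 maps per tree) keeps the chunk fast while exercising every
stage:

```{r example}
spec <- synthetic_spec(n_taxa = c(30L, 36L), n_trees = 5L, n_traits = 12L,
                       n_eco = 4L, seed = 7L)
ds <- generate_paired_families(spec)
ds

sum_a <- summarize_trait_changes(ds$samples$A, ds$traits$A,
                                 n_maps = 5L, seed = derive_seed(7L, 1L))
sum_b <- summarize_trait_changes(ds$samples$B, ds$traits$B,
                                 n_maps = 5L, seed = derive_seed(7L, 2L))
head(sum_a)

cmp <- run_comparison(sum_a, sum_b, method = "pars")
cmp
```

At this size the statistics are noisy; the package's acceptance checks run
the full default spec (100/112 societies, 28 traits, 10 trees, 20 maps),
where the cross-family partial correlation, the eco/social contrast and the
MP-vs-SCM rank agreement are all comfortably recovered.

File-based runs go through `run_config()` + `run_pipeline()`, which write
per-family summary CSVs, a combined per-trait table sorted by the family-A
residual, a long-form statistics CSV and a self-describing text report; a
thin command-line wrapper with `simulate`/`count`/`compare`/`all`
subcommands ships in `inst/scripts/cultrates-cli.R`.

## Known limitations

* Counts, not time: no absolute-rate calibration is attempted, and none is
  possible on change-unit branch lengths.
* The Mk fit ignores rate variation within a trait across lineages and any
  asymmetry between categories.
* Borrowing between societies violates the tree assumption; its net effect
  on relative counts is not modelled here.
* Un-analysable traits (fewer than two coded societies, or constant after
  recoding) are flagged and dropped from the comparison rather than
  imputed.
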