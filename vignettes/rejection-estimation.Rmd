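---
title: "Estimating transmission biases by grid-search rejection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transmission biases by grid-search rejection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transbias)
```

## The inferential problem

A participant learns two variants of a behaviour from two sources — an
*expert* and a *peer* — and then produces one of them. The experiment is run
in two transmission contexts: *expert-to-novice*, where the congruent source
(the one whose social role matches the context) is the expert, and
*peer-to-peer*, where the congruent source is the peer. The data are four
counts: expert-variant versus peer-variant productions in each context.

Two latent biases could drive those counts. An **expert bias** favours the
expert's variant in both contexts; a **congruence bias** favours the
expert's variant in the expert-to-novice context but the peer's variant in
the peer-to-peer context. The two-context design makes them separable:
roughly, the expert bias moves both conditions in the same direction while
the congruence bias moves them apart.

## The choice model and its assumptions

Each bias strength $b \in [-1, 1]$ becomes a multiplicative factor weight
$w(b) = (1 + b)/2$. A variant is described by three binary attributes —
source (expert/peer), contextual congruence of that source, and learning
order (first/last) — and its total weight is the product of one factor per
attribute, with the factor for the "other" pole using the negated bias.
The production probability is the Luce choice rule over the two competing
variants:

$$
P(v \mid v, v') = \frac{W(v)}{W(v) + W(v')},
\qquad W(v) = w(\pm b_E)\, w(\pm b_C)\, w(\pm b_P).
$$

Modelling assumptions:

- **Independence.** Participants are i.i.d. given the parameters, so each
  context's expert-variant count is binomial (stratified by learning order
  when the primacy bias is active).
- **Boundary convention.** At total opposing biases both weights can be
  zero; `choice_probability()` then returns $1/2$ by declared convention
  rather than `NaN`. This is the package's resolution of the model's only
  indeterminate point, and it is exercised by tests.
- **Primacy sign convention.** `primacy_bias > 0` favours the *last-learned*
  variant; `recency_bias()` is its negation. With `primacy_bias = 0` the
  order factor is $1/2$ for both variants and cancels, which is why the
  default analysis uses four counts rather than eight.

Useful exact identities of this model (each verified to $10^{-12}$ in the
test suite over random parameter draws):

- complementary probabilities sum to one;
- negating the expert bias and swapping the produced/alternative roles maps
  one context onto the other;
- negating the congruence bias maps each context's probabilities onto the
  other context's;
- negating *both* biases swaps the two variants within a context;
- with neutral primacy, learning order is irrelevant.

Note the third identity is a *between*-context mapping: within a single
context, negating the congruence bias does **not** simply exchange the
congruent and incongruent production probabilities once the expert bias is
nonzero, because the normalization couples the factors.

## Rejection estimation

`run_grid()` implements grid-search rejection (a form of approximate
Bayesian computation with a uniform lattice prior and an exact-match
kernel):

1. lay a lattice over the parameter space — `grid_spec()` defaults to
   $-1, -0.99, \dots, 1$ on both axes (201 × 201 cells);
2. in each cell simulate `s = 5000` experiments with the design's condition
   sizes, drawing the per-context counts from the model binomials;
3. count how many replicates reproduce the observed table exactly
   (`tolerance = 0`; an integer tolerance relaxes the match per cell).

The retained multiset — each lattice value repeated once per matching
replicate — is summarized by `summarize_matches()`: match-weighted mean and
SD per parameter, a one-sample $t$ against zero on the expanded multiset,
and Welch (default) or pooled two-sample $t$ between parameters. With fewer
than two total matches the summary is flagged `undefined` rather than
reporting meaningless moments.

The three-parameter variant (`grid_spec_primacy()`: steps 0.1, 0.1, 0.05 and
tolerance 1) matches the eight-cell table stratified by learning order; the
coarser steps and relaxed tolerance keep the much larger lattice and the
smaller per-stratum counts tractable.

### Reproducibility

Cell simulations use per-cell RNG substreams: `derive_cell_seeds(seed, n)`
seeds `sample.int()` once and deals an independent seed to every cell, so
results are reproducible and independent of cell evaluation order.

## The analytic oracle

Because the counts are binomial, the probability that a simulated replicate
matches the observed table is available in closed form:
`match_probability()` multiplies, across contexts (or across the four
counterbalancing strata in the eight-cell case), the binomial mass on the
tolerated window around each observed count. From it,
`exact_weighted_moments()` computes the $s \to \infty$ limit of the
Monte-Carlo summary — the lattice mean and SD weighted by exact match
probabilities — in milliseconds.

The oracle serves three purposes: it validates the simulator (the suite
checks Monte-Carlo match frequencies against analytic probabilities within
binomial standard errors), it provides instant estimates for simulation
studies such as parameter-recovery sweeps where thousands of full
Monte-Carlo grids would be wasteful, and it bounds Monte-Carlo error in the
end-to-end tests.

## Numerical choices

- Probabilities are ratios of products of factors in $[0, 1]$; no logs are
  needed at this scale and all oracle sums run over at most
  $n + 1 \le 33$ binomial terms.
- The lattice is generated as `min + step * (0:k)`, so lattice values carry
  ordinary floating-point representation error (e.g. a step of $0.01$ does
  not land exactly on $0.43$). All internal comparisons are by index, never
  by `==` on values.
- Chi-squared statistics (`chisq_goodness_of_fit()`, equal-expected
  two-cell; `chisq_independence()`, 2 × 2 without continuity correction) and
  $t$ statistics delegate to `stats::chisq.test()` / `stats::t.test()`; the
  closed forms serve as independent oracles in the tests.
- `analyze_counts()` applies a Bonferroni correction across its three
  planned hypotheses ($\alpha/3$) and reports control analyses (content and
  counterbalancing checks) uncorrected.

## Synthetic cohorts

`generate_participants()` draws fully counterbalanced cohorts: per
condition, participants are balanced over learning order × strategy order
(four cells, so `n` must be divisible by four), the expert's demonstrated
content is tied to the counterbalancing cell, and optional random exclusions
mimic attrition in one condition. `tabulate_productions()` folds a cohort
back to the four- or eight-cell table, closing the loop for recovery
studies:

```r
truth <- bias_params(expert_bias = 0.4, congruent_bias = 0.5)
cohort <- generate_participants(truth, n_per_condition = 32, seed = 1)
obs <- tabulate_productions(cohort)
tidy(exact_weighted_moments(obs, experiment_design(32, 32), grid_spec()))
```

## Limitations

- The estimator assumes the observed table is *reachable* under the model;
  a table impossible under every lattice cell yields an `undefined` summary
  (Monte Carlo) or an explicit error (oracle).
- The lattice prior is uniform and bounded at $\pm 1$ by construction of the
  bias scale; the match-weighted mean is a posterior mean under that prior,
  not a maximum-likelihood estimate.
- The $t$ statistics treat the expanded multiset as an i.i.d. sample; they
  are descriptive of the match distribution, not frequentist tests about
  the data-generating process.
- With exact matching and small `s`, low-probability tables can produce few
  matches and noisy summaries; raise `s`, relax `tolerance`, or switch to
  the exact oracle.
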