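---
title: "Modelling substrate-niche evolution over posterior tree sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling substrate-niche evolution over posterior tree sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyniche)
```

# The setting

phyniche analyses a categorical niche character — its motivating case is
the preferred substrate of crustose lichen fungi, coded over the fixed
alphabet *rock, soil, bark, wood, lichen*, plus a binary
generalist/specialist coding — on a clade of ~100 species whose phylogeny
is known only up to a Bayesian posterior sample of time-calibrated trees.
Every inference is therefore designed to run over a tree *set* (typically
100 trees) rather than a single topology, and every per-tree result is
summarized across the set.

Two coding rules sit upstream of all models. A species is a *specialist*
when strictly more than 95% of its recorded occurrences come from one
substrate (`classify_gs()`; the threshold is an argument, the inequality is
strict, and modal-substrate ties for generalists are flagged rather than
broken arbitrarily). Sampling completeness is the per-group ratio of
included to described species (`sampling_fractions()`), with an all-ones
constructor for complete-sampling scenarios. The five-state alphabet is
fixed even when a state is unobserved in a dataset, so rate matrices and
diversification parameter vectors remain comparable across datasets.

# Models and procedures

## Mk machinery

Discrete-character evolution is modelled as a continuous-time Markov chain
with a k×k rate matrix Q. Models are *constraint masks* over the
off-diagonal cells: equal-rates (ER), symmetric (SYM), all-rates-different
(ARD), or any custom mask mixing fixed zeros and tied rates. The
likelihood is computed by Felsenstein's pruning algorithm in a compiled
core, with per-edge rescaling against underflow; multifurcations are
handled natively and zero-length branches act as identity transitions.
P(t) = exp(Qt) uses eigendecomposition when the eigenvector matrix is well
conditioned (condition number below 1e8) and scaling-and-squaring
otherwise — absorbing-state masks are frequently defective, so the
fallback is exercised routinely. ER has a closed form and bypasses both.

Maximum-likelihood fitting is multi-start local optimization in log-rate
space with box constraints [1e-9, 1e3] per rate (Brent for one-parameter
models, L-BFGS-B otherwise). A fit that never attains a finite likelihood
is flagged rather than raised as an error, because the model-ranking
stages must tolerate and exclude failed cells. Root priors are uniform
(default), stationary, data-conditional (FitzJohn weights), or explicit.

Marginal ancestral states come from the standard up-down
(inside-outside) pass; each node's posterior integrates over all other
nodes' states.

## No-switch (dead-end) model family

One model per non-empty proper subset S of states: every transition out of
every state in S is fixed to zero and all remaining off-diagonal rates are
free — 2^k − 2 models, 30 for k = 5, ordered by subset size then state
index. Each model is fitted to each tree; per tree, converged fits are
ranked by AIC with dense ranks (ties within 1e-6 share a rank; listing
order breaks ties toward fewer parameters, then model order — the rank
plots need integers, and byte-identical models must order
deterministically). `top_models()` counts, per model, the trees on which
its rank is at most 5 and returns the models supported by strictly more
than half of the non-dropped trees. Trees where every model fails are
dropped with a warning; individual failures are simply excluded from that
tree's ranking.

## Ancestral-state ensemble

Node identity across topologically varying trees is the one genuinely open
design point: a posterior sample has no shared node indexing. A focal node
is therefore *anchored* as the MRCA of a fixed reference tip subset; votes
are counted from the anchored MRCA in every tree regardless of monophyly,
and the monophyly fraction is reported alongside so that readers can
discount nodes that dissolve under topological variation.

The ensemble grid is a plain tibble of method × model × root-prior cells.
The default is the full product {ml, simmap} × {ER, SYM, ARD} ×
{uniform, stationary, fitzjohn} — 18 cells for a five-state character,
12 for a binary one (SYM duplicates ER at k = 2 and is dropped). We chose
the complete product over a hand-pruned cell list because any pruning rule
would be arbitrary: no natural product of methods, models and priors lands
on a particular historical grid size, and the grid is serialized into the
report header so any alternative can be swapped in. Votes are argmax
marginals for `ml` cells and modal sampled node states for `simmap` cells;
per node, votes plus logged failures always account for n_trees × n_cells.

## Stochastic character mapping

Histories conditional on tip data and a fitted Q are sampled in two steps:
node states from their joint conditional distribution (post-order
likelihoods, pre-order sampling), then each branch path conditional on its
endpoints by uniformization — Poissonized jumps at the dominating rate
Ω = max|Q_ii|, bridge-sampled intermediate states via cached powers of
R = I + Q/Ω, virtual (self) jumps collapsed into dwell segments. When
Ω·t < 1e-8 the sampler falls back to forward rejection sampling (and an
infeasible endpoint pair under a masked Q raises an error). Uniformization
is exact and efficient in the low-rate regime these characters occupy.
The default replication — 100 maps per tree × 100 trees — yields the
10 000-history totals the transition summaries are built from. Q is refit
per tree by default, since each tree's reconstruction should condition on
its own branch lengths; a fixed-Q option exists.

## Phylogenetic-signal tests

Both tests are permutation tests with the add-one estimator
p = (1 + #{null at least as extreme}) / (1 + n_perm), so p is never zero
and, under exchangeable labels, rejection at level α occurs with
probability exactly α (the calibration tests check this at 199
permutations and 400 replicates).

The λ test fits an ER Mk model on λ-transformed trees (internal branches
scaled by λ, pendant branches re-stretched so root-to-tip depths are
preserved) and compares the observed maximized log-likelihood with its
distribution over tip-label permutations. The scenario grid
{0, 0.25, 0.5, 0.75, 1} is configurable; ER is used because the statistic
only needs to order real against permuted data under a common model, and
the one-parameter fit keeps 100 × (1 + n_perm) optimizations cheap. At
λ = 0 the transformed tree is a star phylogeny, every permutation has the
same likelihood function, and p = 1 by construction; lnL equality is
detected with a 1e-7 tolerance because summation order perturbs the last
bits.

The distance test uses the mean patristic distance over all unordered
same-state tip pairs, per state and pooled (pair-count weighted), with a
one-sided "shorter than null" p-value. States with fewer than two tips are
reported as untestable, with tip counts attached so low-power states are
visible rather than silently dropped.

## State-dependent diversification

The MuSSE likelihood integrates, along each branch, the extinction
probabilities E_i(t) and data probabilities D_i(t) of the standard
state-dependent speciation–extinction equations, joining daughters at each
node with a per-state speciation factor. Integration uses a compiled
Cash–Karp Runge–Kutta 4(5) scheme with rtol 1e-8 / atol 1e-10 per branch;
after each accepted step E is clamped to [0, 1] and D to non-negative,
because an E overshooting 1 turns the quadratic term explosive at the
extreme parameter values optimizers like to visit, and a step-size
underflow is reported as an invalid likelihood rather than an error so the
optimizer can back away. Tip conditions are D_i = ρ_i for the observed
state and E_i(0) = 1 − ρ_i, with state-specific sampling fractions ρ_i
(clade-specific sampling is out of scope). The root uses FitzJohn
(D-proportional) weighting by default, with flat and explicit-prior
options; survival conditioning divides D_i by λ_i (1 − E_i)² before
weighting. These are the defaults of the method's literature; both are
arguments.

Three exact reductions anchor the implementation: with k = 1 the machinery
is the constant-rate birth–death likelihood, whose pure-birth case has the
closed form (n−1)·log λ − λ·(total branch length); and with all states
sharing λ and μ at ρ = 1 the MuSSE likelihood factorizes exactly into
birth–death × Mk. Both are asserted in the tests at 1e-8 and 1e-6.

ML fitting reuses the log-space multi-start scheme; constraint blocks tie
λ or μ across states, or fix μ at exactly zero. The MCMC sampler is
random-walk Metropolis on log-parameters under independent exponential
priors, with the proposal scale adapted toward 30% acceptance during
burn-in only (adapting after burn-in would bias the chain); a prior-only
mode drops the data term so prior recovery can be checked directly.
Defaults are 10 000 steps and 10% burn-in for single-tree runs; when
pooling across 100 trees, shorter per-tree chains (~1 000 steps) are
appropriate since only the pooled density is consumed. Pooled per-state
densities of r = λ − μ are compared pairwise with two-sided Mann–Whitney
tests (exact for tie-free samples of at most 8, tie-corrected normal
approximation otherwise; all-tied samples return p = 1 with a note).

The trait-independence check simulates neutral binary characters on a
fixed tree under symmetric Mk(q) for each q in a grid, fits the
state-dependent model against the tied-rates null (transitions free in
both; df = 2), and reports the fraction preferred by a likelihood-ratio
test at α = 0.05 with a binomial confidence interval. Constant simulated
characters are redrawn (they carry no information about state
dependence). On a homogeneous pure-birth tree this fraction is the
machinery's type-1 error and sits at the nominal level in the tests.

# The synthetic-data generator

`simulate_bd_tree()`, `simulate_mk()`, `simulate_musse()` and
`simulate_posterior_set()` emulate the study conditions: ~100-tip
ultrametric trees, a five-state substrate character with strong
phylogenetic clustering, a binary strategy character, and 100-tree
posterior-like sets. Design choices:

- **Birth–death conditioning.** Forward Gillespie simulation, retried on
  extinction, stopped the first time the extant count reaches n; the tree
  is then extended by u·Δt (u uniform, Δt the next waiting time) so
  pendant edges are never zero. Simple resampling rather than conditioned
  bridges is adequate at this scale. The state-dependent simulator is the
  same code path with per-state rates; the neutral tree simulator is its
  k = 1 case.
- **Posterior-set emulation.** Internal node ages are jittered by i.i.d.
  lognormal noise (σ = `jitter`, default 0.1) with parent–child ordering
  repaired top-down, preserving ultrametricity exactly; an optional
  fraction of trees receives one rooted NNI move for topological
  variation. This mimics the variance structure of a Bayesian posterior —
  correlated branch-length uncertainty with occasional topology changes —
  but not its correlation with the data, asymmetric clade supports, or
  burn-in artifacts; conclusions about real posteriors should lean on the
  multi-tree design, not on this generator matching a Bayesian dating
  run in distribution.
- **Demo scale.** `demo_dataset()` produces 100 tips × 100 trees with a
  clustered five-state character (0.15 expected changes per unit height)
  and a binary character (0.3), so documented pipelines run in minutes.

What passing tests on these data do and do not show: parameter-recovery
and calibration results demonstrate correctness of the estimators under
the generating models; they do not certify behaviour under model
misspecification (rate heterogeneity across clades, hidden states,
correlated characters), which real data surely exhibit.

# Numerical choices and problem sizes

- Rate boxes [1e-9, 1e3]; a constant character drives the ER rate to the
  lower bound and lnL to log(1/k), as it should.
- AIC ties share dense ranks within 1e-6.
- Ultrametricity tolerance: (max − min root-to-tip depth) ≤ 1e-6 × height;
  operations that require ultrametricity (λ transform, SSE) re-check and
  error, others warn.
- Newick output carries 9 significant digits, bounding round-trip error at
  5e-9 relative.
- Test problem sizes were chosen to exercise each claim at the scale that
  is integral to it while keeping the default run practical on one CPU:
  the dead-end grid runs at its full 30 × 100 design on 100-tip trees with
  single-start optimization (restarts matter little for ranking, which
  only needs lnL to well under one AIC unit); signal-test calibration uses
  400 replicates × 199 permutations on a 50-tip tree; stochastic-mapping
  consistency uses 10 000 maps on a 15-tip tree; MuSSE rank recovery uses
  ten 500-tip replicates; the dead-end recovery experiment uses a 150-tip
  tree and 20 jittered trees with churn 0.5 and wood-entry 0.15 expected
  events per unit height — moderate churn keeps every free state's exit
  evidence comparable, which is what makes the generating singleton mask
  identifiable against both its sub- and super-models.

# Known limitations

- Hidden-rate (covarion/precursor) models, model averaging over the mask
  family, Bayes-factor comparisons, and character-independent
  shift-detection samplers are out of scope.
- The ensemble's default grid is a documented choice, not a canonical
  object; vote counts are only comparable within one grid.
- MuSSE inherits the known fragility of state-dependent diversification
  models on real trees; the trait-independence check quantifies, not
  removes, it. Polytomies are rejected in SSE likelihoods.
- Secondary-substrate observations are carried as annotations only; all
  models are single-state-per-tip.
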