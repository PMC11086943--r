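---
title: "Entropy-based echo-chamber detection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based echo-chamber detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An echo chamber is a bounded media space in which a group of users is
repeatedly exposed to the same news and the same opinions, amplifying them
internally and insulating them from rebuttal. `echonet` operationalizes
this with three jointly necessary conditions on a set of users observed in
a social-media post dataset:

1. they engage with the same news sources in a statistically significant
   way (they share a *news engagement community*, NEC);
2. they contribute to the same discourse (they share a *discursive
   community*, DiCo);
3. they actually interact: they form a weakly connected component of the
   retweet network.

The distinctive element is the statistical benchmark used in conditions 1
and 2: raw co-occurrence counts ("how many URLs do these two users both
share?", "how many common retweeters do these two verified accounts
have?") are compared against a maximum-entropy null model of the
underlying bipartite network, so that everything explainable by activity
levels alone is discarded as noise.

## The null model

Both detection paths start from a binary bipartite network with
biadjacency matrix $B$ ($b_{i\alpha} \in \{0,1\}$), top-layer degrees
$k_i = \sum_\alpha b_{i\alpha}$ and bottom-layer degrees
$h_\alpha = \sum_i b_{i\alpha}$. The Bipartite Configuration Model (BiCM)
is the ensemble that maximizes the Shannon entropy
$S = -\sum_G P(G)\ln P(G)$ subject to the expected degree sequences
matching the observed ones. The Lagrangian maximization factorizes the
graph probability into independent Bernoulli links,

$$P(G) = \prod_{i\alpha} p_{i\alpha}^{\,b_{i\alpha}}
          (1-p_{i\alpha})^{1-b_{i\alpha}},
  \qquad
  p_{i\alpha} = \frac{e^{-(\theta_i+\eta_\alpha)}}
                      {1+e^{-(\theta_i+\eta_\alpha)}},$$

and likelihood maximization fixes the multipliers through
$\sum_\alpha p_{i\alpha} = k_i^*$, $\sum_i p_{i\alpha} = h_\alpha^*$.

**Solver.** `fit_bicm()` solves the likelihood conditions on the
degree-reduced system (nodes with equal degree provably share a
multiplier, which also makes equal-degree multipliers bit-identical) with
a fixed-point iteration in the variables $x_i = e^{-\theta_i}$,
$y_\alpha = e^{-\eta_\alpha}$; if the iteration has not reached the
tolerance it falls back to quasi-Newton (BFGS) maximization of the reduced
log-likelihood in log coordinates. Defaults: tolerance `1e-8` on the
maximum absolute degree residual, 10,000 iterations. The tolerance is our
choice — the upstream description delegates the numerics — and `1e-8` on
counts of magnitude 1–1000 is far below any statistical resolution of the
p-values computed from the fit.

**Degenerate nodes.** Degree-0 and full-degree rows/columns would push
multipliers to $\pm\infty$. They are peeled off iteratively before solving
(a full node's certain links reduce the opposite residual degrees, which
can cascade) and reinstated with exact limits $p \in \{0, 1\}$. The peel
records probabilities in order, so a column drained to residual degree 0
by full rows keeps its $p = 1$ links to those rows rather than being
mistaken for an originally empty column.

## Validated projections

For an unordered pair $(i, j)$ on the projected layer the co-occurrence
$V^*_{ij} = \sum_\alpha b_{i\alpha}b_{j\alpha}$ is, under the BiCM, a sum
of independent Bernoulli variables with heterogeneous probabilities
$p_{i\alpha}p_{j\alpha}$ — a Poisson–binomial. `poisson_binomial_sf()`
evaluates the upper tail $P(V \ge V^*)$ by exact dynamic-programming
convolution in $O(\text{len}\cdot V^*)$; a normal approximation exists but
is opt-in (never default) so that test results stay bit-stable. The test
is one-tailed upper because the method looks for over-expressed
co-occurrence only.

The family of tests is *all* $\binom{N}{2}$ pairs on the layer, including
pairs with $V^* = 0$ whose p-value is exactly 1; this makes the number of
hypotheses $m$ unambiguous. False discoveries are controlled with
Benjamini–Hochberg at $\alpha = 0.05$ by default (`--alpha` exposes it):
reject all pairs with $p \le p_{(\hat k)}$,
$\hat k = \max\{k: p_{(k)} \le k\alpha/m\}$. Validated pairs become edges
of the monopartite projection; nodes with at least one validated edge are
the validated users.

## Communities and labels

**Best-of-N Louvain.** Louvain is node-order dependent, so
`louvain_best_of()` repeats it (default 1,000 times) on randomly permuted
copies of the graph under sub-seeds derived from one master seed and keeps
the configuration with the greatest modularity. Two numerical choices are
ours: (i) the connected-components partition competes as a reference
configuration, because on a single connected near-clique every Louvain
restart can land on a spurious $Q = 0$ split that merely *ties* the
trivial partition — under "greatest modularity" a tie must not fragment a
community; (ii) exact modularity ties resolve to fewer communities, then
to the earliest restart, making the winner deterministic.

**Label propagation.** DiCo labels are seeded by the communities of the
validated verified-user projection and extended over the undirected
retweet network by a two-phase majority rule: a user with verified
neighbors takes the (edge-weight-weighted) majority label of those
verified neighbors; a user with none takes the majority label of its
already-labeled unverified neighbors; sweeps continue asynchronously in
seeded random order until no label changes. Majority ties keep the current
label when it is among the tied set (this guarantees convergence) and are
otherwise broken uniformly at random under the run seed. Retweet
multiplicities weight the votes by default because repeated endorsement is
stronger evidence of alignment; `weighted = FALSE` disables this. Users
never reached keep no label — the analogue of the users that belong to no
discursive community.

## Echo chambers

`detect_echo_chambers()` intersects NEC co-membership, DiCo co-membership
and retweet connectivity. Two connectivity readings are exposed because
the definition can be read both ways:

- `nec_induced` (default): components of the retweet subgraph induced by
  the (NEC, DiCo) co-members themselves. This is the stricter reading and
  matches the observed behaviour that NECs whose members never retweet
  each other yield no chamber.
- `dico_paths`: co-members may be connected through any user of the same
  DiCo (the "flow of influence restricted to the discursive community"
  reading).

Every component with at least two members is a chamber and inherits the
NEC id (suffixed `.1`, `.2`, ... if one NEC yields several components —
uniqueness is never guaranteed by the definition). Diagnostics per
chamber: the average undirected local clustering coefficient of members
(degree-<2 nodes contribute 0), and generated/received retweet volumes.
`aggregate_flow()` collapses the host DiCo's retweet network onto chamber
ids, pooling non-chamber DiCo users into the sentinel node `-1`, with a
minimum-weight filter for display.

## The synthetic world

`generate_dataset()` emulates a polarized debate so that every stage is
testable offline. Its defaults are a *fixed stated world*, not knobs:

- **2 blocks** of 10 verified + 400 unverified users. Unverified users
  retweet each verified account of their own block with probability 0.3
  and of the other block with probability 0.01. The audience size is our
  choice: the detectability of a planted block through validated
  co-occurrences grows like the square root of the audience, and a few
  hundred retweeters per block is both realistic for the verified accounts
  that anchor a national political debate and the desk-scale point where
  the stated rates (0.3 vs 0.01) are a *strong* effect.
- **Background URL sharing**: each block has a 100-URL pool over domains
  with trust labels drawn T/N/UNC with probabilities (0.5, 0.25, 0.25);
  each unverified user shares Poisson(1) pool URLs, each verified user
  one.
- **One planted NEC** of 8 users inside block 1 with a dedicated 20-URL
  pool, each member sharing each pool URL with probability 0.8, making
  members roughly an order of magnitude heavier URL-sharers than the
  background — the same contrast observed between validated and
  nonvalidated accounts in real data (tens vs single URLs per account).
- **Planted connectivity**: a random retweet spanning tree over the NEC
  members, so the planted chamber satisfies the three-condition definition
  by construction.

What the generator does *not* emulate: heavy-tailed degree distributions,
multi-topic overlap, bursty timing (timestamps are decorative), URL
shorteners in the wild, or verified users retweeting each other. A green
end-to-end test therefore establishes that the machinery recovers planted
structure at a strong effect size — not that real data behave this way.
Label propagation retains its real stochasticity: a planted member whose
few verified neighbors split evenly across blocks can be mislabeled under
an unlucky seed, which occasionally trims a planted chamber by a member or
two.

## Numerical and degenerate-input conventions

- $0\cdot\ln 0 = 0$ in the log-likelihood; probabilities hitting exactly
  0/1 on matching entries contribute 0.
- Poisson–binomial p-values are clamped to $[0, 1]$ against float
  round-off; `observed = 0` returns exactly 1, `observed` above the trial
  count exactly 0; trials with $p = 1$ are counted as certain successes
  before the DP.
- Empty validated projections are warnings, not errors: downstream stages
  emit empty assignments.
- Self-retweets and duplicate post ids are dropped at load with per-reason
  counts; a file more than half malformed is a fatal format error.
- Multiple identical URLs inside one post count once (distinct URLs per
  post); the same URL across posts keeps its multiplicity in trust
  tallies.
- Registrable domains come from an embedded subset of multi-part public
  suffixes (`co.uk`-style) plus the default last-two-labels rule;
  `extra_suffixes` extends it. This deliberately narrows the full public
  suffix list.

## Known limitations

- The exact DP p-value is $O(\text{len}\cdot V^*)$ per pair; at hundreds
  of thousands of pairs with large counts the opt-in normal approximation
  becomes necessary.
- Verified-verified retweets are excluded from the bipartite layer by
  construction; we keep them in the retweet network used for propagation
  and connectivity (the upstream description is silent; endorsement
  between content creators is still endorsement).
- Trust labels are consumed as an input table; unknown domains fall back
  to UNC, so coverage of the label table directly caps the interpretability
  of N/T ratios.
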