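---
title: "Quantifying regulatory nonlinearity in Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regulatory nonlinearity in Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnonlin)
```

## The model

A Boolean network assigns each node a binary state updated by a logic
rule of its regulators. `regnonlin` asks how *nonlinearly* those rules
combine their inputs, by three steps.

**1. Multilinear extension.** Treating each input as an independent
Bernoulli variable with success probability $p_i$, a rule
$f:\{0,1\}^k \to \{0,1\}$ extends to
$\hat f(p) = \sum_{x \in R_1} \prod_i \hat p_i$, where $R_1$ is the set
of 1-states and $\hat p_i$ is $p_i$ or $1-p_i$ according to $x_i$. The
extension is the unique multilinear polynomial agreeing with $f$ on the
binary corners; at $p = (1/2,\dots,1/2)$ it equals the output bias
$|R_1|/2^k$.

**2. Taylor decomposition.** Because $\hat f$ is square-free, its
Taylor series about a center $p$ is finite, with one term per binary
multi-index $\alpha$ and coefficient $\partial^\alpha \hat f(p)$ (a
mixed finite difference). We center at $(1/2,\dots,1/2)$ throughout —
the unbiased choice, whose constant term is the bias; other centers are
supported but nothing downstream uses them. Order $|\alpha|$ groups
terms by how many inputs act jointly: order 1 is the independent
(linear) part, higher orders the genuinely nonlinear interactions.
Truncating at order $m$ defines the order-$m$ approximation of the
rule; $m \ge k$ is exact.

**3. Approximability.** The network is simulated synchronously from
shared random binary initial states, once exactly and once with every
rule truncated at order $m$ (continuous states clamped to $[0,1]$ after
each update). The mean approximation error (MAE) is the mean squared
difference of final states. A model's MAE is compared with two null
ensembles via
$\mathrm{PMAE}_X = 100(\mathrm{MAE}_X -
\mathrm{MAE}_{\mathrm{unc}})/\mathrm{MAE}_{\mathrm{unc}}$ and
$\mathrm{approximability} = \mathrm{PMAE}_{\mathrm{con}} -
\mathrm{PMAE}_{\mathrm{model}}$: positive values mean the model's rules
are easier to approximate at that order than random rules with the
same wiring and biases.

## Assumptions and conventions

- **Row order.** State code $i \in [0, 2^k)$ gives input $j$ the $j$-th
  *most significant* bit of $i$; the first-listed regulator is the
  high-order bit. All tables, decompositions, files and oracles use
  this single convention, matching conventional truth-table listings.
- **Update scheme.** Synchronous (parallel) updating. Asynchronous and
  stochastic schemes are out of scope; trajectories of the 3-node
  worked example are consistent with synchronous updating.
- **MAE compares final states only.** "End of the simulation" is the
  headline statistic; `mae(..., time_average = TRUE)` averages the
  squared error over all steps instead, as a sensitivity variant.
- **Constant and source nodes** are encoded as the node regulating
  itself with a constant (or identity) output column, so every node
  has in-degree $\ge 1$ and a decomposable table. The `.bnet` writer
  keeps the declared wiring of a constant rule by emitting
  `0 & <regulators>`.
- **Rule grammar.** `&`, `|`, `!`, parentheses, constants `0`/`1`,
  `#` comments; XOR must be written expanded. Regulator order is the
  order of first appearance in the rule and is semantic.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_init` | 1000 | random binary initial states per simulation |
| `steps` | 500 | synchronous update steps before scoring |
| `ensemble_size` | 100 | members per null ensemble |
| `orders` | 1 … max in-degree | truncation orders evaluated |
| rule-size cap | 16 inputs | exhaustive $2^k$ tables stay cheap below it |

The simulation defaults match the scale at which published model
suites have been benchmarked. Initial states are drawn uniformly
without deduplication, so `n_init` may exceed $2^n$ for small
networks. Identical seeds give bit-identical reports; the same initial
states feed the model and both of its ensembles so that order effects
are isolated from sampling noise.

## The random-model generator

`generate_random_model()` draws, per node, an in-degree from
$\{1,2,3,4\}$ (mean 2.5) and a target bias uniformly on
$[0.1625, 0.65625]$, then wires $k$ distinct regulators uniformly
(self-loops allowed) and fills the table with exactly
$\mathrm{round}(b\,2^k)$ ones placed uniformly. The default ranges
bracket the mean in-degrees (about 1.18–4.94) and mean output biases
reported across published Boolean models of biochemical regulation, so
generated suites emulate those first-order statistics. They do *not*
emulate canalization, redundancy, degree correlations, modular
topology, or the curated semantics of real rules — so tests passing on
generated networks validate the machinery and its statistical
calibration, not biological claims about real models.

Null-ensemble choices that the underlying description leaves open:

- **Constrained ensemble**: each node's output column is replaced by a
  uniform random permutation of itself — bias conservation is exact,
  member by member; bias-0/1 rules are necessarily unchanged.
- **Unconstrained ensemble**: per-node (in-degree, bias) pairs are
  bootstrap-resampled *jointly*, preserving their empirical coupling;
  `joint = FALSE` switches to independent marginal resampling. Wiring
  is redrawn with distinct regulators (no multi-edges), self-loops
  allowed.
- Per-member RNG streams are seeded `seed + member`, so any member is
  reproducible in isolation.

## Numerical choices

- Coefficients are computed by an $O(k2^k)$ per-variable basis change
  (corner values to shifted-monomial coefficients); the per-index
  finite difference and an independent symbolic expansion of the $R_1$
  sum are kept as cross-checks in the test suite, and all three agree
  to $10^{-12}$ over every 3-input function.
- Dense coefficient storage up to $k = 8$; above that only
  coefficients with magnitude $> 10^{-12}$ are kept (the $2^k$ term
  count makes dense storage wasteful).
- Bias-to-count rounding is half-*up* (`floor(x + 0.5)`): biases of
  real rules are multiples of $2^{-k}$ so rounding is usually exact,
  and half-up gives a deterministic, parity-independent tie-break.
- Clamping resets out-of-range states to the nearest boundary after
  every node update; it is idempotent on in-range values. Truncated
  values themselves are *not* clamped by `eval_truncated()` — range
  restriction belongs to the simulator.
- Spectrum normalization divides each order-$\ell$ derivative by
  $(\min(b,1/2)-\max(b-1/2,0))\,2^\ell$, the largest magnitude any
  order-$\ell$ derivative of a bias-$b$ rule can attain. For $b \in
  \{0,1\}$ this is $0/0$; the derivative is provably 0 there and the
  normalized term is defined as 0. The bound is attained order by
  order but not necessarily by one function at several orders at once,
  and the test suite deliberately does not assert cross-order
  simultaneity.
- Spectra pool *raw* derivative magnitudes across nodes (not per-node
  means) — every term of the order is averaged in, including exact
  zeros — and report the standard deviation of that pool. With
  bimodal magnitude distributions (many zeros plus a cluster of large
  terms) the standard deviation is naturally large.
- When the unconstrained ensemble's MAE is 0 at an order (common once
  the order reaches the maximum in-degree), PMAE is undefined; the
  report carries `NA` with a warning rather than dividing by zero.

## Design choices that were genuinely open

- *Approximability definition.* "Linear approximability" is computed
  as the PMAE difference (constrained minus model) at order 1; the raw
  PMAEs are always reported alongside, so the alternative reading —
  the model's own order-1 PMAE — is recoverable from the same table.
- *Statistics.* Group comparisons use two-sided Welch $t$- and
  variance-ratio $F$-tests with raw pairwise $p$-values; a Bonferroni
  flag exists but is off by default. All category pairs are compared.
- *Test problem sizes.* The suite exercises dynamics on 50 seeded
  random networks of up to 20 nodes (in-degree $\le 4$) for exactness,
  and benchmarks 12-node networks with 20-member ensembles, 100–200
  initial states and 100 steps for the directional and calibration
  properties — sizes chosen so the full suite runs in about a minute
  while keeping Monte-Carlo noise well below the effect sizes tested.

## Limitations

- Approximation accuracy necessarily improves with order (the maximum
  order is exact), so approximability is meaningful only relative to
  ensembles at a fixed order, never as an absolute score.
- Only synchronous dynamics and final-state (or time-averaged) mean
  squared error are implemented; attractor structure, basin sizes and
  Derrida-style analyses are out of scope.
- SBML-qual/GINsim import is not supported; models arrive as `.bnet`
  rule files or explicit truth-table JSON.
- Conclusions drawn from generated suites inherit the generator's
  simplifications listed above.
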