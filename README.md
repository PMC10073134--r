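# regnonlin

How nonlinear is the regulation inside a Boolean network model of a
biological system — do a gene's regulators act on it independently, or
jointly? `regnonlin` answers this quantitatively for Boolean network
models of gene regulation and signaling (BoolNet-style `.bnet` rule
files), for the theorists and modelers who build and analyze such
models.

## The idea

A Boolean rule `f : {0,1}^k → {0,1}` is lifted to its **multilinear
(pseudo-Boolean) extension** by treating each input `i` as an
independent Bernoulli variable with success probability `p_i`:

    f̂(p_1, …, p_k) = Σ_{x ∈ R1} Π_i p̂_i ,   p̂_i = p_i if x_i = 1, else 1 − p_i

where `R1` is the set of input states mapped to 1. `f̂` agrees with `f`
on every binary corner, and `f̂(1/2, …, 1/2)` is the rule's **output
bias** `|R1| / 2^k`. Being a square-free polynomial, `f̂` has a finite
Taylor expansion about a center `p` over binary multi-indices `α`:

    f̂(x) = Σ_{|α| ≤ k} ∂^α f̂(p) · (x − p)^α

With `p = (1/2, …, 1/2)`, the order-0 term is the bias, order-1 terms
capture each input's independent (linear) effect, and higher orders
capture joint — nonlinear — action. Truncating at order `m` gives an
order-`m` approximation of the rule; truncating every rule of a network
and iterating the synchronous dynamics (states clamped to `[0,1]`)
gives an order-`m` approximation of the whole network.

The **mean approximation error** (MAE) is the mean squared difference
between exact Boolean and order-truncated final states over shared
random initial states. A model's MAE is benchmarked against two null
ensembles: **constrained** (same wiring and per-node bias, rules
shuffled) and **unconstrained** (per-node in-degree/bias pairs
bootstrap-resampled, wiring redrawn). From these,

    PMAE_X          = 100 · (MAE_X − MAE_unconstrained) / MAE_unconstrained
    approximability = PMAE_constrained − PMAE_model

so a positive approximability at order 1 ("linear approximability")
means the model is *more* linearly approximable than chance given its
wiring and biases. Per-order **nonlinearity spectra** (mean absolute
Taylor derivative, normalized by the bias-dependent maximum
`(min(p, 1/2) − max(p − 1/2, 0)) · 2^|α|`) show how regulatory weight
is apportioned across orders.

## Worked example

A 3-node network using all three 2-input gate types — `a ← NOT b`,
`b ← a OR c`, `c ← a XOR b`:

```r
library(regnonlin)
net <- boolean_network(
  inputs = list(a = "b", b = c("a", "c"), c = c("a", "b")),
  tables = list(a = truth_table(c(1, 0), inputs = "b"),
                b = truth_table(c(0, 1, 1, 1), inputs = c("a", "c")),
                c = truth_table(c(0, 1, 1, 0), inputs = c("a", "b"))))

taylor_decompose(net$tables$c)
#> Taylor decomposition: k = 2 , center = 0.5, 0.5
#>  alpha order value
#>     00     0   0.5
#>     11     2  -2.0

nonlinearity_spectrum(net)
#>   order mean        sd n
#> 1     1  0.6 0.5477226 5
#> 2     2  1.0 0.0000000 2

benchmark_model(net, orders = 1, ensemble_size = 20,
                n_init = 200, steps = 100, seed = 1)
#> Approximability benchmark (20 members, 200 initial states, 100 steps)
#>  order MAE_model MAE_constrained MAE_unconstrained PMAE_model PMAE_constrained
#>      1    0.2263          0.1815           0.07685      194.5            136.1
#>  approximability
#>           -58.33
#> linear approximability: -58.33%
```

The XOR rule has *no* linear terms — all of its weight sits at order 2
(the spectrum's order-1 mean counts its two zero derivatives) — so the
network's linear truncation is worse than that of typical rule-shuffled
nulls with the same wiring and biases: its linear approximability is
negative (−58%). Replace the XOR with a monotone rule and the sign
flips.

Models can equally be loaded from rule files with
`read_bnet("model.bnet")`, written back with `write_bnet()`, and
generated randomly with `generate_random_model()`. Category-level
comparisons of linear approximability (Welch's t-test, F-test of equal
variances) are available through `welch_t_test()`, `f_variance_test()`
and `category_report()`.

## Command line

```sh
Rscript inst/cli/regnonlin.R decompose <model.bnet> [--out-dir DIR]
Rscript inst/cli/regnonlin.R spectrum  <model.bnet>
Rscript inst/cli/regnonlin.R benchmark <model.bnet> --orders 1,2 --seed 1
Rscript inst/cli/regnonlin.R generate  --nodes 10 --seed 1
Rscript inst/cli/regnonlin.R categories <reports.tsv> <labels.tsv>
```
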