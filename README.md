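# copace

Entropy-based model selection for single-cell **time-stamped snapshot
(TSS)** data: protein abundances measured in thousands of cells at time 0
and at a later time t, with no cell tracked across the two (as in
CyTOF-style experiments). Given several candidate mass-action ODE models
that could explain how the population distribution evolved, `copace`
estimates each candidate's rates, estimates each candidate's predicted
multivariate density, and selects the candidate closest to the data in the
Kullback–Leibler sense — without ever writing down a likelihood.

The chain of ideas:

* KL divergence decomposes as cross-entropy minus entropy, and the entropy
  of the data distribution is shared by all candidates, so the KL-closest
  candidate is the one with the smallest cross-entropy
  `-E_f[log h_i(y)]`.
* Cross-entropy needs only *samples* from the data density `f`. Its sample
  average over held-out cells, the **approximate cross-entropy**

  `ACE_i = (1/N) Σ_k  −log ĥ_i(y_k | θ̃_i)`   (natural log, nats)

  is computable once two estimates are in hand:
* `θ̃_i` — candidate rates fitted by a **generalized method of moments**
  (weighted squared distance between observed moments and the moments of
  the model-evolved cells), and
* `ĥ_i` — the candidate's predicted density at time t, assembled from one
  kernel density estimate per protein joined by a **Gaussian copula**
  (Sklar's theorem) fitted to the model-evolved cells.

A 20%/80% split keeps estimation and selection on disjoint cells; an
**AICc** on the six mean differences cross-checks the winner; bootstrap
resampling of both snapshots yields **model-selection probabilities**.

Cell-to-cell variability is modeled as *extrinsic noise only*: log-normal
initial abundances evolved deterministically through the network. The
built-in system is a six-species NK-cell signaling motif (Syk
phosphorylates Vav1; SHP1 reverses it) with three free rates θ1, θ2, θ3
and three fixed ones, and three nested candidates: h1 (θ2 = 9θ1,
θ3 = 2θ1), h2 (θ2 = 9θ1), h3 (all free). The network is a declarative,
YAML-serializable object, so other topologies are data, not code.

## A worked example

Simulate a study-sized dataset under the MEDIUM ground truth
(θ = (0.10, 0.90, 0.18), 8000 cells per snapshot, t = 1.5 s), then run the
full selection:

```r
library(copace)

tss <- generate_tss("MEDIUM", n_cells = 8000, time = 1.5, seed = 11)
report <- run_selection(tss$t0, tss$yt, time = 1.5, seed = 5)
tidy(report)
#> # A tibble: 3 × 9
#>   candidate k_free theta1 theta2 theta3    cost   ace  aicc converged
#>   <chr>      <int>  <dbl>  <dbl>  <dbl>   <dbl> <dbl> <dbl> <lgl>
#> 1 h1             1 0.0938  0.844  0.188 0.0394   28.4  63.0 TRUE
#> 2 h2             2 0.102   0.921  0.179 0.00428  22.9  20.2 TRUE
#> 3 h3             3 0.103   0.921  0.179 0.00427  22.8  30.0 TRUE
report$selected_by_ace
#> [1] "h3"
report$selected_by_aicc
#> [1] "h2"
```

Reading the table: `cost` is the attained moment-matching objective — it
can only decrease as candidates gain freedom (h3 ≤ h2 ≤ h1), which is why
it cannot select a model on its own. `ace` is the approximate
cross-entropy of the held-out observed cells under each candidate's fitted
density, in nats. The fitted h2 rates (θ1 = 0.102, θ3 = 0.179) recover
the truth (0.10, 0.18) to a few percent; h1 cannot bend θ2 away from
9·θ1 and pays ~5.5 nats for the misfit. On this particular dataset h2 and
h3 are an ACE near-tie (22.9 vs 22.8): h3 contains the truth too, and one
realization cannot always distinguish "just right" from "one parameter too
many". That is exactly what the bootstrap selection probabilities are for:

```r
bs <- bootstrap_selection(tss$t0, tss$yt, time = 1.5, B = 100, seed = 5,
                          base = report)
tidy(bs)
#> # A tibble: 3 × 3
#>   candidate p_ace p_aicc
#>   <chr>     <dbl>  <dbl>
#> 1 h1         0.07   0.06
#> 2 h2         0.8    0.94
#> 3 h3         0.13   0
autoplot(bs)
```

Across 100 resamples the generating family h2 wins 80% of the time by ACE
(h3's extra freedom chases resampling noise and usually costs it the
ranking) and 94% by AICc.

`run_experiment()` drives the whole grid (scenarios × sample sizes ×
observation times) and writes CSV/JSON outputs with full provenance;
`inst/scripts/copace` exposes `simulate`, `fit`, `select`, `bootstrap`,
and `experiment` subcommands for shell use.

See the methods vignette (`vignettes/copace-methods.Rmd`) for the model,
the estimators, every numerical choice, and known limitations.

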