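# mirstress

Ranks the contribution of stress-responsive miRNAs to abiotic-stress
discrimination in *Arabidopsis thaliana*, and predicts stress type and
severity from a small miRNA panel.

The package is built around a biosensor-measured database of 11 leaf
miRNAs (miRNA-156 … miRNA-398, concentrations in fM, mean ± SD over
n = 5) under 17 treatments: a shared control plus four severity levels
of drought (% field capacity), salinity (mM NaCl), cold and heat (°C).
It answers two questions:

* **Which miRNAs matter for which stress?** Each miRNA is a player in a
  cooperative game over feature coalitions. A coalition S wins
  (v(S) = 1) when it retains at least a fraction θ of the full feature
  set's discriminative power — discretized mutual information with the
  severity class by default, leave-one-out 1-NN accuracy as the
  alternative. With σᵢ the number of *swings* for player i (coalitions
  S with v(S) = 0 but v(S ∪ {i}) = 1) and σₒ = Σⱼ σⱼ, the normalized
  Banzhaf power index is **bᵢ = σᵢ / σₒ**; ranking the bᵢ per stress
  yields the miRNA importance table. All 2¹¹ coalitions are enumerated
  exactly; a seeded Monte-Carlo estimator covers larger feature sets.
* **Can the stress be predicted from three miRNAs?** ε-SVR (own SMO
  dual solver), least-squares SVM (dense saddle-point solve), CART and
  a Gaussian Naive Bayes level predictor share one fit/predict
  contract, with the kernel family f = γ·x·x₀ (linear), (γ·x·x₀)³
  (polynomial), exp(−γ‖x−x₀‖²) (Gaussian) and tanh(γ·x·x₀) (sigmoid).
  Models are scored by pooled out-of-fold R² under repeated 3-fold
  cross-validation.

It also generates the synthetic data needed to test all of this:
truncated-normal replicates drawn from the printed mean ± SD summaries,
and planted-signal datasets with a known informative feature subset for
parameter-recovery checks of the ranker.

## Worked example

```r
library(mirstress)

tab <- load_expression_table()        # packaged 17 x 11 database
rank_all_stresses(tab)
#> miRNA importance ranks per stress (1 = most important)
#> # A tibble: 11 × 5
#>    mirna     drought salinity  cold  heat
#>    <chr>       <int>    <int> <int> <int>
#>  1 miRNA-156       3        4     2     5
#>  2 miRNA-159       4        5     3     6
#>  3 miRNA-167       5        6     1     7
#>  4 miRNA-168       6        7     5     2
#>  5 miRNA-169       1        8     6     1
#>  6 miRNA-170       7        2     7     3
#>  7 miRNA-171       8        3     8     8
#>  8 miRNA-319       9        9     9     9
#>  9 miRNA-393      10       10    10    10
#> 10 miRNA-396      11       11    11    11
#> 11 miRNA-398       2        1     4     4
```

Rank 1 marks the most important miRNA: under the default
information-theoretic payoff, miRNA-169 carries the most power for the
drought games. Long runs of consecutive ranks (e.g. miRNA-319/-393/-396)
are tied zero-power players ordered by the fixed table column order.

```r
d <- build_stress_dataset(tab, scope = "all",
                          features = c("miRNA-169", "miRNA-393",
                                       "miRNA-396"))
g <- default_model_grid()
run_model_grid(d, g[g$family == "svr" & g$gamma == 0.05, ],
               k = 3, seeds = 1:20)[, c("label", "r2_mean", "r2_sd")]
#>                          label   r2_mean      r2_sd
#> 1     svr / linear, gamma=0.05 0.6694701 0.07963475
#> 2 svr / polynomial, gamma=0.05 0.1455853 0.10393909
#> 3   svr / gaussian, gamma=0.05 0.7483689 0.06445024
#> 4    svr / sigmoid, gamma=0.05 0.6549559 0.08239459
```

`r2_mean` is the pooled out-of-fold R² for predicting ordinal severity
(0 = control … 4 = most severe) from the three miRNA concentrations,
averaged over 20 fold seeds; the Gaussian kernel is the best of the
four at γ = 0.05. `reproduce("out/")` runs the whole pipeline (rank
matrix, 26-configuration model grid, fold-change summary, provenance
manifest) and writes CSV/JSON outputs; `autoplot()` methods draw the
rank heatmap and the R² grid. All outputs are reproducible
bit-for-bit under fixed seeds.

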