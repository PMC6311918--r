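# lncwalk

Network propagation for prioritising lncRNA–disease associations.

Curated databases record only a sliver of the true disease–lncRNA matrix,
and wet-lab validation is slow; computational ranking of the unobserved
pairs is the standard way to decide what to test next. `lncwalk` is for
computational biologists who have a table of known associations (and,
optionally, lncRNA expression profiles across tissues) and want a
reproducible, tested ranking of all candidate pairs plus an honest
cross-validated estimate of how well that ranking works.

## The method

From the binary association matrix *A* (diseases × lncRNAs) the package
builds:

- **Gaussian interaction-profile kernels** for both node types:
  `K(i,j) = exp(−γ‖IP(i) − IP(j)‖²)` over binary profiles (columns of *A*
  for lncRNAs, rows for diseases), with bandwidth `γ = γ′ / mean(‖IP‖²)`
  so the kernel adapts to network density;
- the **lncRNA similarity** `SL = ew·SPC + (1 − ew)·KL` where `SPC` is
  Spearman rank correlation of expression over tissues (pairs outside the
  profiled subset fall back to `KL`);
- the **disease similarity** `SD = 1 / (1 + exp(c·KD + d))`, a logistic
  sharpening with `c = −15`, `d = log(9999)`;
- a **two-step Laplacian normalization** of each: divide nonzero entries by
  `√(row sum · column sum)`, then rescale rows of the lncRNA matrix (`LL`)
  and columns of the disease matrix (`LD`) to unit mass;
- a **bi-random walk with restart** from the seed `Rt₀ = A / sum(A)`:

  ```
  RTᵗ = ½(α·RTᵗ⁻¹·LL + (1−α)·Rt₀) + ½(α·LD·RTᵗ⁻¹ + (1−α)·Rt₀)
  ```

  iterated to a 1e−10 fixed point. `RT(i,j)` is the predicted association
  strength of disease *i* and lncRNA *j*.

Evaluation is leave-one-out cross-validation with full per-fold similarity
recomputation, tie-aware ROC/AUC, and per-disease top-k candidate tables.
A seeded generator of block-structured synthetic networks (with matched
degree-preserving null model) makes every stage testable without external
downloads.

## Worked example

```r
library(lncwalk)

sim <- simulate_lnc_network(nd = 12, nl = 10, n_blocks = 2,
                            p_in = 0.6, p_out = 0.05, seed = 3)
scores <- lnc_predict(sim$associations, sim$expression)
glance(scores)
#> # A tibble: 1 × 6
#>   alpha iterations converged final_delta n_diseases n_lncrnas
#>   <dbl>      <int> <lgl>           <dbl>      <int>     <int>
#> 1   0.9        117 TRUE         9.66e-11         12        10

top_candidates(scores, "D001", k = 3)
#> # A tibble: 3 × 4
#>   disease lncrna  score  rank
#>   <chr>   <chr>   <dbl> <int>
#> 1 D001    L004   0.0117     1
#> 2 D001    L006   0.0102     2
#> 3 D001    L010   0.0101     3

cv <- lnc_loocv(sim$associations, sim$expression)
glance(cv)
#> # A tibble: 1 × 6
#>     auc n_folds mean_rank median_rank prop_converged alpha
#>   <dbl>   <int>     <dbl>       <dbl>          <dbl> <dbl>
#> 1 0.671      33      30.5          30              1   0.9
```

The `glance()` on the prediction says the walk reached its fixed point in
117 iterations. The candidate table lists the three highest-scoring
lncRNAs not yet linked to disease `D001` — the package's analogue of the
per-cancer candidate lists such methods are used to produce. The LOOCV
summary says that when each of the 33 known associations is withheld and
re-predicted, it lands at mean rank 30.5 among the ~88 candidate pairs
(AUC 0.671 on this small, noisy toy network).

`autoplot(cv)` draws the ROC curve; `tidy(cv)` returns the per-fold ranks;
`lnc_alpha_sweep()` tabulates AUC over a grid of walk parameters. A thin
command-line wrapper with `predict`, `loocv`, `rank` and `simulate`
subcommands ships in `inst/cli/lncwalk.R`.

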