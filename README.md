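# spotweave

Joint batch-effect correction, dimension reduction, and spatially aware
clustering for multi-slice spatial transcriptomics.

Spatial transcriptomics assays (ST, 10x Visium, Slide-seqV2) measure a gene
expression profile at each spot of a tissue section together with the spot's
2-D position. Studies almost always profile several sections, and the slices
carry batch effects that, if corrected separately from clustering and
embedding, leak technical artifacts into the biology. spotweave fits one
hierarchical hidden Markov random field over all slices at once and returns
batch-corrected low-dimensional embeddings plus spatial domain labels that
are aligned across slices. It ships a full generative simulator with ground
truth, evaluation metrics (ARI, NMI, LISI), broom-style tidiers, ggplot2
`autoplot()` methods, and a command-line interface.

## The model

For spot $i$ in slice $b$ with centered log-normalized expression
$y_{bi} \in \mathbb{R}^p$:

$$y_{bi} = L f_{bi} + \gamma_b + \varepsilon_{bi}, \qquad
  \varepsilon_{bi} \sim N_p(0, T_b^{-1})$$

$$f_{bi} \mid c_{bi}=k,\ \omega_{bi} \sim
  N_d(\mu_k, \omega_{bi}^{-1}\Lambda^{-1}), \qquad
  \omega_{bi} \sim \mathrm{Gamma}(\tfrac{\nu_\omega}{2},
  \tfrac{\nu_\omega}{2})$$

$$P(c) \propto \exp\Bigl(\sum_b \sum_i \eta_b \sum_{j\sim i}
  1(c_i = c_j)\Bigr)$$

- $L$ is a $p \times d$ loading matrix shared by all slices, with a
  spike-and-slab prior whose slab is the nonlocal pMOM density
  $(l^2/\lambda_1)\,N(l; 0, \lambda_1)$ — selected loadings are repelled
  from zero.
- $\gamma_b$ (additive) and the diagonal precisions $T_b$ (multiplicative)
  are the location-and-scale batch effects.
- Integrating $\omega_{bi}$ out makes the factor scores multivariate
  Student-t with $\nu_\omega$ degrees of freedom (default 2) — robust to
  outlying spots.
- The Potts prior lives on a combined graph: spatial K-nearest-neighbour
  edges within each slice (K = 4 for ST, K = 6 for Visium, radius 50 for
  Slide-seqV2) and mutual-nearest-neighbour expression edges (depth 2)
  between slices.

Inference is hard EM with iterated-conditional-modes label updates; the
tracked objective (the $\omega$-marginalized log joint) is provably
non-decreasing. See the methods vignette
(`vignettes/spotweave-methods.Rmd`) for the update equations, the
initialization conventions, and the simulator design.

## Worked example

Simulate the default two-slice reference study (two 40 x 40 lattices,
p = 200 genes, d = 10 factors, q = 5 domains, Potts smoothness 1.5,
moderate batch effects), fit, and score against the ground truth:

```r
library(spotweave)

sim <- simulate_dataset(sim_config(), seed = 1)
ds  <- center_genes(sim$dataset)
g   <- build_graph(ds)
fit <- fit_em(ds, g, st_hyper(q = 5, d = 10, eta = 1.5),
              seed = 1, max_iter = 60)
fit
#> <st_fit> 3200 spots, d = 10, q = 5; 60 iterations (not converged)
#>   final objective -431103.66

glance(fit)
#> # A tibble: 1 x 8
#>       n     p     d     q n_iter converged objective prop_selected
#>   <int> <int> <int> <int>  <int> <lgl>         <dbl>         <dbl>
#> 1  3200   200    10     5     60 FALSE      -431104.         0.536

tidy(fit)
#> # A tibble: 3,200 x 5
#>   barcode batch      x     y domain
#>   <chr>   <chr>  <dbl> <dbl> <fct>
#> 1 s1_1    slice1     1     1 5
#> 2 s1_2    slice1     1     2 5
#> # ...

evaluate_fit(fit, sim$truth$labels)
#> # A tibble: 1 x 6
#>     ari   nmi batch_lisi_median batch_lisi_mean domain_lisi_median
#>   <dbl> <dbl>             <dbl>           <dbl>              <dbl>
#> 1 0.981 0.967              1.85            1.79               1.00
```

Reading the numbers: ARI 0.981 / NMI 0.967 mean the recovered domains agree
almost perfectly with the simulated truth; a median batch-LISI of 1.85 (out
of a maximum of 2 for two slices) says that around a typical spot the two
slices are nearly perfectly interleaved in the corrected embedding, while a
median domain-LISI of 1.00 says each neighbourhood is purely one domain —
batch mixing without blurring the domain structure. `autoplot(fit)` draws
the domain maps per slice; `autoplot(fit, "objective")` the objective trace;
`tidy(fit, embedding = TRUE)` appends the per-spot embedding columns.

Real data enter through `load_slice()` (10x MTX triplets or dense CSV, plus
`barcode,x,y` or 10x tissue-positions coordinates), then
`normalize_log()` |> `assemble_dataset()` |> `select_hvgs()` /
`filter_genes()` |> `center_genes()` |> `fit_em()`.

## Command line

```sh
inst/exec/spotweave simulate -c sim.yaml    # write a dataset bundle + truth
inst/exec/spotweave run -c run.yaml         # load -> graph -> fit -> CSVs
inst/exec/spotweave evaluate --run out/ --labels truth/labels.csv
```

Configs are flat YAML; `cmd_run()`, `cmd_simulate()` and `cmd_evaluate()`
are the same entry points as R functions. Every run writes a
`manifest.json` with the config, seed, and objective summary.

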