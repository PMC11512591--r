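---
title: "Joint integration, dimension reduction and spatial clustering of multi-slice spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint integration, dimension reduction and spatial clustering of multi-slice spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatial transcriptomics assays (ST, 10x Visium, Slide-seqV2) measure a gene
expression profile at every spot of a tissue section together with the spot's
2-D position. A single section captures limited biological variation, so
studies routinely profile several sections — replicate slices, adjacent
slices, or slices from different donors. Slices carry non-negligible batch
effects, and running batch correction, dimension reduction, and spatial
clustering as separate pipeline stages lets technical artifacts leak into the
biology and vice versa. spotweave fits all three jointly in one hierarchical
model and returns batch-corrected low-dimensional embeddings together with
spatially coherent domain labels that are aligned across slices.

## The model

Let $y_{bi} \in \mathbb{R}^p$ be the centered log-normalized expression of
spot $i$ in slice (batch) $b$, $b = 1, \dots, B$, $i = 1, \dots, n_b$.

**Observation layer (factor analysis with location-and-scale batch
adjustment).**
$$y_{bi} = L f_{bi} + \gamma_b + \varepsilon_{bi}, \qquad
\varepsilon_{bi} \sim N_p(0, T_b^{-1}),$$
where $L \in \mathbb{R}^{p \times d}$ is a sparse loading matrix shared by
all slices, $f_{bi} \in \mathbb{R}^d$ the spot's latent factor score,
$\gamma_b \in \mathbb{R}^p$ an additive (mean-shift) batch effect and $T_b$ a
diagonal matrix of per-gene noise precisions, the multiplicative
(scale) batch effect. The batch-free expression is $x_{bi} = L f_{bi}$.

**Factor layer (Student-t mixture over spatial domains).** Given the spot's
domain label $c_{bi} = k$ and a per-spot precision multiplier $\omega_{bi}$,
$$f_{bi} \mid c_{bi} = k, \omega_{bi} \sim
  N_d\!\left(\mu_k, \omega_{bi}^{-1} \Lambda^{-1}\right), \qquad
\omega_{bi} \sim \mathrm{Gamma}(\nu_\omega/2,\ \nu_\omega/2).$$
Integrating $\omega_{bi}$ out gives a multivariate Student-t with
$\nu_\omega$ degrees of freedom — heavy tails that make the clustering
robust to outlying spots.

**Label layer (Potts prior on a combined graph).** Labels live on an
undirected graph over all spots of all slices: within a slice, spots are
joined to their spatial K nearest neighbours (K = 4 for cartesian ST arrays,
K = 6 for hexagonal Visium arrays) or to all spots within a fixed radius
(r = 50 for Slide-seqV2 beads); across slices, spots are joined when they
are mutual nearest neighbours (depth 2) in a joint 50-component PCA of the
pair's expression. The label prior is the Potts model
$$P(c) \propto \exp\Bigl(\textstyle\sum_b \sum_i \eta_b
  \sum_{j \sim i} 1(c_i = c_j)\Bigr),$$
written per spot, so each concordant edge contributes from both endpoints
($2\eta_b$ within a slice; $\eta_a + \eta_b$ across slices). The normalizing
constant is never needed because $\eta$ is fixed.

**Priors.** $\gamma_b \sim N_p(0, I)$; $t_{bj} \sim
\mathrm{Gamma}(\nu_t/2, \nu_t/2)$ with $\nu_t = 1$; $\mu_k \sim N_d(0, 100
I)$ (zero mean is appropriate because genes are centered);
$\Lambda \sim \mathrm{Wishart}_d(n_\Lambda = d, 100 I)$, the least
informative choice satisfying $n_\Lambda > d - 1$; and each loading entry
carries a spike-and-slab prior whose slab is the nonlocal product-moment
(pMOM) density
$$L_{jk} \mid s_{jk} \sim (1 - s_{jk})\, N(0, \lambda_0) +
  s_{jk}\, \frac{L_{jk}^2}{\lambda_1} N(0, \lambda_1),$$
with $s_{jk} \sim \mathrm{Bern}(p_k)$ and $p_k \sim \mathrm{Beta}(1, 1)$.
The pMOM slab vanishes at zero, so entries that are selected are pushed away
from zero — a sharper separation between signal and noise loadings than a
plain Gaussian slab. The variances are fixed at $\lambda_0 = 0.015$ and
$\lambda_1 = 0.871$.

### Tunable parameters

| parameter | meaning | default |
|---|---|---|
| `q` | number of spatial domains | user-supplied (required) |
| `d` | latent dimension | 15 |
| `eta` | Potts smoothness per batch (0 = no smoothing) | 1 |
| `k_intra` | spatial KNN depth | 4 (ST) / 6 (Visium) |
| `radius` | spatial radius for bead platforms | 50 |
| `k_mnn` | cross-slice MNN depth | 2 |
| `lambda0`, `lambda1` | spike / slab variances | 0.015 / 0.871 |
| `nu_omega` | Student-t degrees of freedom | 2 |
| `nu_t` | noise-precision prior shape | 1 |
| `n_hvg` | highly variable genes kept | 2000 |

`q` and `d` are deliberately not chosen automatically; model selection is out
of scope.

## Inference

spotweave uses hard (point-value) EM with iterated conditional modes (ICM)
for the labels. Per iteration, in order:

1. **Factor scores**: $f_{bi} \leftarrow (\omega_{bi}\Lambda +
   L^\top T_b L)^{-1} (L^\top T_b (y_{bi} - \gamma_b) +
   \omega_{bi}\Lambda\mu_{c_{bi}})$, solved for all spots of a batch at once
   through a generalized eigendecomposition shared by the batch.
2. **Precision multipliers**: the conjugate posterior mean
   $\omega_{bi} \leftarrow (\nu_\omega + d) / (\nu_\omega + \delta^2_{bi})$
   with $\delta^2_{bi} = (f_{bi} - \mu_k)^\top \Lambda (f_{bi} - \mu_k)$.
3. **Labels**: ICM sweeps in global-index order;
   each spot takes the domain maximizing its Gaussian log-density plus the
   Potts bonus of concordant neighbours; ties break to the smaller index.
4. **Loadings**: coordinate ascent per entry. The spike stationary point is
   $b/(a + 1/\lambda_0)$ and the slab stationary point solves
   $l^2(a + 1/\lambda_1) - b l - 2 = 0$, where $a$ and $b$ are the
   coordinate's quadratic and linear likelihood statistics; among
   {current value, spike root, slab root} the entry keeps the argmax of the
   penalized objective, so the step can never decrease it. Inclusion
   probabilities come from the marginalized evidences of the two mixture
   components; slab probabilities from the Beta-posterior formula.
5. **Batch effects**: $\gamma_{bj} \leftarrow t_{bj}\sum_i r_{bij} /
   (1 + n_b t_{bj})$ (posterior mode under the $N(0,1)$ prior), then
   $t_{bj} \leftarrow (\nu_t + n_b - 2)/(\nu_t + \mathrm{SSR}_{bj})$, the
   mode of the Gamma full conditional, floored at $10^{-6}$.
6. **Ridge recentering**: the likelihood is exactly invariant under
   $f_{bi} \mathrel{+}= \delta_b$, $\gamma_b \mathrel{-}= L\delta_b$, so
   plain EM crawls along this direction at a rate set by the
   prior-to-likelihood curvature ratio (hundreds of iterations). A
   parameter-expansion move sets $\delta_b$ to the closed-form maximizer of
   the remaining quadratic terms (factor prior + $\gamma$ prior). This is
   exact coordinate ascent, so monotonicity is untouched, and it makes the
   additive effects converge in a handful of iterations.
7. **Cluster parameters**: Gaussian posterior mean for each $\mu_k$
   ($\omega$-weighted), Wishart posterior mode for $\Lambda$. Empty clusters
   keep their previous mean rather than being reseeded.

**The tracked objective.** The trace reported in `objective_trace` is the
log joint with $\omega$ integrated out analytically (the factor layer in its
Student-t form). The reason is statistical rather than cosmetic: the
$\omega$ update is a posterior *mean*, not a mode, so the point-evaluated
complete-data joint is not a coordinate-ascent objective for it. With
$\omega$ marginalized, every step above either maximizes the
$\omega$-expected complete-data objective or leaves the marginal unchanged,
and the standard EM inequality guarantees the trace never decreases —
a property the test suite verifies on dozens of randomized fits. The
point-evaluated joint (`log_joint()`) is still exposed and is the objective
each individual update is verified against.

**Initialization** is deterministic given a seed: PCA (SVD) of the pooled
centered expression for $L$ and $f$, in the unit-variance factor convention
($f = \sqrt{n}\,U$, $L = V D / \sqrt{n}$, where $Y \approx U D V^\top$) —
scores carry unit scale and loadings carry the magnitudes. The convention
matters because the scale direction $L \to L s$, $f \to f/s$ is
likelihood-invariant and EM barely moves along it: started from orthonormal
loadings, the fit stays in a gauge where every entry looks like spike noise
and the pMOM selection layer never activates. k-means for the initial
labels; batch
moments of the PCA residuals for $\gamma$ and $T$; empirical cluster moments
for $\mu$ and $\Lambda$; $\omega = 1$. Two robustness details matter with
heavy-tailed ($\nu_\omega = 2$) factors. First, k-means is run on
per-column 2%/98%-winsorized scores: raw k-means on infinite-variance data
spends clusters on single outliers (in pilot runs two of five clusters
started empty, and empty clusters are never reseeded). Second, the initial
$\Lambda$ uses the winsorized within-cluster scatter: the raw scatter is
outlier-dominated and would start $\Lambda$ orders of magnitude too small,
near a spurious low-precision fixed point of the EM map that the iteration
does not escape. Winsorization affects only the starting point, never the
model updates.

## The simulator and what it emulates

`simulate_dataset()` draws from the generative model itself: Potts labels on
rectangular lattices (sequential Gibbs, supercritical smoothness), Gamma
precisions, Gaussian-given-$\omega$ factor scores, sparse loadings with slab
entries drawn exactly from the pMOM density by rejection from
$N(0, 3\lambda_1)$ (ratio bound $3\sqrt{3}/e$), additive effects recentred
to spot-weighted contrasts (so $\sum_b n_b \gamma_b = 0$ — the component
that remains identifiable once genes are centered), and log-normal spreads
around per-batch noise-precision scales. It emits continuous expression on
the normalized scale, not counts; count-level noise and zero inflation are
out of scope, so conclusions from simulations speak to the model layers
above preprocessing, not to preprocessing itself.

The default scenario — two 40 x 40 slices, $p = 200$ genes, $d = 10$
factors, $q = 5$ domains, $\eta = 1.5$, $\nu_\omega = 2$, moderate batch
effects — is designed as a realistic, fully identifiable reference study:

* **Potts burn-in of 30 sweeps.** At $\eta = 1.5$ the chain is above the
  ordering transition and long runs coarsen a 40 x 40 field until a domain
  almost vanishes from a slice. Thirty sweeps give strongly coherent fields
  (neighbour concordance about 0.9) in which every domain still occupies a
  meaningful share of every slice — as with cortical layers, which appear in
  every section of a multi-slice study. Balanced composition also matters
  statistically: the additive effect $\gamma_b$ is informed by same-domain
  spots across batches, and a domain observed in only one slice contributes
  nothing to that contrast.
* **Loading density 0.1.** Each gene loads on one factor on average and each
  factor on about twenty genes — the standard working regime of sparse
  factor analysis, matching the view of factors as gene programs with
  specific membership.
* **Moderate batch preset: `gamma_sd = 1`, noise-precision scales (3, 6).**
  An additive effect worth modelling is one that visibly separates batches
  in an uncorrected embedding, as donor effects do in real multi-donor
  cortex data; `gamma_sd = 1` achieves that while remaining smaller than the
  between-domain expression differences. The two-fold precision ratio gives
  the slices genuinely different noise floors.
* **Cluster means $\mu_k \sim N(0, 4 I_d)$, $\Lambda = I$.** Pairwise
  cluster separation of a few within-cluster standard deviations — clusters
  that overlap in single dimensions but are separable in $\mathbb{R}^{10}$.

Because $\nu_\omega = 2$ implies infinite factor variance,
covariance-based distributional checks use $\nu_\omega = 30$; inference
tests keep the default 2.

What the simulator does *not* emulate: count noise, library-size variation,
spatially smooth continuous gradients (domains are piecewise constant),
curved or torn tissue geometries, and partial spatial overlap between
slices. Passing recovery tests on these simulations therefore demonstrates
correctness of the estimator under its own model assumptions, not robustness
to real-data violations of them.

## Numerical choices

* SPD factorizations go through a Cholesky with escalating diagonal jitter
  (starting at $10^{-8}$); a failure after six escalations is an error.
* Noise precisions are clipped to $[10^{-4}, 10^4]$ at initialization and
  floored at $10^{-6}$ in the M-step.
* KNN ties break to the lower spot index; the radius rule is strict (`<`);
  ICM ties break to the smaller domain index; all sweeps run in global-index
  order. These conventions make every fit bit-reproducible given a seed.
* Convergence is declared when the relative change of the tracked objective
  falls below `tol` (default $10^{-5}$); the default iteration cap is 30.
* The slab root at $b = 0$ is taken as $+\sqrt{2/(a + 1/\lambda_1)}$ (the
  two stationary points are symmetric; the positive one is chosen for
  determinism).

## Problem sizes used by the test suite

The suite exercises the full default scenario (two 40 x 40 slices, three
replicate seeds) for parameter recovery and batch mixing, 50 smaller
two-slice instances ($p = 50$, $d = 5$, $q = 3$, 20 x 20 lattices) for
objective monotonicity, 20 000-sample draws for distributional checks, and
brute-force-verifiable instances (up to 100 spots) for the graph builders.
These sizes were chosen so each property is measured with comfortable
statistical resolution while a complete check remains an everyday,
laptop-scale run.

## Known limitations

* Linear dimension reduction: strongly non-linear manifolds lose structure
  that an autoencoder-style embedding could retain.
* Hard EM underestimates posterior uncertainty; no posterior samples or
  credible intervals are produced.
* $q$ and $d$ must be supplied; there is no automatic model selection.
* The additive effect is identified only as a contrast between batches
  (after gene centering), and under very heavy factor tails a small
  span($L$) component of it is inherently confounded with batch-level
  fluctuations of the factor means; the reported `gamma` should be read as
  the identifiable contrast.
* ICM finds a local optimum of the label field; with very large `eta` it can
  over-smooth fine structures.
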