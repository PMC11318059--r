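# treebn

Signed gene regulatory network inference, with per-edge time delays, from
tree-shaped (cell-lineage) Boolean gene expression data.

## Who this is for, and what problem it solves

Time-lapse confocal microscopy of *C. elegans* embryos yields per-cell
fluorescence series for one labelled gene per embryo, sampled every
1.5 minutes and laid out on the invariant cell lineage.  Each founder-cell
subtree (AB, C, D, E, MS) can be analysed on its own — but the raw files
are *non-pairwise*: the same cell lives for different numbers of samples in
different embryos, so series from different genes cannot be aligned on
absolute time.  `treebn` is for computational biologists who want to turn
such recordings into a directed, signed, delay-annotated gene regulatory
network, and for methodologists who want a fully testable Boolean-network
inference stack with a simulator and recovery metrics.

## The model

Boolean states `s_i(t) ∈ {0, 1}` (1 = high expression *rate*) evolve on the
lineage tree.  A network is a signed adjacency `A` (`a_ij ∈ {−1, 0, 1}`,
zero diagonal) plus delays `Δ` (`δ_ij ∈ {0, …, 5}` interpolation units).
With input signal `H_i(t) = Σ_j a_ij s_j(t − δ_ij)` (lags resolved through
cell divisions: daughters read their mother's history),

* `H = 0`:  `P(s_i(t) = s_i(t − Δt)) = 1 / (1 + e^{−α})` (persistence),
* `H ≠ 0`:  `P(s_i(t) | ·) = exp[β (2 s_i(t) − 1) H] / (e^{βH} + e^{−βH})`
  (Boltzmann response; `β` is an inverse temperature).

Priors: per-row spike (mass `κ` on the empty row) + truncated-exponential
in-degree (`λ`) spread uniformly over regulator sets and signs; uniform
delays on present edges and a spike-and-slab on absent ones; hyperpriors
`α ~ Γ(1,10)`, `β ~ Γ(100,100)`, `λ ~ Γ(490,70)`, `κ ~ Beta(6,24)`
(shape–rate).  Inference is Gibbs sampling of each `(a_ij, δ_ij)` pair from
its 18-state conditional, a posterior-invariant edge-swap move per row, and
Metropolis–Hastings for `(α, β, λ, κ)`, after a Fisher-exact pre-screen
over lags 0–5 removes ~70% of candidate edges without losing true ones.
The point estimate is the joint-argmax MAP over post-burn-in samples.

## Worked example

Simulate a ground-truth network at the D-subtree dimensions (20 genes, 12
cells, 28 interpolations per cell), screen, fit and score:

```r
library(treebn)

truth <- draw_truth(20, seed = 42)        # network + (alpha, beta, lambda, kappa)
ds    <- simulate_dataset(truth, make_table1_config("D"), seed = 43)
ds
#> <subtree_dataset>
#>   subtree: D
#>   genes:   20
#>   cells:   12 (1 root)
#>   points:  336 (331 usable for likelihood)
#>   missing: 0 (0.00%)

mask <- run_prescreen(ds)                 # Fisher-exact screen, theta = 0.05
mask
#> <prescreen_mask> theta = 0.05: 124 of 380 candidate edges retained (PR = 0.674)

fit <- run_mcmc(ds, mask, n_iter = 800, n_chains = 3, seed = 44)
est <- map_estimate(fit)
est
#> <bn_map> MAP estimate
#> <grn> 20 genes, 18 edges (12 activating, 6 repressing)
#>   alpha = 0.050, beta = 1.024, lambda = 7.061, kappa = 0.155
#>   log posterior -3728.39 (chain 3, iteration 598)

network_metrics(est$net, truth$net)
#> # A tibble: 1 × 4
#>     TPR   PPR   TNR   PNR
#>   <dbl> <dbl> <dbl> <dbl>
#> 1     1     1     1     1

delay_accuracy(A_hat = est$net, truth_delta = truth$net)
#> [1] 1

head(tidy(est$net), 4)
#> # A tibble: 4 × 4
#>   regulator target  sign delay_units
#>   <chr>     <chr>  <int>       <int>
#> 1 g8        g1         1           1
#> 2 g14       g10        1           5
#> 3 g2        g11        1           2
#> 4 g18       g12       -1           3
```

On this replicate the screen eliminates 67% of candidate edges, and the MAP
network recovers every activating and repressing edge with its exact delay.
Across prior-drawn replicates the recovery rates average a few percent
lower (see the vignette); `autoplot(fit)` shows the per-chain log-posterior
plateau, and `tidy(fit)` gives per-edge posterior sign probabilities.

Real per-embryo recordings enter through `read_embryo_file()` and the
four-step `integrate_subtree()` (lifetime normalisation, rate differencing
with FMM-spline interpolation, median binarisation, majority merging of
gene copies), which produces the same `subtree_dataset` container.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/treebn.R simulate --subtree D --seed 1 --out out/
Rscript inst/cli/treebn.R infer --dataset out/dataset --chains 3 --iters 2000 --out out/
```

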