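#' Joint-distribution ("getting it right") check of the sampler
#'
#' Compares two ways of sampling the joint distribution of (parameters,
#' data): the marginal-conditional route (draw parameters and a network
#' from the priors) and the successive-conditional route (alternate
#' simulating a dataset from the current parameters with one full MCMC
#' iteration -- a Gibbs sweep over all edges plus one M-H update per
#' continuous parameter).  If the sampler targets the stated posterior,
#' both routes have identical parameter marginals, so the z-scores of the
#' mean differences on summary statistics (network density, mean delay,
#' `alpha`, `beta`, `lambda`, `kappa`) should be small; gross sampler bugs
#' produce |z| far above 4.  The successive chain's autocorrelation is
#' handled with batch-means standard errors.
#'
#' @param n_genes,n_cells,inters Dimensions of the toy model (small, so
#'   the check is sharp and fast).
#' @param n_marginal Independent prior draws.
#' @param n_cycles Successive-conditional cycles.
#' @param n_batches Batches for the successive-side standard error.
#' @param seed Master seed.
#' @return A tibble with one row per statistic: both means, both standard
#'   errors and the z-score.
#' @export
geweke_check <- function(n_genes = 4L, n_cells = 2L, inters = 8L,
                         n_marginal = 5000L, n_cycles = 5000L,
                         n_batches = 50L, seed = 1L) {
  config <- sim_config(n_genes, n_cells, inters)
  off <- which(row(diag(n_genes)) != col(diag(n_genes)))
  stat_fun <- function(A, delta, alpha, beta, lambda, kappa) {
    c(density = mean(A[off] != 0), delay = mean(delta[off]),
      alpha = alpha, beta = beta, lambda = lambda, kappa = kappa)
  }

  set.seed(derive_seed(seed, "geweke-marginal"))
  marg <- vapply(seq_len(n_marginal), function(r) {
    tr <- draw_truth(n_genes)
    stat_fun(tr$net$A, tr$net$delta, tr$alpha, tr$beta, tr$lambda, tr$kappa)
  }, numeric(6))

  set.seed(derive_seed(seed, "geweke-successive"))
  tr <- draw_truth(n_genes)
  st0 <- list(A = tr$net$A, delta = tr$net$delta,
              x = as.integer(rowSums(tr$net$A != 0)),
              alpha = tr$alpha, beta = tr$beta,
              lambda = tr$lambda, kappa = tr$kappa)
  edges <- mask_edges(NULL, n_genes)
  row_pos <- split(edges[, 2L], edges[, 1L])
  scales <- mh_scales(0.2)
  succ <- matrix(NA_real_, 6, n_cycles)
  st <- st0
  for (cy in seq_len(n_cycles)) {
    ds <- simulate_dataset(list(net = grn(st$A, st$delta), alpha = st$alpha,
                                beta = st$beta), config)
    ctx <- prep_ctx(ds, n_genes)
    st$H <- input_matrix(st$A, st$delta, ctx$LS)
    ftab <- build_ftab(ctx$N, st$alpha, st$beta)
    st <- sweep_internal(ctx, st, edges, ftab)
    st <- swap_sweep(ctx, st, row_pos, ftab)
    for (p in names(scales)) {
      st <- mh_internal(ctx, st, p, scales[[p]])$state
    }
    succ[, cy] <- stat_fun(st$A, st$delta, st$alpha, st$beta, st$lambda,
                           st$kappa)
  }

  se_batch <- function(v, B) {
    bm <- vapply(split(v, cut(seq_along(v), B, labels = FALSE)), mean,
                 numeric(1))
    stats::sd(bm) / sqrt(B)
  }
  nm <- rownames(marg) <- rownames(succ) <-
    c("density", "delay", "alpha", "beta", "lambda", "kappa")
  tibble(
    statistic = nm,
    marginal_mean = rowMeans(marg),
    marginal_se = apply(marg, 1, stats::sd) / sqrt(n_marginal),
    successive_mean = rowMeans(succ),
    successive_se = apply(succ, 1, se_batch, B = n_batches),
    z = (rowMeans(marg) - rowMeans(succ)) /
      sqrt((apply(marg, 1, stats::sd) / sqrt(n_marginal))^2 +
             apply(succ, 1, se_batch, B = n_batches)^2)
  )
}
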