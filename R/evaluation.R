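#' Pre-screening performance indices
#'
#' The pre-screening rate PR is the fraction of candidate (off-diagonal)
#' edges eliminated; the false negative rate FNR is the fraction of
#' ground-truth edges (either sign) that were eliminated.  A good screen
#' has a high PR at FNR = 0.
#'
#' @param tilde_A Retention indicator matrix (a `prescreen_mask` or its
#'   `tilde_A`): 1 retained, 0 eliminated.
#' @param truth_A Ground-truth signed adjacency matrix (or a [grn]).
#' @return A tibble with columns `PR` and `FNR` (`FNR` is `NA` when the
#'   truth has no edges).
#' @export
prescreen_metrics <- function(tilde_A, truth_A) {
  if (inherits(tilde_A, "prescreen_mask")) tilde_A <- tilde_A$tilde_A
  if (inherits(truth_A, "grn")) truth_A <- truth_A$A
  off <- which(row(tilde_A) != col(tilde_A))
  elim <- tilde_A[off] == 0
  true_edge <- truth_A[off] != 0
  tibble(
    PR = mean(elim),
    FNR = if (sum(true_edge) == 0) NA_real_ else
      sum(elim & true_edge) / sum(true_edge)
  )
}

#' Signed-edge recovery indices of an estimated network
#'
#' Computed over off-diagonal entries: TPR is the fraction of true
#' activating edges recovered as activating, PPR the fraction of predicted
#' activating edges that are truly activating, and TNR / PNR the same pair
#' for repressing edges.  Ratios with an empty denominator (e.g. a truth
#' with no repressing edge) are `NA`.
#'
#' @param A_hat Estimated signed adjacency (or a [grn]).
#' @param truth_A Ground-truth signed adjacency (or a [grn]).
#' @return A tibble with columns `TPR`, `PPR`, `TNR`, `PNR`.
#' @export
network_metrics <- function(A_hat, truth_A) {
  if (inherits(A_hat, "grn")) A_hat <- A_hat$A
  if (inherits(truth_A, "grn")) truth_A <- truth_A$A
  off <- which(row(A_hat) != col(A_hat))
  h <- A_hat[off]; a <- truth_A[off]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    TPR = ratio(sum(h == 1 & a == 1), sum(a == 1)),
    PPR = ratio(sum(h == 1 & a == 1), sum(h == 1)),
    TNR = ratio(sum(h == -1 & a == -1), sum(a == -1)),
    PNR = ratio(sum(h == -1 & a == -1), sum(h == -1))
  )
}

#' Delay estimation accuracy on predicted edges
#'
#' Among predicted (nonzero) edges, the fraction whose estimated delay
#' equals the ground-truth delay; `NA` when no edge is predicted.
#'
#' @param delta_hat Estimated delay matrix.
#' @param A_hat Estimated signed adjacency (or a [grn], in which case its
#'   delays are used and `delta_hat` may be missing).
#' @param truth_delta Ground-truth delay matrix (or a [grn]).
#' @return A single numeric value `ACC`.
#' @export
delay_accuracy <- function(delta_hat, A_hat, truth_delta) {
  if (inherits(A_hat, "grn")) {
    if (missing(delta_hat) || is.null(delta_hat)) delta_hat <- A_hat$delta
    A_hat <- A_hat$A
  }
  if (inherits(truth_delta, "grn")) truth_delta <- truth_delta$delta
  off <- which(row(A_hat) != col(A_hat))
  pred <- A_hat[off] != 0
  if (sum(pred) == 0) return(NA_real_)
  sum(pred & delta_hat[off] == truth_delta[off]) / sum(pred)
}

#' Replicated simulation study
#'
#' For each replicate: draw a ground-truth network and parameters from the
#' priors, simulate a subtree dataset of the configured dimensions, run
#' pre-screening, optionally run the MCMC and take the MAP network, and
#' score everything against the truth.  Replicates are independently
#' seeded from the master seed, so any one can be rerun alone.  Undefined
#' ratios (`NA`) are dropped from the replicate means.
#'
#' @param subtree Subtree label whose real-data dimensions to mirror
#'   (ignored when `config` is given).
#' @param n_replicates Number of replicates.
#' @param config A [sim_config()]; defaults to `make_table1_config(subtree)`.
#' @param theta Pre-screening threshold (see [run_prescreen()]).
#' @param prescreen_only If `TRUE`, skip the MCMC and report only PR/FNR.
#' @param n_iter,n_chains MCMC size per replicate.
#' @param seed Master seed.
#' @return An `eval_report`: list with `replicates` (per-replicate
#'   tibble) and `summary` (one-row tibble of `NA`-dropped means).
#' @export
replicate_study <- function(subtree = "D", n_replicates = 5L,
                            config = make_table1_config(subtree),
                            theta = formals(run_prescreen)$theta,
                            prescreen_only = FALSE,
                            n_iter = 800L, n_chains = 3L, seed = 1L) {
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    rseed <- derive_seed(seed, "replicate", r)
    set.seed(rseed)
    truth <- draw_truth(config$n_genes)
    ds <- simulate_dataset(truth, config)
    mask <- run_prescreen(ds, theta = theta)
    row <- dplyr::bind_cols(
      tibble(replicate = r, seed = rseed,
             n_true_edges = sum(truth$net$A != 0)),
      prescreen_metrics(mask, truth$net)
    )
    if (!prescreen_only) {
      fit <- run_mcmc(ds, mask, n_iter = n_iter, n_chains = n_chains,
                      seed = rseed)
      est <- map_estimate(fit)
      row <- dplyr::bind_cols(
        row, network_metrics(est$net, truth$net),
        tibble(ACC = delay_accuracy(A_hat = est$net,
                                    truth_delta = truth$net),
               n_pred_edges = sum(est$net$A != 0))
      )
    }
    row
  })
  replicates <- bind_rows(reps)
  metric_cols <- intersect(c("PR", "FNR", "TPR", "PPR", "TNR", "PNR", "ACC"),
                           names(replicates))
  summary <- dplyr::summarise(replicates, dplyr::across(
    dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)))
  structure(list(replicates = replicates, summary = summary,
                 subtree = config$subtree, config = config, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d replicate%s of the %s configuration\n",
              nrow(x$replicates),
              if (nrow(x$replicates) == 1) "" else "s",
              if (is.na(x$subtree)) "custom" else x$subtree))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}
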