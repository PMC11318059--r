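#' Tidy a network into an edge tibble
#'
#' @param x A [grn].
#' @param ... Unused.
#' @return One row per nonzero edge: `regulator`, `target`, `sign`,
#'   `delay_units`.
#' @export
tidy.grn <- function(x, ...) as_edges(x)

#' @export
glance.grn <- function(x, ...) {
  tibble(n_genes = nrow(x$A), n_edges = sum(x$A != 0),
         n_activating = sum(x$A == 1), n_repressing = sum(x$A == -1))
}

#' Tidy MCMC output
#'
#' `tidy()` returns post-burn-in posterior summaries: per retained edge,
#' the posterior probability of each sign and the modal `(sign, delay)`;
#' per continuous parameter, posterior mean and quantiles.  `glance()`
#' gives one row of chain-level diagnostics.
#'
#' @param x A `bn_mcmc` from [run_mcmc()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bn_mcmc <- function(x, ...) {
  n <- x$n_iter
  keep <- seq.int(floor(n / 2) + 1L, n)
  a_all <- do.call(rbind, lapply(x$chains, function(ch) {
    ch$a[keep, , drop = FALSE]
  }))
  d_all <- do.call(rbind, lapply(x$chains, function(ch) {
    ch$delta[keep, , drop = FALSE]
  }))
  E <- nrow(x$edges)
  if (E == 0) {
    return(tibble(target = character(), regulator = character(),
                  p_activate = numeric(), p_repress = numeric(),
                  p_edge = numeric(), mode_sign = integer(),
                  mode_delay = integer()))
  }
  mode_ad <- vapply(seq_len(E), function(e) {
    key <- paste(a_all[, e], d_all[, e])
    as.integer(strsplit(names(which.max(table(key))), " ")[[1]])
  }, integer(2))
  tibble(
    target = x$edges$target, regulator = x$edges$regulator,
    p_activate = colMeans(a_all == 1),
    p_repress = colMeans(a_all == -1),
    p_edge = colMeans(a_all != 0),
    mode_sign = mode_ad[1, ], mode_delay = mode_ad[2, ]
  )
}

#' @rdname tidy.bn_mcmc
#' @export
glance.bn_mcmc <- function(x, ...) {
  n <- x$n_iter
  keep <- seq.int(floor(n / 2) + 1L, n)
  pars <- do.call(rbind, lapply(x$chains, function(ch) {
    ch$pars[keep, , drop = FALSE]
  }))
  tibble(
    n_chains = length(x$chains), n_iter = n,
    n_retained_edges = nrow(x$edges),
    alpha = mean(pars[, "alpha"]), beta = mean(pars[, "beta"]),
    lambda = mean(pars[, "lambda"]), kappa = mean(pars[, "kappa"]),
    max_lp = max(pars[, "lp"])
  )
}

#' Long-format parameter traces
#'
#' @param x A `bn_mcmc`.
#' @param params Which traces to extract.
#' @return A tibble with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
mcmc_traces <- function(x, params = c("alpha", "beta", "lambda", "kappa",
                                      "lp")) {
  stopifnot(inherits(x, "bn_mcmc"))
  purrr::imap(x$chains, function(ch, idx) {
    as_tibble(ch$pars[, params, drop = FALSE]) |>
      mutate(chain = idx, iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                          values_to = "value")
  }) |> bind_rows()
}

#' @export
tidy.eval_report <- function(x, ...) x$replicates

#' @export
glance.eval_report <- function(x, ...) x$summary

#' Tidy a subtree dataset into long format
#'
#' @param x A [subtree_dataset].
#' @param ... Unused.
#' @return A tibble with one row per (gene, point): `gene`, `point`,
#'   `cell`, `k`, `state`.
#' @export
tidy.subtree_dataset <- function(x, ...) {
  tibble(
    gene = rep(rownames(x$states), times = ncol(x$states)),
    point = rep(x$points$point, each = nrow(x$states)),
    cell = rep(x$points$cell, each = nrow(x$states)),
    k = rep(x$points$k, each = nrow(x$states)),
    state = as.integer(x$states)
  )
}
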