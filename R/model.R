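#' Hyperprior specification
#'
#' Shape--rate Gamma priors for the persistence strength `alpha`
#' (Gamma(1, 10), mean 0.1), the inverse-noise parameter `beta`
#' (Gamma(100, 100), mean 1, sd 0.1) and the sparsity decay `lambda`
#' (Gamma(490, 70), mean 7), and a Beta(6, 24) prior (mean 0.2) for the
#' empty-row mass `kappa`.  The tight priors on `beta` and `lambda` encode
#' that the network is sparse and the Boolean dynamics moderately noisy.
#'
#' @format A named list of `c(shape, rate)` / `c(shape1, shape2)` pairs.
#' @export
hyper_priors <- list(
  alpha  = c(shape = 1, rate = 10),
  beta   = c(shape = 100, rate = 100),
  lambda = c(shape = 490, rate = 70),
  kappa  = c(shape1 = 6, shape2 = 24)
)

#' Input signal received by a gene
#'
#' The summed, signed, delay-resolved input `H_i(t) = sum_j A[i, j] *
#' s_j(t - delta[i, j])`: each regulator contributes its state at the
#' edge-specific lag, weighted by the edge sign.
#'
#' @param a_row Signed adjacency row of the target gene (length `N`,
#'   diagonal entry 0).
#' @param delta_row Delay row (entries in `0:5`).
#' @param lagged `N x 6` matrix of regulator states; column `m + 1` holds
#'   every gene's state at lag `m`.
#' @return Integer in `[-x_i, x_i]` where `x_i` is the number of regulators.
#' @export
input_signal <- function(a_row, delta_row, lagged) {
  nz <- which(a_row != 0)
  if (length(nz) == 0) return(0L)
  as.integer(sum(a_row[nz] * lagged[cbind(nz, delta_row[nz] + 1L)]))
}

#' State persistence probability under zero input
#'
#' With no net input a gene keeps its previous state with probability
#' `1 / (1 + exp(-alpha))`; larger `alpha` means stronger persistence
#' (`alpha -> 0` gives a coin flip, `alpha -> Inf` a frozen state).
#'
#' @param alpha Positive persistence strength.
#' @return Probability in `(1/2, 1)`.
#' @export
persistence_prob <- function(alpha) {
  stopifnot(all(alpha > 0))
  plogis(alpha)
}

#' State transition probability under nonzero input
#'
#' `P(s | H) = exp(beta * (2s - 1) * H) / (exp(beta * H) + exp(-beta * H))`:
#' a Boltzmann-type response in which `beta` plays the role of an inverse
#' temperature -- small `beta` is a noisy system that barely feels its
#' input, large `beta` a nearly deterministic switch.
#'
#' @param s Target state, 0 or 1 (vectorised).
#' @param H Nonzero integer input signal (vectorised).
#' @param beta Nonnegative inverse-noise parameter.
#' @return Probability; `P(1 | H) + P(0 | H) = 1`.
#' @export
transition_prob <- function(s, H, beta) {
  v <- beta * (2 * s - 1) * H
  a <- abs(beta * H)
  exp(v - a - log1p(exp(-2 * a)))
}

#' Log prior of one adjacency row
#'
#' The sparsity prior over the `3^(N-1)` signed configurations of a row:
#' mass `kappa` on the empty row, and for a row with `x >= 1` regulators,
#' `(1 - kappa) * c(lambda) * exp(-lambda * x) / (choose(N-1, x) * 2^x)` --
#' a truncated-exponential prior on the in-degree spread uniformly over the
#' possible regulator sets and sign patterns.
#'
#' @param a_row Full signed row (its own diagonal entry 0); `N` is taken
#'   as `length(a_row)`.
#' @param lambda Positive sparsity decay.
#' @param kappa Empty-row mass in (0, 1).
#' @return Log prior mass of the row.
#' @export
log_prior_row <- function(a_row, lambda, kappa) {
  log_prior_row_x(sum(a_row != 0), length(a_row), lambda, kappa)
}

# same prior as a function of the in-degree x
log_prior_row_x <- function(x, N, lambda, kappa) {
  ifelse(x == 0, log(kappa),
         log1p(-kappa) + log_normalizing_c(lambda, N) - lambda * x -
           lchoose(N - 1, x) - x * log(2))
}

#' Normalising constant of the in-degree prior
#'
#' `c(lambda) = 1 / sum_{x=1}^{N-1} exp(-lambda * x)`, chosen so the row
#' prior sums to one over all signed configurations.
#'
#' @param lambda Positive sparsity decay.
#' @param N Number of genes (`N >= 2`).
#' @return The constant (`normalizing_c`) or its log (`log_normalizing_c`).
#' @export
normalizing_c <- function(lambda, N) exp(log_normalizing_c(lambda, N))

#' @rdname normalizing_c
#' @export
log_normalizing_c <- function(lambda, N) {
  stopifnot(N >= 2)
  # -log sum_{x=1}^{N-1} e^{-lambda x}, computed stably
  -(-lambda + log(sum(exp(-lambda * (1:(N - 1)) + lambda))))
}

#' Log prior of a delay entry
#'
#' Present edges (`a != 0`) carry a flat delay prior (1/6 on lags 0..5);
#' absent edges keep a dimension-preserving spike-and-slab delay with mass
#' 0.999 at lag 0 and 0.0002 on each of lags 1..5.
#'
#' @param delta Delay entries in `0:5` (vectorised).
#' @param a Matching signed adjacency entries (vectorised).
#' @return Log prior mass.
#' @export
log_prior_delay <- function(delta, a) {
  stopifnot(all(delta %in% 0:5))
  ifelse(a != 0, log(1 / 6),
         ifelse(delta == 0, log(0.999), log(2e-04)))
}

# Precomputed likelihood context: observed states, their lag-1 values and
# the six lag-resolved state matrices, all restricted to usable points.
# The likelihood requires complete data, so missing states are an error.
make_model_context <- function(ds, max_lag = 5L) {
  stopifnot(inherits(ds, "subtree_dataset"))
  if (anyNA(ds$states)) {
    abort("dataset contains missing states; run fill_missing() first.")
  }
  li <- lag_index(ds, max_lag)
  usable <- which(!is.na(li[, max_lag + 1L]))
  if (length(usable) == 0) abort("no usable points (history too short).")
  LS <- lapply(0:max_lag, function(m) {
    ds$states[, li[usable, m + 1L], drop = FALSE]
  })
  list(
    y = ds$states[, usable, drop = FALSE],
    yprev = ds$states[, li[usable, 2L], drop = FALSE],
    LS = LS, usable = usable,
    N = nrow(ds$states), Tu = length(usable),
    genes = rownames(ds$states)
  )
}

# N x Tu matrix of input signals for every gene at every usable point
input_matrix <- function(A, delta, LS) {
  H <- matrix(0, nrow(A), ncol(LS[[1]]))
  for (m in 0:5) {
    Am <- A * (delta == m)
    if (any(Am != 0)) H <- H + Am %*% LS[[m + 1L]]
  }
  H
}

# log-likelihood from the input matrix; `rows` restricts to a subset of
# target genes (the edge conditional needs only gene i's terms)
loglik_from_H <- function(H, y, yprev, alpha, beta, rows = NULL) {
  if (!is.null(rows)) {
    H <- H[rows, , drop = FALSE]
    y <- y[rows, , drop = FALSE]
    yprev <- yprev[rows, , drop = FALSE]
  }
  z <- H == 0
  p <- plogis(alpha)
  n_same <- sum(y[z] == yprev[z])
  n_zero <- sum(z)
  ll0 <- n_same * log(p) + (n_zero - n_same) * log1p(-p)
  if (n_zero < length(H)) {
    Hn <- H[!z]
    v <- beta * (2 * y[!z] - 1) * Hn
    a <- abs(beta * Hn)
    ll1 <- sum(v - a - log1p(exp(-2 * a)))
  } else ll1 <- 0
  ll0 + ll1
}

#' Log likelihood of a network on a subtree dataset
#'
#' The product, over every root segment, every point with a resolved 5-lag
#' history and every gene, of the persistence probability (zero input) or
#' the Boltzmann transition probability (nonzero input), conditioned on the
#' delay-lagged regulator states resolved along the lineage path (daughter
#' cells read their early lags from the parent's terminal points).
#'
#' @param ds A [subtree_dataset] without missing states.
#' @param net A [grn].
#' @param alpha,beta Model parameters.
#' @param context Optional precomputed context (internal use).
#' @return Log likelihood (finite for all valid inputs).
#' @export
log_likelihood <- function(ds, net, alpha, beta, context = NULL) {
  ctx <- context %||% make_model_context(ds)
  H <- input_matrix(net$A, net$delta, ctx$LS)
  loglik_from_H(H, ctx$y, ctx$yprev, alpha, beta)
}

#' Log posterior of the full parameter state
#'
#' Likelihood plus the row sparsity priors, the per-entry delay priors and
#' the [hyper_priors] densities of `alpha`, `beta`, `lambda`, `kappa`.
#'
#' @inheritParams log_likelihood
#' @param lambda,kappa Sparsity hyperparameters.
#' @return Log posterior density (unnormalised).
#' @export
log_posterior <- function(ds, net, alpha, beta, lambda, kappa,
                          context = NULL) {
  ll <- log_likelihood(ds, net, alpha, beta, context = context)
  ll + log_prior_network(net, lambda, kappa) +
    log_hyper_density(alpha, beta, lambda, kappa)
}

# joint prior of (A, delta) given hyperparameters
log_prior_network <- function(net, lambda, kappa) {
  N <- nrow(net$A)
  x <- rowSums(net$A != 0)
  off <- row(net$A) != col(net$A)
  sum(log_prior_row_x(x, N, lambda, kappa)) +
    sum(log_prior_delay(net$delta[off], net$A[off]))
}

log_hyper_density <- function(alpha, beta, lambda, kappa) {
  hp <- hyper_priors
  dgamma(alpha, hp$alpha[1], rate = hp$alpha[2], log = TRUE) +
    dgamma(beta, hp$beta[1], rate = hp$beta[2], log = TRUE) +
    dgamma(lambda, hp$lambda[1], rate = hp$lambda[2], log = TRUE) +
    dbeta(kappa, hp$kappa[1], hp$kappa[2], log = TRUE)
}
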