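#' MCMC for the delayed Boolean network posterior
#'
#' `run_mcmc()` draws from the joint posterior of the signed adjacency `A`,
#' the delay matrix `delta` and the continuous parameters `alpha`, `beta`,
#' `lambda`, `kappa` given a binary subtree dataset.  Each iteration is one
#' Gibbs sweep -- every retained edge `(i, j)` is redrawn jointly as an
#' `(a_ij, delta_ij)` pair from its 18-state full conditional -- followed by
#' one Metropolis--Hastings update of each continuous parameter (log-scale
#' random walks for `alpha`, `beta`, `lambda`; logit scale for `kappa`).
#' Edges eliminated by pre-screening stay fixed at zero.  Chains start from
#' the empty network with the continuous parameters at their prior means,
#' and are independently seeded via [derive_seed()].
#'
#' @param ds A [subtree_dataset] without missing values, or `NULL` to
#'   sample from the prior (flat likelihood), which is useful for sampler
#'   validation.
#' @param mask A `prescreen_mask` from [run_prescreen()], or `NULL` to
#'   retain every off-diagonal edge.  Required when `ds` is `NULL` (it
#'   fixes the number of genes).
#' @param n_iter Iterations per chain.
#' @param n_chains Number of independent chains (3 in the simulation
#'   studies, 5 for real-data runs).
#' @param seed Master seed.
#' @param proposal_scale Random-walk sd on the log/logit scale; scalar or
#'   named per-parameter vector.
#' @param adapt If `TRUE`, proposal scales are tuned toward 44% acceptance
#'   during the first (burn-in) half only, so the post-burn-in kernel is
#'   fixed.
#' @param sample_hyper If `FALSE`, `alpha`, `beta`, `lambda`, `kappa` are
#'   held at their initial values (Gibbs-only chain at fixed parameters).
#' @param swap_moves If `TRUE` (default), each iteration also attempts one
#'   Metropolised edge-swap per target gene, exchanging a present edge
#'   with a retained absent position of the same row.  The move is a
#'   symmetric involution (row and delay priors cancel), so it leaves the
#'   posterior invariant; it exists because correlated regulators make the
#'   single-edge conditionals multimodal -- once a proxy regulator
#'   occupies a row the true one is conditionally redundant, and only a
#'   joint exchange crosses between those modes.
#' @param init Optional named list overriding the initial `alpha`, `beta`,
#'   `lambda`, `kappa`.
#' @return A `bn_mcmc` object: per-chain traces of every retained edge's
#'   `(a, delta)`, the continuous parameters and the log posterior, plus
#'   the edge index, mask and configuration.
#' @export
run_mcmc <- function(ds, mask = NULL, n_iter = 2000L, n_chains = 3L,
                     seed = 1L, proposal_scale = 0.2, adapt = FALSE,
                     sample_hyper = TRUE, swap_moves = TRUE, init = NULL) {
  if (is.null(ds) && is.null(mask)) {
    abort("either `ds` or `mask` must be given.")
  }
  N <- if (!is.null(ds)) nrow(ds$states) else nrow(mask$tilde_A)
  ctx <- prep_ctx(ds, N)
  edges <- mask_edges(mask, N)
  scales <- mh_scales(proposal_scale)
  chains <- lapply(seq_len(n_chains), function(ch) {
    set.seed(derive_seed(seed, "chain", ch))
    run_one_chain(ctx, edges, n_iter, scales, adapt, sample_hyper,
                  swap_moves, init)
  })
  genes <- ctx$genes %||% paste0("g", seq_len(N))
  structure(list(
    chains = chains,
    edges = tibble(target = genes[edges[, 1L]],
                   regulator = genes[edges[, 2L]],
                   i = edges[, 1L], j = edges[, 2L]),
    genes = genes, n_genes = N, n_iter = as.integer(n_iter),
    seed = seed, mask = mask, sample_hyper = sample_hyper
  ), class = "bn_mcmc")
}

# retained edges as an E x 2 (i, j) matrix
mask_edges <- function(mask, N) {
  if (is.null(mask)) {
    keep <- which(matrix(TRUE, N, N) & row(diag(N)) != col(diag(N)),
                  arr.ind = TRUE)
  } else {
    stopifnot(nrow(mask$tilde_A) == N)
    keep <- which(mask$tilde_A == 1L, arr.ind = TRUE)
  }
  unname(keep)
}

mh_scales <- function(proposal_scale) {
  nm <- c("alpha", "beta", "lambda", "kappa")
  if (length(proposal_scale) == 1L && is.null(names(proposal_scale))) {
    return(setNames(rep(proposal_scale, 4), nm))
  }
  stopifnot(all(nm %in% names(proposal_scale)))
  proposal_scale[nm]
}

# Extended likelihood context: per-regulator 6 x Tu lag-state blocks and
# per-gene sufficient pieces used by the edge conditional.
prep_ctx <- function(ds, N) {
  if (is.null(ds)) {
    return(list(N = N, Tu = 0L, genes = NULL,
                y = matrix(0L, N, 0), yprev = matrix(0L, N, 0),
                LS = rep(list(matrix(0L, N, 0)), 6),
                LSrows = rep(list(matrix(0L, 6, 0)), N),
                same = matrix(0, N, 0), s2 = matrix(0, N, 0)))
  }
  ctx <- make_model_context(ds)
  ctx$LSrows <- lapply(seq_len(ctx$N), function(j) {
    do.call(rbind, lapply(ctx$LS, function(M) M[j, ]))
  })
  # static per-regulator key offsets into the likelihood lookup table:
  # Tu x 12 matrix, columns = (a = -1, lags 0..5; a = +1, lags 0..5)
  ctx$LSoff <- lapply(ctx$LSrows, function(M) t(rbind(-4 * M, 4 * M)))
  ctx$same <- (ctx$y == ctx$yprev) + 0
  ctx$s2 <- 2 * ctx$y - 1
  # per-point likelihood case code: 2 * state + persistence indicator
  ctx$enc <- 2 * ctx$y + ctx$same
  ctx$enc_rows <- lapply(seq_len(ctx$N), function(i) ctx$enc[i, ])
  ctx
}

new_chain_state <- function(ctx, init = NULL) {
  hp <- hyper_priors
  st <- list(
    A = matrix(0L, ctx$N, ctx$N),
    delta = matrix(0L, ctx$N, ctx$N),
    x = integer(ctx$N),
    H = matrix(0, ctx$N, ctx$Tu),
    alpha = hp$alpha[[1]] / hp$alpha[[2]],
    beta = hp$beta[[1]] / hp$beta[[2]],
    lambda = hp$lambda[[1]] / hp$lambda[[2]],
    kappa = hp$kappa[[1]] / (hp$kappa[[1]] + hp$kappa[[2]])
  )
  for (p in intersect(names(init), c("alpha", "beta", "lambda", "kappa"))) {
    st[[p]] <- init[[p]]
  }
  st
}

run_one_chain <- function(ctx, edges, n_iter, scales, adapt, sample_hyper,
                          swap_moves, init) {
  st <- new_chain_state(ctx, init)
  E <- nrow(edges)
  row_pos <- if (swap_moves) split(edges[, 2L], edges[, 1L]) else NULL
  a_tr <- matrix(0L, n_iter, E)
  d_tr <- matrix(0L, n_iter, E)
  par_tr <- matrix(0, n_iter, 5,
                   dimnames = list(NULL, c("alpha", "beta", "lambda",
                                           "kappa", "lp")))
  n_acc <- setNames(numeric(4), names(scales))
  n_try <- 0
  burn_end <- floor(n_iter / 2)
  for (it in seq_len(n_iter)) {
    ftab <- build_ftab(ctx$N, st$alpha, st$beta)
    rowtab <- log_prior_row_x(0:(ctx$N - 1), ctx$N, st$lambda, st$kappa)
    st <- sweep_internal(ctx, st, edges, ftab, rowtab)
    if (swap_moves) st <- swap_sweep(ctx, st, row_pos, ftab)
    if (sample_hyper) {
      n_try <- n_try + 1
      suff <- hyper_suff(ctx, st)
      for (p in names(scales)) {
        res <- mh_internal(ctx, st, p, scales[[p]], suff)
        st <- res$state
        n_acc[[p]] <- n_acc[[p]] + res$accepted
      }
      if (adapt && it <= burn_end && it %% 50L == 0L) {
        rate <- n_acc / n_try
        scales <- scales * exp(0.5 * (rate - 0.44))
        n_acc[] <- 0; n_try <- 0
      }
    }
    if (E > 0) {
      a_tr[it, ] <- st$A[edges]
      d_tr[it, ] <- st$delta[edges]
    }
    par_tr[it, ] <- c(st$alpha, st$beta, st$lambda, st$kappa,
                      lp_internal(ctx, st))
  }
  list(a = a_tr, delta = d_tr, pars = par_tr,
       accept = if (n_try > 0) n_acc / n_try else n_acc,
       final_scales = scales)
}

# Per-point log-likelihood lookup table for fixed (alpha, beta).  The
# input signal H is an integer in [-N, N] and the per-point term depends
# only on (H, state, persistence indicator), so one Gibbs sweep can score
# every candidate edge state by an indexed gather into this table.  Index:
# (H + N) * 4 + enc + 1 with enc = 2 * y + same.
build_ftab <- function(N, alpha, beta) {
  h <- rep(-N:N, each = 4L)
  y <- rep(c(0, 0, 1, 1), 2L * N + 1L)
  same <- rep(c(0, 1, 0, 1), 2L * N + 1L)
  v <- beta * (2 * y - 1) * h
  a <- abs(beta * h)
  f <- v - a - log1p(exp(-2 * a))
  p <- plogis(alpha)
  f[h == 0] <- ifelse(same[h == 0] == 1, log(p), log1p(-p))
  f
}

# one Gibbs sweep over the retained edges, in a random scan order;
# the per-point likelihood table and the row-prior table are fixed within
# a sweep because (alpha, beta, lambda, kappa) only move in the M-H steps
sweep_internal <- function(ctx, st, edges, ftab = NULL, rowtab = NULL) {
  E <- nrow(edges)
  if (E == 0) return(st)
  if (is.null(ftab)) ftab <- build_ftab(ctx$N, st$alpha, st$beta)
  if (is.null(rowtab)) {
    rowtab <- log_prior_row_x(0:(ctx$N - 1), ctx$N, st$lambda, st$kappa)
  }
  for (e in sample.int(E)) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    st <- update_edge(ctx, st, i, j, ftab, rowtab)
  }
  st
}

# One Metropolised edge-swap attempt per target gene: exchange the
# (a, delta) pair of one present edge with one retained absent position of
# the same row.  The proposal is a symmetric involution and keeps the
# in-degree, so the row prior and the delay priors cancel and the
# acceptance probability is the bare likelihood ratio of the row.
swap_sweep <- function(ctx, st, row_pos, ftab) {
  if (ctx$Tu == 0) return(st)
  for (i_chr in names(row_pos)) {
    i <- as.integer(i_chr)
    cand <- row_pos[[i_chr]]
    pres <- cand[st$A[i, cand] != 0L]
    absent <- cand[st$A[i, cand] == 0L]
    if (length(pres) == 0L || length(absent) == 0L) next
    jp <- pres[sample.int(length(pres), 1L)]
    ja <- absent[sample.int(length(absent), 1L)]
    a <- st$A[i, jp]; d <- st$delta[i, jp]
    Hrow <- st$H[i, ]
    Hnew <- Hrow - a * ctx$LSrows[[jp]][d + 1L, ] +
      a * ctx$LSrows[[ja]][d + 1L, ]
    enc1 <- ctx$enc_rows[[i]] + 1
    dll <- sum(ftab[(Hnew + ctx$N) * 4 + enc1]) -
      sum(ftab[(Hrow + ctx$N) * 4 + enc1])
    if (dll >= 0 || log(runif(1)) < dll) {
      d_spike <- st$delta[i, ja]
      st$A[i, ja] <- a; st$delta[i, ja] <- d
      st$A[i, jp] <- 0L; st$delta[i, jp] <- d_spike
      st$H[i, ] <- Hnew
    }
  }
  st
}

# joint (a_ij, delta_ij) draw from the 18-state full conditional
update_edge <- function(ctx, st, i, j, ftab = NULL, rowtab = NULL) {
  if (is.null(ftab)) ftab <- build_ftab(ctx$N, st$alpha, st$beta)
  if (is.null(rowtab)) {
    rowtab <- log_prior_row_x(0:(ctx$N - 1), ctx$N, st$lambda, st$kappa)
  }
  LSj <- ctx$LSrows[[j]]
  a_cur <- st$A[i, j]; d_cur <- st$delta[i, j]
  Hrow <- st$H[i, ]
  Hbase <- if (a_cur == 0) Hrow else Hrow - a_cur * LSj[d_cur + 1L, ]
  lw <- edge_log_weights(ctx, st, i, j, Hbase, ftab, rowtab)
  pr <- exp(lw - max(lw))
  pick <- sample.int(18L, 1L, prob = pr)
  a_new <- edge_cand_a[pick]; d_new <- edge_cand_d[pick]
  st$x[i] <- st$x[i] - (a_cur != 0L) + (a_new != 0L)
  st$A[i, j] <- a_new
  st$delta[i, j] <- d_new
  st$H[i, ] <- if (a_new == 0) Hbase else Hbase + a_new * LSj[d_new + 1L, ]
  st
}

# candidate enumeration: a = -1 (lags 0..5), a = +1 (lags 0..5), a = 0
# (lags 0..5, all sharing the a = 0 likelihood)
edge_cand_a <- c(rep(-1L, 6), rep(1L, 6), rep(0L, 6))
edge_cand_d <- rep(0:5, 3)

# log posterior weights of the 18 candidate states of one edge; only gene
# i's likelihood terms, its row prior and the edge's delay prior vary,
# everything else cancels in the conditional
edge_log_weights <- function(ctx, st, i, j, Hbase, ftab, rowtab = NULL) {
  if (is.null(rowtab)) {
    rowtab <- log_prior_row_x(0:(ctx$N - 1), ctx$N, st$lambda, st$kappa)
  }
  Tu <- ctx$Tu
  ll <- numeric(13)
  if (Tu > 0) {
    keybase <- (Hbase + ctx$N) * 4 + ctx$enc_rows[[i]] + 1
    G <- ftab[keybase + ctx$LSoff[[j]]]
    ll[1:12] <- .colSums(G, Tu, 12L)
    ll[13] <- sum(ftab[keybase])
  }
  x_other <- st$x[i] - (st$A[i, j] != 0L)
  lp_present <- rowtab[x_other + 2L] + log(1 / 6)
  lp_absent <- rowtab[x_other + 1L] +
    c(log(0.999), rep(log(2e-04), 5))
  c(ll[1:6] + lp_present,    # a = -1, lags 0..5
    ll[7:12] + lp_present,   # a = +1, lags 0..5
    ll[13] + lp_absent)      # a = 0,  spike-and-slab over lags 0..5
}
#' Full conditional of one edge
#'
#' Evaluates the normalised 18-state joint conditional distribution of
#' `(a_ij, delta_ij)` given the data and all other parameters: the
#' likelihood factor uses only gene `i`'s transition terms, multiplied by
#' the row sparsity prior (whose in-degree changes with `a_ij`) and the
#' delay prior (flat for a present edge, spike-and-slab for an absent one).
#'
#' @param ds A [subtree_dataset] (or `NULL` for a flat likelihood).
#' @param i,j Target and regulator gene indices.
#' @param net Current [grn] state.
#' @param alpha,beta,lambda,kappa Current continuous parameters.
#' @return A tibble with columns `a`, `delay` and `prob` (18 rows summing
#'   to 1).
#' @export
edge_conditional <- function(ds, i, j, net, alpha, beta, lambda, kappa) {
  N <- nrow(net$A)
  ctx <- prep_ctx(ds, N)
  st <- new_chain_state(ctx)
  st$A <- net$A; st$delta <- net$delta
  st$x <- as.integer(rowSums(net$A != 0))
  st$alpha <- alpha; st$beta <- beta; st$lambda <- lambda; st$kappa <- kappa
  if (ctx$Tu > 0) st$H <- input_matrix(net$A, net$delta, ctx$LS)
  LSj <- ctx$LSrows[[j]]
  a_cur <- st$A[i, j]; d_cur <- st$delta[i, j]
  Hbase <- if (a_cur == 0) st$H[i, ] else
    st$H[i, ] - a_cur * LSj[d_cur + 1L, ]
  lw <- edge_log_weights(ctx, st, i, j, Hbase,
                         build_ftab(ctx$N, alpha, beta),
                         log_prior_row_x(0:(N - 1), N, lambda, kappa))
  pr <- exp(lw - max(lw))
  tibble(a = edge_cand_a, delay = edge_cand_d, prob = pr / sum(pr))
}

# full log posterior of the current chain state (Eq.-style decomposition:
# likelihood from the maintained input matrix + network prior + hyperpriors)
lp_internal <- function(ctx, st) {
  ll <- if (ctx$Tu > 0) {
    loglik_from_H(st$H, ctx$y, ctx$yprev, st$alpha, st$beta)
  } else 0
  off <- which(row(st$A) != col(st$A))
  ll + sum(log_prior_row_x(st$x, ctx$N, st$lambda, st$kappa)) +
    sum(log_prior_delay(st$delta[off], st$A[off])) +
    log_hyper_density(st$alpha, st$beta, st$lambda, st$kappa)
}

# sufficient statistics of the likelihood in (alpha, beta) given (A, delta):
# persistence counts at zero input, and tallies of the signed and absolute
# nonzero inputs
hyper_suff <- function(ctx, st) {
  if (ctx$Tu == 0) {
    return(list(n_zero = 0, n_same = 0, v_sum = 0,
                h = numeric(0), h_n = numeric(0)))
  }
  z <- st$H == 0
  n_zero <- sum(z)
  n_same <- sum(ctx$same[z])
  if (n_zero < length(st$H)) {
    Hn <- st$H[!z]
    v_sum <- sum(ctx$s2[!z] * Hn)
    tab <- tabulate(abs(Hn))
    h <- which(tab > 0)
    h_n <- tab[h]
  } else {
    v_sum <- 0
    h <- numeric(0)
    h_n <- numeric(0)
  }
  list(n_zero = n_zero, n_same = n_same, v_sum = v_sum, h = h, h_n = h_n)
}

# conditional log density of one continuous parameter (up to a constant)
cond_logdens <- function(param, value, suff, st, N) {
  hp <- hyper_priors
  switch(param,
    alpha = {
      p <- plogis(value)
      suff$n_same * log(p) + (suff$n_zero - suff$n_same) * log1p(-p) +
        dgamma(value, hp$alpha[1], rate = hp$alpha[2], log = TRUE)
    },
    beta = {
      ll <- value * suff$v_sum
      if (length(suff$h) > 0) {
        ll <- ll - sum(suff$h_n *
                         (value * suff$h + log1p(exp(-2 * value * suff$h))))
      }
      ll + dgamma(value, hp$beta[1], rate = hp$beta[2], log = TRUE)
    },
    lambda = {
      nz <- st$x[st$x > 0]
      sum(log_normalizing_c(value, N) - value * nz) +
        dgamma(value, hp$lambda[1], rate = hp$lambda[2], log = TRUE)
    },
    kappa = {
      n0 <- sum(st$x == 0)
      n0 * log(value) + (N - n0) * log1p(-value) +
        dbeta(value, hp$kappa[1], hp$kappa[2], log = TRUE)
    }
  )
}

# one M-H step on a continuous parameter: log-scale Gaussian random walk
# (logit scale for kappa) with the Jacobian folded into the acceptance
mh_internal <- function(ctx, st, param, scale, suff = NULL) {
  if (is.null(suff)) suff <- hyper_suff(ctx, st)
  cur <- st[[param]]
  if (param == "kappa") {
    prop <- plogis(qlogis(cur) + scale * stats::rnorm(1))
    log_jac <- log(prop) + log1p(-prop) - log(cur) - log1p(-cur)
  } else {
    prop <- cur * exp(scale * stats::rnorm(1))
    log_jac <- log(prop) - log(cur)
  }
  la <- cond_logdens(param, prop, suff, st, ctx$N) -
    cond_logdens(param, cur, suff, st, ctx$N) + log_jac
  accepted <- is.finite(la) && log(runif(1)) < la
  if (accepted) st[[param]] <- prop
  list(state = st, accepted = accepted)
}

#' One Gibbs sweep over the retained edges
#'
#' Updates every retained `(a_ij, delta_ij)` pair once from its joint full
#' conditional, in a random scan order drawn from the current RNG state;
#' eliminated edges are untouched.  Exposed for sampler diagnostics --
#' [run_mcmc()] is the user-facing driver.
#'
#' @inheritParams edge_conditional
#' @param mask A `prescreen_mask`, or `NULL` for all off-diagonal edges.
#' @param context Optional precomputed context from repeated calls.
#' @return A list with the updated `net` (a [grn]) unchanged continuous
#'   parameters.
#' @export
gibbs_sweep <- function(ds, net, alpha, beta, lambda, kappa, mask = NULL,
                        context = NULL) {
  N <- nrow(net$A)
  ctx <- context %||% prep_ctx(ds, N)
  st <- new_chain_state(ctx)
  st$A <- net$A; st$delta <- net$delta
  st$x <- as.integer(rowSums(net$A != 0))
  st$alpha <- alpha; st$beta <- beta; st$lambda <- lambda; st$kappa <- kappa
  if (ctx$Tu > 0) st$H <- input_matrix(net$A, net$delta, ctx$LS)
  st <- sweep_internal(ctx, st, mask_edges(mask, N))
  list(net = grn(st$A, st$delta), alpha = alpha, beta = beta,
       lambda = lambda, kappa = kappa)
}

#' One Metropolis--Hastings update of a continuous parameter
#'
#' Proposes on the log scale (`alpha`, `beta`, `lambda`) or logit scale
#' (`kappa`) and accepts against the parameter's full conditional under
#' the current network state.  With `ds = NULL` the likelihood is flat and
#' the move targets the conditional prior.
#'
#' @inheritParams edge_conditional
#' @param param One of `"alpha"`, `"beta"`, `"lambda"`, `"kappa"`.
#' @param proposal_scale Random-walk sd on the transformed scale.
#' @return A list with the (possibly) updated parameter values, the `net`,
#'   and `accepted`.
#' @export
mh_update <- function(ds, net, alpha, beta, lambda, kappa,
                      param = c("alpha", "beta", "lambda", "kappa"),
                      proposal_scale = 0.2) {
  param <- match.arg(param)
  N <- nrow(net$A)
  ctx <- prep_ctx(ds, N)
  st <- new_chain_state(ctx)
  st$A <- net$A; st$delta <- net$delta
  st$x <- as.integer(rowSums(net$A != 0))
  st$alpha <- alpha; st$beta <- beta; st$lambda <- lambda; st$kappa <- kappa
  if (ctx$Tu > 0) st$H <- input_matrix(net$A, net$delta, ctx$LS)
  res <- mh_internal(ctx, st, param, proposal_scale)
  out <- res$state[c("alpha", "beta", "lambda", "kappa")]
  out$net <- net
  out$accepted <- res$accepted
  out
}

#' Maximum-a-posteriori estimate from MCMC samples
#'
#' Discards the first half of every chain (burn-in) and returns, by
#' default, the sampled joint state with the highest recorded log
#' posterior across chains.  The alternative `"marginal"` rule takes each
#' edge's posterior-modal `(a, delta)` pair and the posterior medians of
#' the continuous parameters.
#'
#' @param fit A `bn_mcmc` from [run_mcmc()].
#' @param method `"joint"` (default) or `"marginal"`.
#' @return A list of class `bn_map` with elements `net` (a [grn]),
#'   `alpha`, `beta`, `lambda`, `kappa`, and for the joint rule `chain`,
#'   `iteration` and `lp`.
#' @export
map_estimate <- function(fit, method = c("joint", "marginal")) {
  stopifnot(inherits(fit, "bn_mcmc"))
  method <- match.arg(method)
  n <- fit$n_iter
  keep <- seq.int(floor(n / 2) + 1L, n)
  N <- fit$n_genes
  E <- nrow(fit$edges)
  ij <- cbind(fit$edges$i, fit$edges$j)
  build_net <- function(a_vals, d_vals) {
    A <- matrix(0L, N, N, dimnames = list(fit$genes, fit$genes))
    delta <- matrix(0L, N, N, dimnames = list(fit$genes, fit$genes))
    if (E > 0) {
      A[ij] <- as.integer(a_vals)
      delta[ij] <- as.integer(d_vals)
    }
    grn(A, delta)
  }
  if (method == "joint") {
    best <- lapply(fit$chains, function(ch) {
      w <- keep[which.max(ch$pars[keep, "lp"])]
      list(lp = ch$pars[w, "lp"], it = w, ch = ch)
    })
    b <- which.max(vapply(best, `[[`, numeric(1), "lp"))
    it <- best[[b]]$it
    ch <- fit$chains[[b]]
    out <- list(
      net = build_net(if (E > 0) ch$a[it, ] else integer(0),
                      if (E > 0) ch$delta[it, ] else integer(0)),
      alpha = unname(ch$pars[it, "alpha"]),
      beta = unname(ch$pars[it, "beta"]),
      lambda = unname(ch$pars[it, "lambda"]),
      kappa = unname(ch$pars[it, "kappa"]),
      chain = b, iteration = it, lp = unname(ch$pars[it, "lp"])
    )
  } else {
    a_all <- do.call(rbind, lapply(fit$chains, function(ch) {
      ch$a[keep, , drop = FALSE]
    }))
    d_all <- do.call(rbind, lapply(fit$chains, function(ch) {
      ch$delta[keep, , drop = FALSE]
    }))
    pars <- do.call(rbind, lapply(fit$chains, function(ch) {
      ch$pars[keep, , drop = FALSE]
    }))
    mode_ad <- vapply(seq_len(E), function(e) {
      key <- paste(a_all[, e], d_all[, e])
      top <- names(which.max(table(key)))
      as.integer(strsplit(top, " ")[[1]])
    }, integer(2))
    out <- list(
      net = build_net(if (E > 0) mode_ad[1, ] else integer(0),
                      if (E > 0) mode_ad[2, ] else integer(0)),
      alpha = median(pars[, "alpha"]), beta = median(pars[, "beta"]),
      lambda = median(pars[, "lambda"]), kappa = median(pars[, "kappa"])
    )
  }
  structure(out, class = "bn_map")
}

#' @export
print.bn_map <- function(x, ...) {
  cat("<bn_map> MAP estimate\n")
  print(x$net)
  cat(sprintf("  alpha = %.3f, beta = %.3f, lambda = %.3f, kappa = %.3f\n",
              x$alpha, x$beta, x$lambda, x$kappa))
  if (!is.null(x$lp)) {
    cat(sprintf("  log posterior %.2f (chain %d, iteration %d)\n",
                x$lp, x$chain, x$iteration))
  }
  invisible(x)
}

#' @export
print.bn_mcmc <- function(x, ...) {
  cat(sprintf("<bn_mcmc> %d chain%s x %d iterations, %d genes, %d retained edge%s\n",
              length(x$chains), if (length(x$chains) == 1) "" else "s",
              x$n_iter, x$n_genes, nrow(x$edges),
              if (nrow(x$edges) == 1) "" else "s"))
  lp <- vapply(x$chains, function(ch) ch$pars[x$n_iter, "lp"], numeric(1))
  cat("  final log posterior by chain:",
      paste(sprintf("%.1f", lp), collapse = ", "), "\n")
  invisible(x)
}
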