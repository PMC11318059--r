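# brute-force evaluation of the 18-state edge conditional through the
# public full-likelihood path (independent of the sampler's fast path)
brute_edge_conditional <- function(ds, i, j, net, alpha, beta, lambda,
                                   kappa) {
  cand <- expand.grid(a = c(-1L, 1L, 0L), delay = 0:5)
  lw <- mapply(function(a, d) {
    A2 <- net$A; D2 <- net$delta
    A2[i, j] <- a; D2[i, j] <- d
    log_likelihood(ds, grn(A2, D2), alpha, beta) +
      log_prior_row(A2[i, ], lambda, kappa) +
      log_prior_delay(d, a)
  }, cand$a, cand$delay)
  w <- exp(lw - max(lw))
  tibble::tibble(a = cand$a, delay = cand$delay, prob = w / sum(w))
}

test_that("the edge conditional matches brute force and normalises", {
  set.seed(20)
  for (rep in 1:8) {
    N <- sample(2:4, 1)
    tr <- draw_truth(N)
    ds <- simulate_dataset(tr, sim_config(N, sample(1:3, 1),
                                          sample(6:10, 1)))
    i <- sample(N, 1)
    js <- setdiff(seq_len(N), i)
    j <- js[sample.int(length(js), 1)]
    al <- runif(1, 0.05, 2); be <- runif(1, 0.3, 2)
    la <- runif(1, 4, 9); ka <- runif(1, 0.1, 0.4)
    ours <- edge_conditional(ds, i, j, tr$net, al, be, la, ka)
    expect_equal(sum(ours$prob), 1, tolerance = 1e-12)
    ref <- brute_edge_conditional(ds, i, j, tr$net, al, be, la, ka)
    key <- function(d) order(d$a, d$delay)
    expect_equal(ours$prob[key(ours)], ref$prob[key(ref)],
                 tolerance = 1e-10)
  }
})

test_that("with a flat likelihood the edge conditional is the prior", {
  net <- grn(matrix(0L, 3, 3))
  la <- 7; ka <- 0.2
  out <- edge_conditional(NULL, 1, 2, net, 0.1, 1, la, ka)
  row1 <- exp(log_prior_row(c(0, 1, 0), la, ka))   # x = 1
  row0 <- exp(log_prior_row(c(0, 0, 0), la, ka))   # x = 0
  z <- 12 * row1 / 6 + row0 * (0.999 + 5 * 2e-4)
  expect_equal(out$prob[out$a == 1 & out$delay == 3], (row1 / 6) / z)
  expect_equal(out$prob[out$a == 0 & out$delay == 0], row0 * 0.999 / z)
  expect_equal(sum(out$prob), 1)
})

test_that("a strong lagged activation is identified as the modal state", {
  A <- matrix(0L, 2, 2); A[2, 1] <- 1L
  delta <- matrix(0L, 2, 2); delta[2, 1] <- 2L
  truth <- list(net = grn(A, delta), alpha = 0.2, beta = 2.5)
  ds <- simulate_dataset(truth, sim_config(2, 3, 30), seed = 21)
  out <- edge_conditional(ds, 2, 1, grn(matrix(0L, 2, 2)), 0.2, 2.5, 7,
                          0.2)
  top <- out[which.max(out$prob), ]
  expect_equal(top$a, 1L)
  expect_equal(top$delay, 2L)
  expect_gt(top$prob, 0.9)
})

test_that("a Gibbs sweep respects the mask and the empty-mask identity", {
  x <- random_dataset(4, 3, 10, seed = 22)
  empty_mask <- structure(list(tilde_A = matrix(0L, 4, 4), theta = 0.05),
                          class = "prescreen_mask")
  set.seed(1)
  out <- gibbs_sweep(x$ds, x$truth$net, 0.1, 1, 7, 0.2, mask = empty_mask)
  expect_identical(out$net$A, x$truth$net$A)
  # a partial mask never writes outside the retained set
  tA <- matrix(0L, 4, 4); tA[2, 1] <- 1L; tA[3, 4] <- 1L
  part <- structure(list(tilde_A = tA, theta = 0.05),
                    class = "prescreen_mask")
  net0 <- grn(matrix(0L, 4, 4))
  set.seed(2)
  for (rep in 1:10) {
    net0 <- gibbs_sweep(x$ds, net0, 0.1, 1, 7, 0.2, mask = part)$net
    expect_true(all(net0$A[tA == 0L] == 0L))
  }
})

test_that("Gibbs sampling reproduces the enumerated posterior on a toy", {
  # 2 genes, only edge (2 <- 1) retained: 18 joint states, exactly the
  # edge conditional at fixed continuous parameters.  Long Gibbs-only run
  # must match the enumeration in total variation.
  A <- matrix(0L, 2, 2); A[2, 1] <- 1L
  delta <- matrix(0L, 2, 2); delta[2, 1] <- 1L
  truth <- list(net = grn(A, delta), alpha = 0.5, beta = 1)
  ds <- simulate_dataset(truth, sim_config(2, 1, 20), seed = 23)
  mask <- structure(list(tilde_A = A, theta = 0.05),
                    class = "prescreen_mask")
  al <- 0.5; be <- 1; la <- 7; ka <- 0.2
  exact <- edge_conditional(ds, 2, 1, grn(matrix(0L, 2, 2)), al, be, la,
                            ka)
  n_sweeps <- 40000
  fit <- run_mcmc(ds, mask, n_iter = n_sweeps, n_chains = 1, seed = 24,
                  sample_hyper = FALSE, swap_moves = FALSE,
                  init = list(alpha = al, beta = be, lambda = la,
                              kappa = ka))
  a_tr <- fit$chains[[1]]$a[, 1]
  d_tr <- fit$chains[[1]]$delta[, 1]
  emp <- vapply(seq_len(18), function(k) {
    mean(a_tr == exact$a[k] & d_tr == exact$delay[k])
  }, numeric(1))
  tv <- 0.5 * sum(abs(emp - exact$prob))
  expect_lt(tv, 0.02)
})

test_that("vanishing proposal scale accepts every M-H move", {
  x <- random_dataset(3, 2, 8, seed = 25)
  set.seed(3)
  for (p in c("alpha", "beta", "lambda", "kappa")) {
    acc <- vapply(1:20, function(r) {
      mh_update(x$ds, x$truth$net, 0.3, 1, 7, 0.2, param = p,
                proposal_scale = 1e-8)$accepted
    }, logical(1))
    expect_true(all(acc))
  }
})

test_that("sampling with a flat likelihood recovers the prior moments", {
  tA <- matrix(1L, 3, 3); diag(tA) <- 0L
  mask <- structure(list(tilde_A = tA, theta = 0.05),
                    class = "prescreen_mask")
  fit <- run_mcmc(NULL, mask, n_iter = 6000, n_chains = 2, seed = 26)
  pars <- do.call(rbind, lapply(fit$chains, function(ch) ch$pars))
  # Gamma(shape, rate) means and sds; Beta mean (absolute tolerances
  # sized to several random-walk-autocorrelated standard errors)
  expect_lt(abs(mean(pars[, "beta"]) - 1), 0.02)
  expect_lt(abs(sd(pars[, "beta"]) - 0.1), 0.02)
  expect_lt(abs(mean(pars[, "lambda"]) - 7), 0.1)
  expect_lt(abs(mean(pars[, "kappa"]) - 0.2), 0.02)
  expect_lt(abs(mean(pars[, "alpha"]) - 0.1), 0.03)
})

test_that("lambda and kappa conditionals read the network only via x", {
  # two networks with identical in-degree profiles but different signs,
  # regulator sets and delays must induce identical M-H behaviour
  A1 <- matrix(0L, 3, 3); A1[1, 2] <- 1L; A1[2, 3] <- -1L
  D1 <- matrix(0L, 3, 3); D1[1, 2] <- 4L
  A2 <- matrix(0L, 3, 3); A2[1, 3] <- -1L; A2[2, 1] <- 1L
  D2 <- matrix(0L, 3, 3); D2[2, 1] <- 2L
  for (p in c("lambda", "kappa")) {
    set.seed(40)
    r1 <- mh_update(NULL, grn(A1, D1), 0.1, 1, 7, 0.2, param = p,
                    proposal_scale = 0.6)
    set.seed(40)
    r2 <- mh_update(NULL, grn(A2, D2), 0.1, 1, 7, 0.2, param = p,
                    proposal_scale = 0.6)
    expect_identical(r1[[p]], r2[[p]])
    expect_identical(r1$accepted, r2$accepted)
  }
})

test_that("burn-in discards exactly the first half", {
  for (n in c(1L, 2L, 7L, 10L)) {
    keep <- seq.int(floor(n / 2) + 1L, n)
    expect_equal(length(keep), ceiling(n / 2))
  }
  mask <- structure(list(tilde_A = matrix(0L, 2, 2), theta = 0.05),
                    class = "prescreen_mask")
  fit <- run_mcmc(NULL, mask, n_iter = 1L, n_chains = 1, seed = 27)
  est <- map_estimate(fit)
  expect_equal(est$iteration, 1L)
})

test_that("the MAP sample is the best state across chains", {
  x <- random_dataset(3, 2, 10, seed = 28)
  mask <- suppressWarnings(run_prescreen(x$ds, theta = 1))
  fit <- run_mcmc(x$ds, mask, n_iter = 60, n_chains = 3, seed = 29)
  est <- map_estimate(fit)
  n <- fit$n_iter
  keep <- seq.int(floor(n / 2) + 1L, n)
  best <- max(vapply(fit$chains, function(ch) max(ch$pars[keep, "lp"]),
                     numeric(1)))
  expect_equal(est$lp, unname(best))
  # the recorded lp is the actual posterior of the recorded state
  expect_equal(
    unname(log_posterior(x$ds, est$net, est$alpha, est$beta, est$lambda,
                         est$kappa)),
    est$lp
  )
})

test_that("the joint MAP matches exhaustive enumeration on a toy grid", {
  A <- matrix(0L, 2, 2); A[2, 1] <- 1L
  delta <- matrix(0L, 2, 2); delta[2, 1] <- 3L
  truth <- list(net = grn(A, delta), alpha = 0.4, beta = 1.5)
  ds <- simulate_dataset(truth, sim_config(2, 1, 25), seed = 30)
  mask <- structure(list(tilde_A = A, theta = 0.05),
                    class = "prescreen_mask")
  al <- 0.4; be <- 1.5; la <- 7; ka <- 0.2
  fit <- run_mcmc(ds, mask, n_iter = 400, n_chains = 1, seed = 31,
                  sample_hyper = FALSE,
                  init = list(alpha = al, beta = be, lambda = la,
                              kappa = ka))
  est <- map_estimate(fit)
  # exhaustive argmax over the 18 edge states at the same fixed
  # continuous values
  cand <- expand.grid(a = c(-1L, 0L, 1L), d = 0:5)
  lps <- mapply(function(a, d) {
    A2 <- matrix(0L, 2, 2); D2 <- matrix(0L, 2, 2)
    A2[2, 1] <- a; D2[2, 1] <- d
    log_posterior(ds, grn(A2, D2), al, be, la, ka)
  }, cand$a, cand$d)
  best <- cand[which.max(lps), ]
  expect_equal(est$net$A[2, 1], best$a)
  if (best$a != 0) expect_equal(est$net$delta[2, 1], best$d)
})

test_that("fixed seeds give identical traces", {
  x <- random_dataset(4, 2, 10, seed = 32)
  mask <- suppressWarnings(run_prescreen(x$ds, theta = 0.5))
  f1 <- run_mcmc(x$ds, mask, n_iter = 30, n_chains = 2, seed = 33)
  f2 <- run_mcmc(x$ds, mask, n_iter = 30, n_chains = 2, seed = 33)
  expect_identical(f1$chains[[1]]$pars, f2$chains[[1]]$pars)
  expect_identical(f1$chains[[2]]$a, f2$chains[[2]]$a)
})
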