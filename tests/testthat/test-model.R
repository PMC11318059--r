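test_that("persistence probability behaves across the alpha range", {
  expect_equal(persistence_prob(1e-9), 0.5, tolerance = 1e-6)
  expect_equal(persistence_prob(50), 1, tolerance = 1e-10)
  expect_equal(persistence_prob(2), 0.880797, tolerance = 1e-6)
  expect_error(persistence_prob(-1))
})

test_that("transition probabilities follow the Boltzmann form", {
  expect_equal(transition_prob(1, 3, 0), 0.5)
  expect_equal(transition_prob(0, -2, 0), 0.5)
  expect_equal(transition_prob(1, 1, 50), 1, tolerance = 1e-10)
  expect_equal(transition_prob(0, 2, 1), exp(-2) / (exp(2) + exp(-2)),
               tolerance = 1e-9)
  # normalisation over s for any (H, beta)
  set.seed(1)
  for (rep in 1:20) {
    H <- sample(c(-5:-1, 1:5), 1); b <- runif(1, 0, 3)
    expect_equal(transition_prob(1, H, b) + transition_prob(0, H, b), 1)
  }
})

test_that("the input signal sums signed delayed regulator states", {
  lagged <- matrix(rbinom(4 * 6, 1, 0.5), 4, 6)
  expect_equal(input_signal(rep(0L, 4), rep(0L, 4), lagged), 0L)
  a <- c(0L, 1L, 0L, 0L); d <- c(0L, 2L, 0L, 0L)
  expect_equal(input_signal(a, d, lagged), as.integer(lagged[2, 3]))
  set.seed(2)
  for (rep in 1:30) {
    a <- sample(c(-1L, 0L, 1L), 5, replace = TRUE)
    d <- sample(0:5, 5, replace = TRUE)
    lag <- matrix(rbinom(30, 1, 0.5), 5, 6)
    brute <- sum(vapply(1:5, function(j) {
      a[j] * lag[j, d[j] + 1]
    }, numeric(1)))
    h <- input_signal(a, d, lag)
    expect_equal(h, as.integer(brute))
    expect_true(abs(h) <= sum(a != 0))
  }
})

test_that("likelihood of the empty network is a pure persistence product", {
  set.seed(3)
  s <- matrix(rbinom(2 * 12, 1, 0.5), 2, 12)
  ds <- chain_dataset(s)
  net <- grn(matrix(0L, 2, 2))
  alpha <- 1.3
  p <- 1 / (1 + exp(-alpha))
  usable <- usable_points(ds)
  n_same <- sum(s[, usable] == s[, usable - 1])
  n_tot <- 2 * length(usable)
  expect_equal(log_likelihood(ds, net, alpha, 1),
               n_same * log(p) + (n_tot - n_same) * log(1 - p))
})

test_that("a single-edge chain likelihood matches a manual product", {
  # gene 2 activated by gene 1 at delay 1; 8-point chain
  s <- rbind(c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),
             c(1L, 0L, 1L, 1L, 0L, 1L, 1L, 1L))
  ds <- chain_dataset(s)
  A <- matrix(c(0L, 1L, 0L, 0L), 2, 2)   # A[2,1] = 1
  delta <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  alpha <- 0.7; beta <- 1.2
  manual <- 0
  p <- 1 / (1 + exp(-alpha))
  for (t in 6:8) {
    # gene 1: no input, persistence of its own lag-1 state
    manual <- manual + ifelse(s[1, t] == s[1, t - 1], log(p), log(1 - p))
    # gene 2: input from gene 1 at lag 1
    H <- s[1, t - 1]
    manual <- manual + if (H == 0) {
      ifelse(s[2, t] == s[2, t - 1], log(p), log(1 - p))
    } else {
      beta * (2 * s[2, t] - 1) * H - log(exp(beta * H) + exp(-beta * H))
    }
  }
  expect_equal(log_likelihood(ds, grn(A, delta), alpha, beta), manual)
})

test_that("likelihood is invariant under gene relabelling", {
  x <- random_dataset(4, 3, 8, seed = 4)
  perm <- c(3, 1, 4, 2)
  ds2 <- x$ds
  ds2$states <- ds2$states[perm, ]
  net2 <- grn(x$truth$net$A[perm, perm], x$truth$net$delta[perm, perm])
  expect_equal(
    log_likelihood(x$ds, x$truth$net, 0.5, 1.1),
    log_likelihood(ds2, net2, 0.5, 1.1)
  )
})

test_that("per-gene likelihood terms depend only on that gene's row", {
  x <- random_dataset(4, 2, 10, seed = 5)
  net <- x$truth$net
  ll1 <- log_likelihood(x$ds, net, 0.4, 0.9)
  # changing row 3 only changes the total by gene 3's contribution
  A2 <- net$A; A2[3, ] <- 0L
  ll2 <- log_likelihood(x$ds, grn(A2, net$delta), 0.4, 0.9)
  A3 <- net$A; A3[3, ] <- 0L; A3[1, ] <- 0L
  A4 <- net$A; A4[1, ] <- 0L
  ll3 <- log_likelihood(x$ds, grn(A3, net$delta), 0.4, 0.9)
  ll4 <- log_likelihood(x$ds, grn(A4, net$delta), 0.4, 0.9)
  expect_equal(ll1 - ll2, ll4 - ll3)
})

test_that("the row prior normalises and matches closed forms", {
  lambda <- 1.7; kappa <- 0.22
  expect_equal(log_prior_row(c(0, 0, 0), lambda, kappa), log(kappa))
  # N = 3, one regulator: (1 - kappa) c(lambda) e^-lambda / 4
  lp <- log_prior_row(c(0, 1, 0), lambda, kappa)
  expect_equal(lp, log((1 - kappa) * normalizing_c(lambda, 3) *
                         exp(-lambda) / (2 * 2)))
  # exhaustive normalisation for N = 2..5
  for (N in 2:5) {
    rows <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), N - 1)))
    tot <- sum(exp(apply(rows, 1, function(r) {
      log_prior_row(c(0, r), lambda, kappa)
    })))
    expect_equal(tot, 1)
  }
})

test_that("the in-degree normalising constant matches direct sums", {
  expect_equal(normalizing_c(2.3, 2), exp(2.3))
  expect_equal(normalizing_c(1, 4), 1 / (exp(-1) + exp(-2) + exp(-3)))
  # lambda -> Inf: c(lambda) e^-lambda -> 1
  expect_equal(normalizing_c(40, 6) * exp(-40), 1, tolerance = 1e-12)
})

test_that("both delay prior branches are proper distributions", {
  expect_equal(log_prior_delay(0:5, rep(1, 6)), rep(log(1 / 6), 6))
  expect_equal(log_prior_delay(0, 0), log(0.999))
  expect_equal(log_prior_delay(3, 0), log(2e-4))
  expect_equal(sum(exp(log_prior_delay(0:5, rep(0, 6)))), 1)
  expect_equal(sum(exp(log_prior_delay(0:5, rep(-1, 6)))), 1)
})

test_that("the log posterior decomposes additively and stays finite", {
  x <- random_dataset(3, 2, 9, seed = 6)
  net <- x$truth$net
  lp1 <- log_posterior(x$ds, net, 0.2, 1.0, 7, 0.2)
  lp2 <- log_posterior(x$ds, net, 0.9, 1.0, 7, 0.2)
  dll <- log_likelihood(x$ds, net, 0.9, 1.0) -
    log_likelihood(x$ds, net, 0.2, 1.0)
  dpr <- dgamma(0.9, 1, rate = 10, log = TRUE) -
    dgamma(0.2, 1, rate = 10, log = TRUE)
  expect_equal(lp2 - lp1, dll + dpr)
  set.seed(7)
  for (rep in 1:5) {
    tr <- draw_truth(3)
    expect_true(is.finite(log_posterior(x$ds, tr$net, tr$alpha, tr$beta,
                                        tr$lambda, tr$kappa)))
  }
})

test_that("a two-gene three-term posterior matches full enumeration", {
  s <- rbind(c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L),
             c(0L, 0L, 1L, 0L, 1L, 1L, 1L, 0L))
  ds <- chain_dataset(s)
  alpha <- 0.4; beta <- 1.1; lambda <- 6; kappa <- 0.3
  manual <- function(a12, a21, d12, d21) {
    ll <- 0
    p <- 1 / (1 + exp(-alpha))
    for (t in 6:8) {
      H1 <- a12 * s[2, t - d12]
      H2 <- a21 * s[1, t - d21]
      for (i in 1:2) {
        H <- c(H1, H2)[i]
        ll <- ll + if (H == 0) {
          ifelse(s[i, t] == s[i, t - 1], log(p), log(1 - p))
        } else {
          beta * (2 * s[i, t] - 1) * H - log(exp(beta * H) + exp(-beta * H))
        }
      }
    }
    pri <- log_prior_row(c(0, a12), lambda, kappa) +
      log_prior_row(c(a21, 0), lambda, kappa) +
      log_prior_delay(d12, a12) + log_prior_delay(d21, a21)
    hyp <- dgamma(alpha, 1, rate = 10, log = TRUE) +
      dgamma(beta, 100, rate = 100, log = TRUE) +
      dgamma(lambda, 490, rate = 70, log = TRUE) +
      dbeta(kappa, 6, 24, log = TRUE)
    ll + pri + hyp
  }
  for (case in list(c(0, 0, 0, 0), c(1, 0, 2, 0), c(-1, 1, 1, 3))) {
    A <- matrix(c(0L, case[2], case[1], 0L), 2, 2)
    D <- matrix(c(0L, case[4], case[3], 0L), 2, 2)
    expect_equal(log_posterior(ds, grn(A, D), alpha, beta, lambda, kappa),
                 manual(case[1], case[2], case[3], case[4]))
  }
})
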