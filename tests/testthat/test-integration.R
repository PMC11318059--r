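test_that("lifetime normalisation is the affine map onto [0, 1]", {
  expect_equal(normalize_lifetime(c(5, 6)), c(0, 1))
  expect_equal(normalize_lifetime(1:4), c(0, 1, 2, 3) / 3)
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    t0 <- sample(1:100, 1)
    times <- t0 + seq_len(n) - 1
    expect_equal(normalize_lifetime(times),
                 (times - min(times)) / (max(times) - min(times)))
  }
  expect_error(normalize_lifetime(3), "length")
})

test_that("expression rates are first-order differences", {
  expect_equal(expression_rates(rep(4, 6)), rep(0, 5))
  expect_equal(expression_rates(c(1, 3, 2)), c(2, -1))
  set.seed(2)
  x <- rnorm(50)
  expect_equal(expression_rates(x), x[-1] - x[-50])
})

test_that("FMM spline interpolation is exact on polynomials up to cubics", {
  # linear input stays linear anywhere
  lin <- seq(2, 8, length.out = 5)
  expect_equal(interpolate_cell(lin, 11), seq(2, 8, length.out = 11))
  # requesting the original abscissae returns the input
  set.seed(3)
  y <- rnorm(7)
  expect_equal(interpolate_cell(y, 7), y)
  # cubic polynomials are reproduced exactly (the FMM property)
  u <- seq(0, 1, length.out = 9)
  cub <- 2 - 3 * u + 0.5 * u^2 + 4 * u^3
  v <- seq(0, 1, length.out = 23)
  expect_equal(interpolate_cell(cub, 23), 2 - 3 * v + 0.5 * v^2 + 4 * v^3,
               tolerance = 1e-10)
  # a one-point cell is replicated, with a message
  expect_message(out <- interpolate_cell(5, 4), "replicated")
  expect_equal(out, rep(5, 4))
})

test_that("the common interpolation count is the lower median", {
  expect_equal(choose_n_target(c(3, 5, 7)), 5L)
  expect_equal(choose_n_target(rep(9, 4)), 9L)
  set.seed(4)
  for (rep in 1:10) {
    counts <- sample(2:40, sample(2:9, 1), replace = TRUE)
    s <- sort(counts)
    expect_equal(choose_n_target(counts), s[ceiling(length(s) / 2)])
  }
})

test_that("binarisation thresholds at the median, ties going low", {
  expect_equal(binarize(rep(2.5, 6)), rep(0L, 6))
  expect_equal(binarize(c(-1, 0, 1)), c(0L, 0L, 1L))
  set.seed(5)
  x <- rnorm(101)
  expect_equal(binarize(x), as.integer(x > median(x)))
  # continuous i.i.d. rates come out half active
  expect_equal(mean(binarize(rnorm(10001))), 0.5, tolerance = 0.01)
  expect_equal(binarize(c(0, NA, 3), threshold = 1), c(0L, NA, 1L))
})

test_that("copy merging follows the strict-majority rule", {
  # all 8 patterns of 3 copies at one point
  pats <- expand.grid(c0 = 0:1, c1 = 0:1, c2 = 0:1)
  merged <- apply(pats, 1, function(p) merge_copies(matrix(p, ncol = 1)))
  expect_equal(merged, as.integer(rowSums(pats) >= 2))
  # two copies: a single active copy is not more than half
  expect_equal(merge_copies(matrix(c(1, 0), 2, 1)), 0L)
  expect_equal(merge_copies(matrix(c(1, 1), 2, 1)), 1L)
  # all copies missing stays missing; available copies carry the vote
  expect_equal(merge_copies(matrix(NA_integer_, 2, 1)), NA_integer_)
  expect_equal(merge_copies(matrix(c(1L, NA), 2, 1)), 1L)
  expect_equal(merge_copies(matrix(c(0L, 1L, NA), 3, 1)), 0L)
})

test_that("copy merging is permutation-invariant", {
  set.seed(6)
  for (rep in 1:20) {
    m <- matrix(sample(c(0L, 1L, NA), 4 * 7, replace = TRUE), 4, 7)
    expect_equal(merge_copies(m[sample(4), ]), merge_copies(m))
  }
})

test_that("residual missing states are imputed as low expression", {
  s <- matrix(0L, 2, 8)
  ds <- chain_dataset(s)
  expect_equal(fill_missing(ds)$states, ds$states)
  s2 <- s; s2[1, 3] <- NA
  filled <- fill_missing(chain_dataset(s2), max_missing = 0.2)
  expect_equal(unname(filled$states[1, 3]), 0L)
  expect_false(anyNA(filled$states))
  # 4% missing: every masked entry becomes 0
  set.seed(7)
  s3 <- matrix(rbinom(2 * 100, 1, 0.5), 2, 100)
  mask <- matrix(runif(200) < 0.04, 2, 100)
  s3[mask] <- NA
  f3 <- fill_missing(chain_dataset(s3), max_missing = 0.1)
  expect_equal(sum(f3$states[mask] == 0), sum(mask))
  # a gene over the cap is excluded with a warning
  s4 <- s; s4[2, 1:6] <- NA
  expect_warning(f4 <- fill_missing(chain_dataset(s4), max_missing = 0.05),
                 "exceed")
  expect_equal(nrow(f4$states), 1L)
})

test_that("the four-step pipeline integrates a toy tree as hand-computed", {
  # one gene, one copy, two cells: D (4 points) and its daughter Da (3
  # points).  Rates: D -> (2, 4, 6); Da -> (1, 1).  n_target = lower
  # median of (4, 3) = 3.  Splines through 2 or 3 points are exact at the
  # knots; D's rates at abscissae {0, 1/2, 1} resample to {2, 4, 6} at
  # {0, 1/2, 1}; Da's two rates (1, 1) resample to (1, 1, 1).  Pooled
  # median of (2, 4, 6, 1, 1, 1) = 1.5; states: D -> (1, 1, 1),
  # Da -> (0, 0, 0).
  recs <- tibble::tibble(
    gene = "gx",
    cell = c(rep("D", 4), rep("Da", 3)),
    time = c(1:4, 5:7),
    intensity = c(0, 2, 6, 12, 12, 13, 14)
  )
  ds <- integrate_subtree(recs, subtree = "D")
  expect_equal(unname(dim(ds)), c(1L, 6L))
  expect_equal(ds$points$cell, c(rep("D", 3), rep("Da", 3)))
  expect_equal(unname(ds$states[1, ]), c(1L, 1L, 1L, 0L, 0L, 0L))
  log <- attr(ds, "integration_log")
  expect_equal(log$n_target, 3L)
  expect_equal(log$threshold, 1.5)
})

test_that("merging two identical copies equals one copy", {
  set.seed(8)
  cells <- tibble::tibble(cell = c("D", "Da", "Dp"),
                          parent = c(NA, "D", "D"))
  rec <- simulate_raw_records(cells, n_points = 6, gene = "gy",
                              high_cells = "Da", seed = 9)
  one <- integrate_subtree(list(rec), subtree = "D")
  two <- integrate_subtree(list(rec, rec), subtree = "D")
  expect_identical(one$states, two$states)
})

test_that("misaligned copies come out pairwise aligned", {
  cells <- tibble::tibble(cell = c("E", "Ea", "Ep"),
                          parent = c(NA, "E", "E"))
  # same biology, different lifetimes per file
  c1 <- simulate_raw_records(cells, n_points = c(E = 8, Ea = 12, Ep = 6),
                             gene = "gz", high_cells = "Ea", seed = 10)
  c2 <- simulate_raw_records(cells, n_points = c(E = 5, Ea = 7, Ep = 9),
                             gene = "gz", high_cells = "Ea", seed = 11)
  ds <- integrate_subtree(list(c1, c2), subtree = "E")
  # every cell contributes exactly n_target points
  counts <- table(ds$points$cell)
  expect_true(all(counts == attr(ds, "integration_log")$n_target))
  expect_false(anyNA(ds$states))
  # the active cell is called active, the low cells mostly not
  expect_true(mean(ds$states[1, ds$points$cell == "Ea"]) > 0.8)
  expect_true(mean(ds$states[1, ds$points$cell == "Ep"]) < 0.2)
})
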