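#' Simulation configuration
#'
#' Dimensions of a synthetic subtree dataset: number of genes, number of
#' cells (grown as a balanced binary lineage tree) and interpolation points
#' per cell.  `make_table1_config()` returns the dimensions of the five
#' real candidate subtree datasets, which the simulation study mirrors.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_cells Number of cells (>= 1).
#' @param inters Interpolation points per cell (>= 6; the maximum delay of
#'   5 time units requires at least a 6-point history).
#' @param subtree Optional label carried into the dataset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes, n_cells, inters, subtree = NA_character_) {
  if (n_genes < 2) abort("`n_genes` must be at least 2.")
  if (n_cells < 1) abort("`n_cells` must be at least 1.")
  if (inters < 6) {
    abort("`inters` must be at least 6 (maximum delay is 5 time units).")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells),
                 inters = as.integer(inters),
                 subtree = subtree),
            class = "sim_config")
}

# Candidate-dataset dimensions of the five founder subtrees
subtree_dims <- tibble(
  subtree = c("AB", "C", "D", "E", "MS"),
  n_genes = c(27L, 30L, 20L, 40L, 29L),
  n_cells = c(112L, 51L, 12L, 26L, 80L),
  inters  = c(24L, 20L, 28L, 16L, 22L)
)

#' @rdname sim_config
#' @export
make_table1_config <- function(subtree) {
  row <- subtree_dims[subtree_dims$subtree == subtree, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown subtree '", subtree,
                 "'; expected one of AB, C, D, E, MS."))
  }
  sim_config(row$n_genes, row$n_cells, row$inters, subtree = subtree)
}

#' Draw a ground-truth network and parameters from the priors
#'
#' Two-stage draw of each adjacency row from the sparsity prior: empty with
#' probability `kappa`, otherwise an in-degree from the truncated
#' exponential, a uniformly chosen regulator set and independent uniform
#' signs.  Delays come from the flat prior on present edges and the
#' spike-and-slab on absent ones; `alpha`, `beta`, `lambda`, `kappa` from
#' [hyper_priors].
#'
#' @param n_genes Number of genes.
#' @param seed Optional integer seed.
#' @return A list with elements `net` (a [grn]), `alpha`, `beta`, `lambda`,
#'   `kappa`.
#' @export
draw_truth <- function(n_genes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hp <- hyper_priors
  kappa <- rbeta(1, hp$kappa[1], hp$kappa[2])
  lambda <- rgamma(1, hp$lambda[1], rate = hp$lambda[2])
  alpha <- rgamma(1, hp$alpha[1], rate = hp$alpha[2])
  beta <- rgamma(1, hp$beta[1], rate = hp$beta[2])
  N <- as.integer(n_genes)
  A <- matrix(0L, N, N)
  delta <- matrix(0L, N, N)
  px <- exp(-lambda * (1:(N - 1)))     # truncated-exponential in-degree
  px <- px / sum(px)
  for (i in seq_len(N)) {
    if (runif(1) < kappa) next
    x <- sample.int(N - 1, 1, prob = px)
    regs <- setdiff(seq_len(N), i)
    regulators <- regs[sample.int(length(regs), x)]
    A[i, regulators] <- sample(c(-1L, 1L), x, replace = TRUE)
  }
  off <- which(row(A) != col(A))
  present <- off[A[off] != 0]
  absent <- off[A[off] == 0]
  delta[present] <- sample(0:5, length(present), replace = TRUE)
  delta[absent] <- sample(0:5, length(absent), replace = TRUE,
                          prob = c(0.999, rep(2e-04, 5)))
  list(net = grn(A, delta), alpha = alpha, beta = beta,
       lambda = lambda, kappa = kappa)
}

# Static update order for zero-delay regulation: topological order of the
# zero-delay subgraph (edge j -> i where A[i,j] != 0 and delta[i,j] == 0),
# ties and cycle-breaking by a seeded random preference.  Returns integer
# positions; a zero-delay regulator is read at its current-slice value iff
# its position precedes the target's.
delay0_positions <- function(A, delta) {
  N <- nrow(A)
  tie <- sample.int(N)
  M <- (A != 0) & (delta == 0)      # M[i, j]: zero-delay edge j -> i
  diag(M) <- FALSE
  indeg <- rowSums(M)
  remaining <- rep(TRUE, N)
  pos <- integer(N)
  for (step in seq_len(N)) {
    avail <- which(remaining & indeg == 0)
    g <- if (length(avail) > 0) {
      avail[which.min(tie[avail])]
    } else {
      # zero-delay cycle: break it at the preferred node, whose unresolved
      # inputs will be read at lag 1
      rem <- which(remaining)
      rem[which.min(tie[rem])]
    }
    pos[g] <- step
    remaining[g] <- FALSE
    hit <- which(remaining & M[, g])
    indeg[hit] <- indeg[hit] - 1L
  }
  pos
}

# Balanced binary lineage tree with Sulston-style synthetic names: root
# `label`, daughters append "a"/"p"; cells added in breadth-first (heap)
# order until n_cells.
balanced_lineage <- function(n_cells, label = "Z") {
  names <- character(n_cells)
  parent <- character(n_cells)
  names[1] <- label
  parent[1] <- NA_character_
  for (i in seq_len(n_cells)[-1]) {
    p <- i %/% 2L
    names[i] <- paste0(names[p], if (i %% 2L == 0L) "a" else "p")
    parent[i] <- names[p]
  }
  tibble(cell = names, parent = parent)
}

#' Simulate a binary subtree dataset from the model
#'
#' Generates states forward along the lineage: the first five points of the
#' root cell are initialised i.i.d. Bernoulli(1/2) per gene (the likelihood
#' never conditions on them), and every later point is emitted from the
#' persistence law (zero input) or the Boltzmann transition law (nonzero
#' input), with lagged regulator states resolved through the lineage path
#' so that both daughters of a division inherit the mother's history.
#' Zero-delay edges inside one time slice are resolved by updating genes in
#' a topological order of the zero-delay subgraph (ties and cycles broken
#' by a seeded random permutation, fixed for the whole dataset): a
#' zero-delay regulator that precedes its target is read at its
#' current-slice value, exactly as the likelihood conditions on it, so the
#' simulator realises the model whenever the zero-delay subgraph is
#' acyclic; only inside a genuine zero-delay cycle does a regulator fall
#' back to its lag-1 value.
#'
#' @param truth A list as from [draw_truth()] (elements `net`, `alpha`,
#'   `beta`).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A [subtree_dataset] with no missing values.
#' @export
simulate_dataset <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth$net$A) != config$n_genes) {
    abort("truth network size does not match `config$n_genes`.")
  }
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_genes
  cells <- balanced_lineage(config$n_cells,
                            label = if (is.na(config$subtree)) "Z"
                                    else config$subtree)
  pts <- lineage_points(cells, config$inters)
  Tn <- nrow(pts)
  A <- truth$net$A
  delta <- truth$net$delta
  Am <- lapply(1:5, function(m) A * (delta == m))
  has_lag0 <- which(rowSums(A != 0 & delta == 0) > 0)
  no_lag0 <- setdiff(seq_len(N), has_lag0)
  lag0_regs <- lapply(seq_len(N), function(g) {
    which(A[g, ] != 0 & delta[g, ] == 0)
  })
  p_keep <- plogis(truth$alpha)
  s <- matrix(NA_integer_, N, Tn, dimnames = list(rownames(A), NULL))
  # lag lookup built directly from pred links
  pred <- pts$pred
  li <- matrix(NA_integer_, Tn, 6L)
  li[, 1] <- seq_len(Tn)
  for (m in 1:5) {
    ok <- !is.na(li[, m])
    li[ok, m + 1L] <- pred[li[ok, m]]
  }
  root_init <- pts$point[pts$cell %in% cells$cell[is.na(cells$parent)] &
                           pts$k <= 5L]
  pos <- delay0_positions(A, delta)
  lag0_order <- has_lag0[order(pos[has_lag0])]
  use_m <- which(vapply(1:5, function(m) any(Am[[m]] != 0), logical(1)))
  for (t in seq_len(Tn)) {
    if (t %in% root_init) {
      s[, t] <- rbinom(N, 1L, 0.5)
      next
    }
    sl1 <- s[, li[t, 2L]]
    Hbase <- numeric(N)
    for (m in use_m) {
      Hbase <- Hbase + drop(Am[[m]] %*% s[, li[t, m + 1L]])
    }
    u <- runif(N)
    s_new <- integer(N)
    if (length(no_lag0) > 0) {
      H <- Hbase[no_lag0]
      keep <- ifelse(u[no_lag0] < p_keep, sl1[no_lag0], 1L - sl1[no_lag0])
      fire <- as.integer(u[no_lag0] < plogis(2 * truth$beta * H))
      s_new[no_lag0] <- ifelse(H == 0, keep, fire)
    }
    for (g in lag0_order) {
      regs <- lag0_regs[[g]]
      eff <- ifelse(pos[regs] < pos[g], s_new[regs], sl1[regs])
      H <- Hbase[g] + sum(A[g, regs] * eff)
      s_new[g] <- if (H == 0) {
        if (u[g] < p_keep) sl1[g] else 1L - sl1[g]
      } else {
        as.integer(u[g] < plogis(2 * truth$beta * H))
      }
    }
    s[, t] <- s_new
  }
  subtree_dataset(s, pts, roots = cells$cell[is.na(cells$parent)],
                  subtree = config$subtree)
}

#' Synthesise raw embryo-style records for pipeline tests
#'
#' Emulates the raw fluorescence files on a small lineage: each cell
#' carries a constant target expression rate (high in `high_cells`, low
#' elsewhere) plus Gaussian noise, and the recorded intensity is the
#' cumulative sum of those rates -- monotone-ish traces like real
#' fluorescence.  Copies with different `n_points` per cell emulate the
#' misaligned lifetimes that make raw files non-pairwise.
#'
#' @param cells Data frame with `cell` and `parent` columns.
#' @param n_points Points per cell: scalar or vector named by cell.
#' @param gene Gene name for the records.
#' @param high_cells Cells in which the gene is actively expressed.
#' @param rate_high,rate_low Mean expression rate in active/inactive cells.
#' @param noise_sd Gaussian noise on the per-step rates.
#' @param seed Optional integer seed.
#' @return A tibble with columns `gene`, `cell`, `time`, `intensity`.
#' @export
simulate_raw_records <- function(cells, n_points, gene = "geneX",
                                 high_cells = character(), rate_high = 5,
                                 rate_low = 0.5, noise_sd = 0.1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- as_tibble(cells)
  if (length(n_points) == 1L) {
    n_points <- setNames(rep(as.integer(n_points), nrow(cells)), cells$cell)
  }
  pts <- lineage_points(cells, n_points)
  start <- numeric(nrow(cells)); names(start) <- cells$cell
  recs <- vector("list", nrow(cells))
  for (ci in order(match(cells$cell, unique(pts$cell)))) {
    cl <- cells$cell[ci]
    np <- as.integer(n_points[[cl]])
    base_rate <- if (cl %in% high_cells) rate_high else rate_low
    rates <- base_rate + stats::rnorm(np - 1L, sd = noise_sd)
    par <- cells$parent[ci]
    t0 <- if (is.na(par)) 1L else max(recs[[match(par, cells$cell)]]$time) + 1L
    base <- if (is.na(par)) 0 else start[[par]]
    intensity <- base + cumsum(c(abs(stats::rnorm(1, sd = noise_sd)), rates))
    start[[cl]] <- intensity[np]
    recs[[ci]] <- tibble(gene = gene, cell = cl,
                         time = t0 + seq_len(np) - 1L,
                         intensity = intensity)
  }
  bind_rows(recs)
}
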