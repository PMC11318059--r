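# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files are read.

# single-cell chain dataset: one root cell with `n` points, states given
# per gene as a matrix (genes x n)
chain_dataset <- function(states) {
  states <- rbind(states)
  pts <- tibble::tibble(point = seq_len(ncol(states)), cell = "Z",
                        k = seq_len(ncol(states)),
                        pred = c(NA, seq_len(ncol(states) - 1L)))
  subtree_dataset(states, pts, roots = "Z")
}

# three-cell lineage (root Z with daughters Za, Zp), `k` points per cell
branching_dataset <- function(states, k) {
  cells <- tibble::tibble(cell = c("Z", "Za", "Zp"),
                          parent = c(NA, "Z", "Z"))
  pts <- lineage_points(cells, k)
  subtree_dataset(rbind(states), pts, roots = "Z")
}

# random small dataset simulated from a prior draw
random_dataset <- function(n_genes = 3, n_cells = 3, inters = 8,
                           seed = 1) {
  set.seed(seed)
  truth <- draw_truth(n_genes)
  list(truth = truth,
       ds = simulate_dataset(truth, sim_config(n_genes, n_cells, inters)))
}

# independent two-sided Fisher p by full enumeration of the joint binomial
# table space is not needed: with margins fixed the null law is
# hypergeometric; enumerate it directly and sum the tail of tables no more
# probable than the observed one.
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[2, ]); r0 <- sum(tab[1, ]); c1 <- sum(tab[, 2])
  support <- max(0, c1 - r0):min(c1, r1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(r0, c1 - x) / choose(r1 + r0, c1)
  }, numeric(1))
  obs <- probs[match(tab[2, 2], support)]
  sum(probs[probs <= obs * (1 + 1e-07)])
}
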