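# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: patristic distances are brute-force path sums
# over the explicit parent chain, and Mann-Whitney p-values are full
# enumerations over all choose(n1+n2, n1) group assignments.

# Brute-force patristic distance between two tips by walking parent chains.
bf_patristic <- function(tree, tip1, tip2) {
  parent <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- rep(NA_real_, length(parent))
  elen[tree$edge[, 2L]] <- tree$edge.length
  chain <- function(tip) {
    nodes <- tip
    while (!is.na(parent[nodes[length(nodes)]]))
      nodes <- c(nodes, parent[nodes[length(nodes)]])
    nodes
  }
  i1 <- match(tip1, tree$tip.label)
  i2 <- match(tip2, tree$tip.label)
  c1 <- chain(i1); c2 <- chain(i2)
  mrca <- intersect(c1, c2)[1L]
  sum(elen[c1[seq_len(which(c1 == mrca) - 1L)]]) +
    sum(elen[c2[seq_len(which(c2 == mrca) - 1L)]])
}

# Exhaustive two-sided Mann-Whitney p-value: probability, over every
# assignment of the pooled ranks to group 1, of a U at least as far from
# n1*n2/2 as the observed U.
bf_mw_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (N - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(N, n1), 2L,
              function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random tree with unique alphanumeric tip labels and positive lengths.
random_test_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE,
                   tip.label = paste0("t", seq_len(n), "_sp", seq_len(n)))
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.01, 2), 6)
  tr
}

trees_isomorphic <- function(t1, t2) {
  isTRUE(ape::all.equal.phylo(t1, t2, use.edge.length = TRUE))
}
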