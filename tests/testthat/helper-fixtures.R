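# Shared fixtures and independent oracles used across test files.

# two 3-gene blocks: within-block r = 0.9, between-block r = 0.2
block_corr <- function() {
  r <- matrix(0.2, 6, 6)
  r[1:3, 1:3] <- 0.9
  r[4:6, 4:6] <- 0.9
  diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("g", 1:6)
  r
}

named_graph <- function(edges) {
  igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
}

# brute-force IC oracle: enumerate all size-k subsets of the other nodes of
# v's component and count those with at least x seeds
ic_brute_force <- function(net, seeds) {
  nodes <- igraph::V(net)$name
  comp <- igraph::components(net)
  vapply(seq_along(nodes), function(i) {
    members <- which(comp$membership == comp$membership[i])
    others <- setdiff(nodes[members], nodes[i])
    nb <- igraph::neighbors(net, nodes[i])$name
    k <- length(nb)
    x <- sum(nb %in% seeds)
    if (k == 0) return(1)
    subsets <- utils::combn(others, k)
    hits <- apply(subsets, 2, function(s) sum(s %in% seeds) >= x)
    mean(hits)
  }, numeric(1))
}

# exhaustive overlap oracle: enumerate all draws of |B| from the universe
# and count overlaps with A at least (greater) / at most (less) observed
overlap_brute_force <- function(set_a, set_b, universe, alternative) {
  k_obs <- length(intersect(set_a, set_b))
  draws <- utils::combn(universe, length(set_b))
  ks <- apply(draws, 2, function(s) length(intersect(s, set_a)))
  if (alternative == "greater") mean(ks >= k_obs) else mean(ks <= k_obs)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# random DEG panel where tissue t has m significant slots per direction
small_deg_panel <- function(n_tissues = 10, n_genes = 100, m = 10, seed = 42) {
  sig <- stats::setNames(rep(m, n_tissues), sprintf("t%02d", seq_len(n_tissues)))
  gen_deg_tables(n_genes, sig, sig, seed = seed)
}
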