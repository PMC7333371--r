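star5 <- function() {
  g <- igraph::make_star(5, mode = "undirected")
  igraph::V(g)$name <- c("hub", "l1", "l2", "l3", "l4")
  g
}

test_that("centralities match closed forms on star, path and triangle", {
  st <- compute_topology(star5(), seeds = "l1")
  expect_equal(st$bc[st$node == "hub"], 1)
  expect_equal(st$bc[st$node != "hub"], rep(0, 4))
  expect_equal(st$cc[st$node == "hub"], 1)

  pg <- named_graph(rbind(c("a", "b"), c("b", "c")))
  pt <- compute_topology(pg, seeds = "a")
  expect_equal(pt$bc[pt$node == "b"], 1)
  expect_equal(pt$bc[pt$node %in% c("a", "c")], c(0, 0))
  expect_equal(pt$cc[pt$node == "a"], 2 / 3)
  expect_equal(pt$local_cc[pt$node == "b"], 0)

  tg <- named_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  tt <- compute_topology(tg, seeds = "a")
  expect_equal(tt$local_cc, rep(1, 3))
  expect_true(all(tt$bc >= 0 & tt$bc <= 1 & tt$cc >= 0 & tt$cc <= 1))
  expect_equal(sum(tt$degree), 2 * igraph::ecount(tg))
})

test_that("betweenness and closeness stay within components", {
  g <- named_graph(rbind(c("a", "b"), c("b", "c"), c("x", "y")))
  tp <- compute_topology(g, seeds = "a")
  # two-node satellite: no pairs to mediate, distance 1 to the only neighbor
  expect_equal(tp$bc[tp$node == "x"], 0)
  expect_equal(tp$cc[tp$node == "x"], 1)
  expect_equal(tp$component[tp$node == "y"], tp$component[tp$node == "x"])
})

test_that("network density matches counts", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(network_density(k4), 1)
  pg <- named_graph(rbind(c("a", "b"), c("b", "c")))
  expect_equal(network_density(pg), 2 / 3)
  g6 <- named_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                          c("d", "e"), c("e", "f"), c("f", "d")))
  expect_equal(network_density(g6), 6 / 15)
  expect_error(network_density(igraph::make_empty_graph(1)), "nodes")
})

test_that("power-law fit recovers an exact log-log line and rejects degenerates", {
  freq <- stats::setNames(64 * c(1, 2, 4, 8)^(-2), c(1, 2, 4, 8))
  fit <- fit_power_law(freq)
  expect_equal(fit$b, -2, tolerance = 1e-12)
  expect_equal(fit$a, 64, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- letters[1:10]
  expect_error(fit_power_law(ring), "distinct degrees")
})

test_that("IC p-values follow the hypergeometric closed form", {
  # n1 adjacent to the three seeds; n2 attached to a seed to stay connected
  g <- named_graph(rbind(c("n1", "s1"), c("n1", "s2"), c("n1", "s3"),
                         c("n2", "s1")))
  ic <- ic_pvalues(g, c("s1", "s2", "s3"))
  expect_equal(ic$ic_p[ic$node == "n1"], 0.25)  # C(3,3)C(1,0)/C(4,3)
  # zero seed neighbours -> sure event
  g2 <- named_graph(rbind(c("s1", "a"), c("a", "b")))
  ic2 <- ic_pvalues(g2, "s1")
  expect_equal(ic2$ic_p[ic2$node == "b"], 1)
  expect_error(ic_pvalues(g, character(0)), "seed")
})

test_that("IC closed form equals exhaustive enumeration on small graphs", {
  set.seed(404)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    g <- igraph::sample_gnp(n, 0.5)
    igraph::V(g)$name <- paste0("v", seq_len(n))
    seeds <- sample(igraph::V(g)$name, sample(1:3, 1))
    got <- ic_pvalues(g, seeds)
    want <- ic_brute_force(g, seeds)
    expect_equal(got$ic_p, want, tolerance = 1e-12)
    expect_true(all(got$ic_p_adj >= got$ic_p - 1e-15))
  }
})

test_that("planted high-IC node attains the top adjusted IC p", {
  top <- vapply(1:20, function(s) {
    net <- gen_scalefree_graph(150, 3, seed_fraction = 0.15,
                               plant_seed_hub = TRUE, seed = s)
    ic <- ic_pvalues(net$graph, net$seeds)
    ic$node[which.min(ic$ic_p_adj)] == net$planted_hub
  }, logical(1))
  expect_gte(mean(top), 0.95)
})

test_that("candidate ranking applies the two-tier rule and flags", {
  report <- structure(data.frame(
    node = sprintf("v%03d", 1:100),
    degree = c(100, 100, rep(1, 98)),
    bc = c(1, 1, rep(0, 98)),
    cc = c(0.2, 0.2, seq(0.9, 0.1, length.out = 98)),
    local_cc = 0, ic_p = 1, ic_p_adj = 1,
    is_seed = c(TRUE, rep(FALSE, 99)),
    component = 1, pct_degree = 0, pct_bc = 0, pct_cc = 0,
    stringsAsFactors = FALSE
  ), class = c("topology_report", "data.frame"))
  cand <- rank_candidates(report)
  # v001 and v002 are top 1% (ceiling rule) in degree and bc
  expect_true(all(c("v001", "v002") %in% cand$node))
  # top 1% in degree only, no IC -> excluded
  report2 <- report
  report2$bc <- seq(0, 0.99, length.out = 100)
  report2$cc <- seq(0, 1, length.out = 100)
  report2$degree <- c(100, rep(1, 99))
  cand2 <- rank_candidates(report2)
  expect_false("v001" %in% cand2$node)
  # significant IC plus one second-tier membership qualifies
  report3 <- report2
  report3$ic_p_adj[1] <- 0.001
  expect_true("v001" %in% rank_candidates(report3)$node)
  # novel_only drops qualifying seeds
  expect_false("v001" %in% rank_candidates(report, novel_only = TRUE)$node)
  expect_true("v002" %in% rank_candidates(report, novel_only = TRUE)$node)
  expect_error(rank_candidates(report, top_pct = 0), "percentile")
})

test_that("candidate ranking is invariant to node relabelling", {
  net <- gen_scalefree_graph(100, 3, seed_fraction = 0.2,
                             plant_seed_hub = TRUE, seed = 2)
  topo <- compute_topology(net$graph, net$seeds)
  cand <- rank_candidates(topo)
  perm <- sample(igraph::vcount(net$graph))
  g2 <- igraph::permute(net$graph, perm)
  topo2 <- compute_topology(g2, net$seeds)
  cand2 <- rank_candidates(topo2)
  expect_setequal(cand$node, cand2$node)
})

test_that("module detection recovers cliques and respects the size filter", {
  clique_edges <- function(nodes) t(utils::combn(nodes, 2))
  two <- named_graph(rbind(clique_edges(paste0("a", 1:5)),
                           clique_edges(paste0("b", 1:5)),
                           c("a1", "b1")))
  part <- detect_modules(two)
  expect_equal(sort(part$sizes, decreasing = TRUE), c(5L, 5L))
  expect_equal(length(unique(part$membership[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(part$membership[paste0("b", 1:5)])), 1)

  one <- named_graph(clique_edges(paste0("c", 1:6)))
  p1 <- detect_modules(one)
  expect_equal(p1$sizes, 6L)
  expect_length(p1$unassigned, 0)

  p_empty <- detect_modules(one, min_size_fraction = 2)
  expect_length(p_empty$sizes, 0)
  expect_length(p_empty$unassigned, 6)
  expect_error(detect_modules(one, lambda = 0), "lambda")
})

test_that("module detection returns disjoint cliques exactly", {
  clique_edges <- function(nodes) t(utils::combn(nodes, 2))
  g <- named_graph(rbind(clique_edges(paste0("a", 1:4)),
                         clique_edges(paste0("b", 1:6)),
                         clique_edges(paste0("c", 1:5))))
  part <- detect_modules(g)
  expect_equal(sort(part$sizes), c(4L, 5L, 6L))
  for (pref in c("a", "b", "c")) {
    ids <- part$membership[grep(pref, names(part$membership))]
    expect_equal(length(unique(ids)), 1)
  }
})
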