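# Topological statistics of seed-gene networks: degree, pair-normalised
# betweenness, closeness as reciprocal mean distance, local clustering,
# hypergeometric increased-connectivity (IC) p-values against the seed set,
# power-law fit of the degree distribution, ECV-based module detection, and
# the candidate-regulator ranking rule built on top of all of these.

#' Per-node topology report
#'
#' Computes, per node and within its connected component: degree;
#' betweenness centrality normalised by the number of node pairs
#' \code{(n-1)(n-2)/2} so it lies in \code{[0, 1]}; closeness centrality as
#' the reciprocal of the mean shortest-path distance to the other reachable
#' nodes (higher = more central; isolated nodes get 0); the local
#' clustering coefficient (0 for degree < 2); and the hypergeometric
#' increased-connectivity p-value against the seed set (see
#' \code{\link{ic_pvalues}}), BH-adjusted across all nodes. Percentile
#' ranks (0-100, fraction of nodes with a value at or below the node's) are
#' attached for degree, betweenness and closeness.
#'
#' @param net An \pkg{igraph} undirected simple graph with named vertices.
#' @param seeds Character vector of seed gene symbols.
#' @return A \code{data.frame} of class \code{topology_report} with columns
#'   \code{node}, \code{degree}, \code{bc}, \code{cc}, \code{local_cc},
#'   \code{ic_p}, \code{ic_p_adj}, \code{is_seed}, \code{component},
#'   \code{pct_degree}, \code{pct_bc}, \code{pct_cc}.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::V(g)$name <- letters[1:5]
#' compute_topology(g, seeds = "b")
#' @export
compute_topology <- function(net, seeds) {
  if (igraph::vcount(net) == 0) stop_input("empty network")
  seeds <- clean_symbols(seeds)
  nodes <- igraph::V(net)$name
  comp <- igraph::components(net)
  comp_size <- comp$csize[comp$membership]
  deg <- igraph::degree(net)

  bc_raw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  pairs <- (comp_size - 1) * (comp_size - 2) / 2
  bc <- ifelse(pairs > 0, bc_raw / pairs, 0)

  d <- igraph::distances(net)
  cc <- vapply(seq_along(nodes), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else 1 / mean(di)
  }, numeric(1))

  local_cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  local_cc[deg < 2] <- 0

  ic <- ic_pvalues(net, seeds)

  pct <- function(x) 100 * vapply(x, function(v) mean(x <= v), numeric(1))
  out <- data.frame(
    node = nodes,
    degree = as.integer(deg),
    bc = bc,
    cc = cc,
    local_cc = local_cc,
    ic_p = ic$ic_p,
    ic_p_adj = ic$ic_p_adj,
    is_seed = nodes %in% seeds,
    component = comp$membership,
    pct_degree = pct(deg),
    pct_bc = pct(bc),
    pct_cc = pct(cc),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("topology_report", "data.frame")
  out
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("Topology report: %d nodes (%d seeds), %d components\n",
              nrow(x), sum(x$is_seed), length(unique(x$component))))
  cat(sprintf("  significant IC (adj p < 0.05): %d nodes\n",
              sum(x$ic_p_adj < 0.05)))
  print.data.frame(utils::head(as.data.frame(x)[order(-x$bc), ], 6),
                   digits = 4)
  invisible(x)
}

#' Network density
#'
#' Fraction of realised edges among all node pairs: \code{2E / (N (N - 1))}.
#'
#' @param net An \pkg{igraph} graph with at least two nodes.
#' @return Density in \code{[0, 1]}.
#' @export
network_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop_input("density needs >= 2 nodes")
  2 * igraph::ecount(net) / (n * (n - 1))
}

#' Log-log least-squares fit of the degree distribution to a power law
#'
#' Fits \code{frequency = a * degree^b} by least squares on the
#' (log degree, log frequency) points over degrees >= 1 with frequency
#' >= 1, the convention of network-analysis topology tools. A negative
#' exponent with a strong log-log correlation indicates scale-free
#' structure.
#'
#' @param net An \pkg{igraph} graph, or a named numeric vector of degree
#'   frequencies (names = degree values).
#' @return Object of class \code{powerlaw_fit}: list with \code{a} (scale),
#'   \code{b} (exponent), \code{corr_loglog}, \code{r_squared},
#'   \code{n_points}.
#' @export
fit_power_law <- function(net) {
  freq <- if (inherits(net, "igraph")) {
    tab <- table(igraph::degree(net))
    setNames(as.numeric(tab), names(tab))
  } else {
    net
  }
  k <- as.numeric(names(freq))
  keep <- k >= 1 & freq >= 1
  k <- k[keep]
  f <- as.numeric(freq[keep])
  if (length(unique(k)) < 3) {
    stop_input("power-law fit needs >= 3 distinct degrees with nonzero frequency")
  }
  lx <- log(k)
  ly <- log(f)
  fit <- lm(ly ~ lx)
  r <- cor(lx, ly)
  structure(list(a = exp(coef(fit)[[1]]), b = coef(fit)[[2]],
                 corr_loglog = r, r_squared = r^2, n_points = length(k)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit f(k) = %.4g * k^%.4g over %d degree values\n",
              x$a, x$b, x$n_points))
  cat(sprintf("  log-log correlation %.3f, R-squared %.3f\n",
              x$corr_loglog, x$r_squared))
  invisible(x)
}

#' Increased-connectivity p-values against a seed set
#'
#' For a node v with k neighbours of which x are seeds, the IC p-value is
#' the one-sided hypergeometric upper tail P(X >= x) for drawing k
#' neighbours from the other N - 1 nodes of v's connected component, of
#' which K are seeds (v itself excluded from the seed count when it is a
#' seed). A small p flags a node whose neighbourhood is overrepresented in
#' seed genes relative to chance. BH adjustment is applied across all
#' nodes of the network.
#'
#' @param net An \pkg{igraph} undirected simple graph with named vertices.
#' @param seeds Character vector of seed symbols; must be a subset of the
#'   node set and non-empty.
#' @return \code{data.frame} with columns \code{node}, \code{k},
#'   \code{x_seed}, \code{ic_p}, \code{ic_p_adj}.
#' @export
ic_pvalues <- function(net, seeds) {
  seeds <- clean_symbols(seeds)
  nodes <- igraph::V(net)$name
  if (length(seeds) == 0) stop_input("empty seed set")
  if (!all(seeds %in% nodes)) {
    stop_input("seeds not in network: %s",
               paste(utils::head(setdiff(seeds, nodes), 5), collapse = ", "))
  }
  comp <- igraph::components(net)
  is_seed <- nodes %in% seeds
  adj <- igraph::adjacent_vertices(net, nodes)
  p <- vapply(seq_along(nodes), function(i) {
    members <- comp$membership == comp$membership[i]
    N <- sum(members)
    K <- sum(is_seed & members) - (is_seed[i])
    nb <- adj[[i]]$name
    k <- length(nb)
    x <- sum(nb %in% seeds)
    # P(X >= x) drawing k from N-1 nodes of which K seeds
    phyper(x - 1, K, (N - 1) - K, k, lower.tail = FALSE)
  }, numeric(1))
  data.frame(node = nodes, k = igraph::degree(net),
             x_seed = vapply(adj, function(v) sum(v$name %in% seeds),
                             numeric(1)),
             ic_p = p, ic_p_adj = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank candidate regulators from a topology report
#'
#' A node qualifies when it sits in the top \code{top_pct}\% of at least
#' two of degree, betweenness and closeness, or when its adjusted IC
#' p-value is below \code{ic_alpha} and it additionally sits in the top
#' \code{second_pct}\% of at least one of the three centralities.
#' Candidates are ordered by the number of qualifying criteria (top-tier
#' memberships plus significant IC), then by betweenness descending, then
#' by node label. Seeds are flagged; \code{novel_only = TRUE} drops them.
#'
#' @param report A \code{\link{compute_topology}} result.
#' @param top_pct Primary percentile tier (default 1).
#' @param second_pct Secondary tier used with significant IC (default 5).
#' @param ic_alpha Adjusted-p cutoff for IC significance (default 0.05).
#' @param novel_only Drop seed nodes from the output.
#' @return \code{data.frame} of candidates with per-criterion flags,
#'   ordered as described.
#' @export
rank_candidates <- function(report, top_pct = 1, second_pct = 5,
                            ic_alpha = 0.05, novel_only = FALSE) {
  for (p in c(top_pct, second_pct)) {
    if (p <= 0 || p >= 100) stop_input("percentile tiers must lie in (0, 100)")
  }
  n <- nrow(report)
  top_set <- function(x, pct) {
    # top pct% by value: ranks from the top, ties share the better rank
    rk <- rank(-x, ties.method = "min")
    rk <= ceiling(pct / 100 * n)
  }
  t1_deg <- top_set(report$degree, top_pct)
  t1_bc <- top_set(report$bc, top_pct)
  t1_cc <- top_set(report$cc, top_pct)
  t2_any <- top_set(report$degree, second_pct) |
    top_set(report$bc, second_pct) | top_set(report$cc, second_pct)
  ic_sig <- report$ic_p_adj < ic_alpha
  n_top <- t1_deg + t1_bc + t1_cc
  qualifies <- (n_top >= 2) | (ic_sig & t2_any)
  out <- data.frame(
    node = report$node,
    degree_top = t1_deg, bc_top = t1_bc, cc_top = t1_cc,
    ic_significant = ic_sig,
    n_criteria = n_top + ic_sig,
    bc = report$bc,
    is_seed = report$is_seed,
    stringsAsFactors = FALSE
  )[qualifies, , drop = FALSE]
  if (novel_only) out <- out[!out$is_seed, , drop = FALSE]
  out <- out[order(-out$n_criteria, -out$bc, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# edge clustering value of edge (u, v): squared common-neighbour count over
# the product of the out-of-edge neighbourhood sizes
ecv_values <- function(adj, from, to) {
  vapply(seq_along(from), function(i) {
    nu <- adj[[from[i]]]
    nv <- adj[[to[i]]]
    du <- length(setdiff(nu, to[i]))
    dv <- length(setdiff(nv, from[i]))
    if (du == 0 || dv == 0) return(0)
    length(intersect(nu, nv))^2 / (du * dv)
  }, numeric(1))
}

#' Detect network modules by edge-clustering agglomeration
#'
#' Fully specified agglomerative clustering driven by the edge clustering
#' value ECV(u, v) = |N(u) n N(v)|^2 / (|N(u) \\ v| |N(v) \\ u|). Edges are
#' processed in decreasing ECV (ties by lexicographic endpoints). An edge
#' joins an unassigned endpoint to the other endpoint's cluster (or starts
#' a new cluster when both are unassigned); an edge between two existing
#' clusters merges them only when the merged cluster is weak in the
#' Radicchi sense at scale \code{lambda}: total internal degree times
#' \code{lambda / 2} exceeds total external degree (at the default
#' \code{lambda = 2} this is the plain Radicchi weak criterion). Edges with
#' ECV = 0 carry no shared-neighbourhood evidence and are never used to
#' merge two already-formed clusters. Clusters smaller than
#' \code{min_size_fraction * N} are discarded.
#'
#' @param net An \pkg{igraph} undirected simple graph with named vertices.
#' @param lambda Weak-cluster scale (> 0), default 2.
#' @param min_size_fraction Minimum module size as a fraction of the node
#'   count, default 0.01.
#' @return List of class \code{module_partition}: \code{membership} (named
#'   module id per assigned node), \code{sizes}, \code{unassigned}.
#' @export
detect_modules <- function(net, lambda = 2, min_size_fraction = 0.01) {
  if (lambda <= 0) stop_input("'lambda' must be > 0")
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  # canonical order within and across edges for deterministic ties
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  adj <- lapply(igraph::adjacent_vertices(net, nodes), function(v) v$name)
  names(adj) <- nodes
  ecv <- ecv_values(adj, el[, 1], el[, 2])
  ord <- order(-ecv, el[, 1], el[, 2])
  el <- el[ord, , drop = FALSE]
  ecv <- ecv[ord]

  cluster_of <- setNames(rep(NA_integer_, length(nodes)), nodes)
  members <- list()
  deg <- setNames(as.integer(igraph::degree(net)), nodes)
  internal_deg <- function(cl) {
    # total internal degree = 2 * internal edge count
    sum(vapply(cl, function(v) sum(adj[[v]] %in% cl), numeric(1)))
  }
  for (i in seq_len(nrow(el))) {
    u <- el[i, 1]; v <- el[i, 2]
    cu <- cluster_of[[u]]; cv <- cluster_of[[v]]
    if (is.na(cu) && is.na(cv)) {
      id <- length(members) + 1L
      members[[id]] <- c(u, v)
      cluster_of[c(u, v)] <- id
    } else if (is.na(cu) || is.na(cv)) {
      id <- if (is.na(cu)) cv else cu
      new <- if (is.na(cu)) u else v
      members[[id]] <- c(members[[id]], new)
      cluster_of[[new]] <- id
    } else if (cu != cv) {
      if (ecv[i] == 0) next
      merged <- c(members[[cu]], members[[cv]])
      int_d <- internal_deg(merged)
      ext_d <- sum(deg[merged]) - int_d
      if (int_d * lambda / 2 > ext_d) {
        members[[cu]] <- merged
        cluster_of[members[[cv]]] <- cu
        members[[cv]] <- character(0)
      }
    }
  }
  min_size <- min_size_fraction * length(nodes)
  keep <- which(vapply(members, length, integer(1)) >= max(min_size, 1))
  membership <- setNames(rep(NA_integer_, length(nodes)), nodes)
  for (j in seq_along(keep)) membership[members[[keep[j]]]] <- j
  assigned <- membership[!is.na(membership)]
  structure(list(
    membership = assigned,
    sizes = if (length(assigned)) as.integer(table(assigned)) else integer(0),
    unassigned = sort(names(membership)[is.na(membership)])
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules (sizes %s), %d unassigned nodes\n",
              length(x$sizes),
              paste(sort(x$sizes, decreasing = TRUE), collapse = ", "),
              length(x$unassigned)))
  invisible(x)
}
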