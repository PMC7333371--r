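# Construction of the two network classes used throughout: correlation
# networks with density-minimising threshold selection, and seed plus
# first-order interaction subnetworks extracted from a physical edge list.

#' Pearson correlation matrix over genes
#'
#' Correlates gene expression profiles across samples. Genes with zero
#' sample variance cannot enter co-expression edges: they are dropped from
#' the returned matrix and recorded in the \code{"excluded"} attribute.
#'
#' @param expr Numeric gene-by-sample matrix with row names; at least two
#'   genes and three samples.
#' @return Symmetric correlation matrix (diagonal 1) over the genes with
#'   positive variance, with attribute \code{excluded} naming dropped genes.
#' @export
pearson_matrix <- function(expr) {
  if (!is.matrix(expr) || nrow(expr) < 2) stop_input("need a matrix of >= 2 genes")
  if (ncol(expr) < 3) stop_input("need >= 3 samples to correlate")
  if (is.null(rownames(expr))) stop_input("'expr' must have gene row names")
  v <- apply(expr, 1, function(x) stats::var(x))
  excluded <- rownames(expr)[v == 0]
  keep <- expr[v > 0, , drop = FALSE]
  if (nrow(keep) < 2) stop_input("fewer than 2 genes with nonzero variance")
  r <- cor(t(keep))
  attr(r, "excluded") <- excluded
  r
}

#' Scan correlation thresholds and record the network density of each
#'
#' For each threshold t the network keeps the edges with correlation
#' \code{>= t} (on the signed correlation by default, on \code{abs(r)} with
#' \code{absolute = TRUE}); only nodes incident to at least one kept edge
#' are counted, and density is \code{n_edges / choose(n_nodes, 2)}.
#' Thresholds keeping zero edges get an undefined (NA) density and never
#' win the selection.
#'
#' @param corr Symmetric correlation matrix with gene names.
#' @param grid Strictly increasing thresholds inside \code{[0, 1)}. Default
#'   0 to 0.99 in steps of 0.01.
#' @param absolute Threshold \code{abs(r)} instead of signed r.
#' @return A \code{data.frame} of class \code{threshold_scan} with columns
#'   \code{threshold}, \code{n_nodes}, \code{n_edges}, \code{density}.
#' @seealso \code{\link{select_threshold}}
#' @export
scan_thresholds <- function(corr, grid = seq(0, 0.99, by = 0.01),
                            absolute = FALSE) {
  if (length(grid) == 0) stop_input("'grid' must not be empty")
  if (any(grid < 0) || any(grid >= 1)) stop_input("'grid' must lie in [0, 1)")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_input("'grid' must be strictly increasing")
  }
  r <- if (absolute) abs(corr) else corr
  ut <- upper.tri(r)
  vals <- r[ut]
  idx <- which(ut, arr.ind = TRUE)
  rows <- lapply(grid, function(t) {
    keep <- vals >= t
    n_edges <- sum(keep)
    n_nodes <- length(unique(c(idx[keep, 1], idx[keep, 2])))
    density <- if (n_edges == 0) NA_real_ else
      n_edges / (n_nodes * (n_nodes - 1) / 2)
    data.frame(threshold = t, n_nodes = n_nodes, n_edges = n_edges,
               density = density)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_scan", "data.frame")
  out
}

#' Select the correlation threshold minimising network density
#'
#' Returns the threshold whose retained network has the lowest defined
#' density; ties are broken toward the lowest threshold, which keeps the
#' most seed genes in the network.
#'
#' @param scan A \code{\link{scan_thresholds}} result.
#' @return The selected threshold (scalar).
#' @export
select_threshold <- function(scan) {
  ok <- scan[!is.na(scan$density), , drop = FALSE]
  if (nrow(ok) == 0) stop_input("all densities undefined; nothing to select")
  ok$threshold[which.min(ok$density)]
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Correlation threshold scan over %d thresholds\n", nrow(x)))
  sel <- tryCatch(select_threshold(x), error = function(e) NA)
  if (!is.na(sel)) {
    cat(sprintf("  minimum density %.5g at threshold %.3g\n",
                min(x$density, na.rm = TRUE), sel))
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Build a seed-anchored co-expression network at a threshold
#'
#' Starts from the seed genes present in the matrix and their
#' super-threshold partners, then keeps every super-threshold edge with at
#' least one endpoint in that set; the network's nodes are the endpoints of
#' the kept edges. Partner-partner edges are therefore included, and a gene
#' beyond the partners enters only through such an edge (no further
#' expansion happens from those genes).
#'
#' @param corr Correlation matrix (see \code{\link{pearson_matrix}}).
#' @param threshold Correlation cutoff, e.g. from
#'   \code{\link{select_threshold}}.
#' @param seeds Character vector of seed gene symbols.
#' @param absolute Threshold on \code{abs(r)}.
#' @return An undirected simple \pkg{igraph} graph.
#' @export
coexpression_network <- function(corr, threshold, seeds, absolute = FALSE) {
  seeds <- clean_symbols(seeds)
  genes <- rownames(corr)
  present <- intersect(seeds, genes)
  if (length(present) == 0) stop_input("no seed gene present in the matrix")
  r <- if (absolute) abs(corr) else corr
  diag(r) <- -Inf
  partner_hits <- r[present, , drop = FALSE] >= threshold
  partners <- colnames(r)[colSums(partner_hits) > 0]
  core <- union(present, partners)
  ut <- which(upper.tri(r) & r >= threshold, arr.ind = TRUE)
  keep <- genes[ut[, 1]] %in% core | genes[ut[, 2]] %in% core
  ut <- ut[keep, , drop = FALSE]
  if (nrow(ut) == 0) stop_input("no edge reaches threshold %.3g", threshold)
  el <- cbind(genes[ut[, 1]], genes[ut[, 2]])
  # seeds with no super-threshold partner drop out (no incident edge)
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

#' Seed plus first-order interactor subnetwork of an edge list
#'
#' Reproduces the standard seed-network extraction from a physical
#' interaction edge list: keep the seeds appearing in the edge list and all
#' their direct interactors, then every input edge with both endpoints in
#' that node set (interactor-interactor edges included). Self-loops and
#' duplicate edges are removed first.
#'
#' @param edges Two-column matrix or data.frame of node symbols.
#' @param seeds Character vector of seed symbols.
#' @return An undirected simple \pkg{igraph} graph.
#' @export
first_order_subnetwork <- function(edges, seeds) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  if (nrow(edges) == 0) stop_input("empty edge list")
  edges[] <- clean_symbols(edges)
  seeds <- clean_symbols(seeds)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  if (nrow(edges) == 0) stop_input("edge list contains only self-loops")
  g_all <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  present <- intersect(seeds, igraph::V(g_all)$name)
  if (length(present) == 0) stop_input("no seed appears in the edge list")
  nbrs <- unlist(lapply(igraph::adjacent_vertices(g_all, present),
                        function(v) v$name))
  nodes <- union(present, nbrs)
  igraph::induced_subgraph(g_all, nodes)
}

#' Connected components, largest first
#'
#' @param net An \pkg{igraph} graph with named vertices.
#' @return List of character vectors (sorted node names), ordered by
#'   decreasing size with ties broken by smallest node label.
#' @export
network_components <- function(net) {
  if (igraph::vcount(net) == 0) stop_input("empty network")
  comp <- igraph::components(net)
  members <- split(igraph::V(net)$name, comp$membership)
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, `[`, character(1), 1))
  unname(members[ord])
}
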