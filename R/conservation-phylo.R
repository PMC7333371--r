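# Conservation statistics: two-proportion z-tests for orthologue
# enrichment, Faith's phylogenetic diversity over a tip subset, and its
# closed-form expectation under independent binomial tip sampling.

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic for comparing k1/n1 against k2/n2, with a
#' two-tailed p from the standard normal. For a panel of species the
#' caller applies \code{\link{bh_adjust}} across tests.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with \code{z}, \code{p}, \code{prop1}, \code{prop2}.
#' @examples
#' two_proportion_ztest(40, 100, 20, 100)
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop_input("group sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop_input("counts must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)), prop1 = p1, prop2 = p2)
}

# edge index of the branch leading into each node, and parent lookup
phylo_parents <- function(tree) {
  parent <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  list(parent = parent, edge_of = edge_of,
       root = length(tree$tip.label) + 1L)
}

#' Faith's phylogenetic diversity of a tip subset
#'
#' Sum of the branch lengths of the minimal subtree spanning the sampled
#' tips: the branches on the paths from each tip to their most recent
#' common ancestor, plus the MRCA-to-root path when \code{include_root}
#' (the default, matching the common R-ecosystem convention). A single tip
#' with \code{include_root = FALSE} spans no branch and yields 0.
#'
#' @param tree An \pkg{ape} \code{phylo} with branch lengths.
#' @param tips Character vector of tip labels, all present in the tree.
#' @param include_root Include the MRCA-to-root branches (default TRUE).
#' @return Branch-length sum (scalar).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B"))
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  if (is.null(tree$edge.length)) stop_input("tree has no branch lengths")
  tips <- clean_symbols(tips)
  if (length(tips) == 0) stop_input("empty tip set")
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop_input("unknown tip label(s): %s",
               paste(tips[is.na(idx)], collapse = ", "))
  }
  pp <- phylo_parents(tree)
  used <- logical(nrow(tree$edge))
  for (i in idx) {
    node <- i
    while (node != pp$root && !used[pp$edge_of[node]]) {
      used[pp$edge_of[node]] <- TRUE
      node <- pp$parent[node]
    }
  }
  if (!include_root) {
    # walk up from the MRCA and drop the root path
    mrca <- if (length(idx) == 1) idx else ape::getMRCA(tree, tips)
    node <- mrca
    while (node != pp$root) {
      used[pp$edge_of[node]] <- FALSE
      node <- pp$parent[node]
    }
  }
  sum(tree$edge.length[used])
}

#' Expected Faith's PD under binomial tip sampling
#'
#' Closed-form expectation of \code{\link{faith_pd}} when every tip is
#' sampled independently with probability \code{sampling_p}: each branch b
#' with n_b descendant tips is covered with probability
#' \code{1 - (1 - p)^n_b}, so the expectation is
#' \code{sum(L_b * (1 - (1 - p)^n_b))} (root path included, matching the
#' \code{include_root = TRUE} convention of the observed PD).
#'
#' @param tree An \pkg{ape} \code{phylo} with branch lengths.
#' @param sampling_p Tip-sampling probability in \code{[0, 1]}.
#' @return Expected branch-length sum.
#' @export
expected_pd <- function(tree, sampling_p) {
  check_prob(sampling_p, "sampling_p")
  if (is.null(tree$edge.length)) stop_input("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  # tips below each edge, by postorder accumulation
  n_below <- integer(max(tree$edge))
  n_below[seq_len(n_tip)] <- 1L
  # accumulate child tip counts into parents in postorder edge order
  for (i in ape::postorder(tree)) {
    child <- tree$edge[i, 2]
    parent <- tree$edge[i, 1]
    n_below[parent] <- n_below[parent] + n_below[child]
  }
  nb_edge <- n_below[tree$edge[, 2]]
  sum(tree$edge.length * (1 - (1 - sampling_p)^nb_edge))
}

#' Orthologue conservation panel: z-tests with BH correction
#'
#' Applies \code{\link{two_proportion_ztest}} to each species row of a
#' counts table (subset orthologue fraction vs genome orthologue fraction)
#' and BH-adjusts across species.
#'
#' @param counts \code{data.frame} with columns \code{species},
#'   \code{k_subset}, \code{n_subset}, \code{k_genome}, \code{n_genome}.
#' @return The input with added \code{z}, \code{p}, \code{p_adj} columns.
#' @export
conservation_ztests <- function(counts) {
  need <- c("species", "k_subset", "n_subset", "k_genome", "n_genome")
  if (!all(need %in% names(counts))) {
    stop_input("counts needs columns %s", paste(need, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(counts)), function(i) {
    two_proportion_ztest(counts$k_subset[i], counts$n_subset[i],
                         counts$k_genome[i], counts$n_genome[i])
  })
  counts$z <- vapply(res, `[[`, numeric(1), "z")
  counts$p <- vapply(res, `[[`, numeric(1), "p")
  counts$p_adj <- bh_adjust(counts$p)
  counts
}
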