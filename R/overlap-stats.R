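# Directional gene-set overlap statistics: exact hypergeometric/Fisher
# overlap tests, BH correction, the dual-direction background adjustment,
# signed heat matrices for per-tissue enrichment/depletion, and the
# fold-change distribution shift test.

#' Exact overlap test between two gene sets
#'
#' Tests the overlap of \code{set_a} and \code{set_b} within \code{universe}
#' with the hypergeometric distribution (equivalently Fisher's exact test on
#' the 2x2 table). The odds ratio is the sample odds ratio
#' \code{k (N - a - b + k) / ((a - k)(b - k))}, with the conventions
#' \code{Inf} when a denominator cell is 0 (and the numerator is not) and 0
#' when either input set is empty.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param universe Character vector containing both sets.
#' @param alternative \code{"greater"} (enrichment, default), \code{"less"}
#'   (depletion) or \code{"two.sided"}.
#' @return \code{data.frame} of class \code{overlap_result} with
#'   \code{n_a}, \code{n_b}, \code{n_overlap}, \code{universe},
#'   \code{expected}, \code{odds_ratio}, \code{p}, \code{direction},
#'   \code{alternative}. BH adjustment across a family of overlaps is the
#'   caller's job (\code{\link{bh_adjust}}).
#' @examples
#' fisher_overlap(letters[1:5], letters[2:5], letters[1:10])
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  set_a <- unique(clean_symbols(set_a))
  set_b <- unique(clean_symbols(set_b))
  universe <- unique(clean_symbols(universe))
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop_input("both sets must be subsets of the universe")
  }
  a <- length(set_a); b <- length(set_b); N <- length(universe)
  k <- length(intersect(set_a, set_b))
  p <- hyper_overlap_p(k, a, b, N, alternative)
  num <- k * (N - a - b + k)
  den <- (a - k) * (b - k)
  or <- if (a == 0 || b == 0) 0
        else if (den == 0) { if (num == 0) 0 else Inf }
        else num / den
  expected <- a * b / N
  out <- data.frame(
    n_a = a, n_b = b, n_overlap = k, universe = N, expected = expected,
    odds_ratio = or, p = p,
    direction = if (k > expected) "enriched" else "depleted",
    alternative = alternative, stringsAsFactors = FALSE
  )
  class(out) <- c("overlap_result", "data.frame")
  out
}

# hypergeometric overlap p-value; two-sided sums all tables at most as
# probable as the observed one (the fisher.test convention)
hyper_overlap_p <- function(k, a, b, N, alternative) {
  if (a == 0 || b == 0) return(1)
  switch(alternative,
    greater = phyper(k - 1, a, N - a, b, lower.tail = FALSE),
    less = phyper(k, a, N - a, b),
    two.sided = {
      support <- max(0, a + b - N):min(a, b)
      d <- dhyper(support, a, N - a, b)
      min(1, sum(d[d <= dhyper(k, a, N - a, b) * (1 + 1e-7)]))
    }
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment (via \code{stats::p.adjust}) with input validation;
#' adjusted values are monotone in p-rank and capped at 1.
#'
#' @param p_list Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_list) {
  check_prob(p_list, "p_list")
  p.adjust(p_list, method = "BH")
}

#' Background adjustment for genes differentially expressed in both directions
#'
#' Genes that appear both in some up-regulated set and some down-regulated
#' set (across tissues) are deliberately counted once in each directional
#' list; to keep the contingency tables consistent the universe is inflated
#' by one per such gene.
#'
#' @param up_sets,down_sets Lists of per-tissue character vectors.
#' @param genome Character vector, the unadjusted background.
#' @return List with \code{up_all}, \code{down_all} (directional unions),
#'   \code{dual_genes}, \code{n_dual}, and \code{universe_size}
#'   (= \code{length(genome) + n_dual}).
#' @export
dual_direction_background <- function(up_sets, down_sets, genome) {
  genome <- unique(clean_symbols(genome))
  up_all <- unique(clean_symbols(unlist(up_sets, use.names = FALSE)))
  down_all <- unique(clean_symbols(unlist(down_sets, use.names = FALSE)))
  if (!all(c(up_all, down_all) %in% genome)) {
    stop_input("directional sets must be subsets of the genome")
  }
  dual <- intersect(up_all, down_all)
  list(up_all = up_all, down_all = down_all, dual_genes = dual,
       n_dual = length(dual),
       universe_size = length(genome) + length(dual))
}

#' Signed enrichment/depletion heat matrix
#'
#' For each (gene set, tissue set) cell, computes one-sided enrichment and
#' depletion p-values and reports a signed heat value: when the observed
#' overlap exceeds expectation, \code{-log2(p_enriched)} (positive heat);
#' when below, \code{log2(p_depleted)} (negative); exactly at expectation,
#' 0. Significance flags mark cells whose directional p survives BH
#' adjustment across the whole matrix at \code{alpha}.
#'
#' @param row_sets Named list of gene sets (matrix rows).
#' @param col_sets Named list of gene sets (matrix columns, e.g. per-tissue
#'   directional DEG sets). Empty sets give NA cells.
#' @param universe Background gene vector.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return Object of class \code{heat_matrix}: list with matrices
#'   \code{heat}, \code{p}, \code{p_adj}, \code{significant},
#'   \code{overlap}.
#' @export
directional_heat <- function(row_sets, col_sets, universe, alpha = 0.05) {
  nr <- length(row_sets); nc <- length(col_sets)
  heat <- p <- ov <- matrix(NA_real_, nr, nc,
                            dimnames = list(names(row_sets), names(col_sets)))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (length(col_sets[[j]]) == 0) next
      enr <- fisher_overlap(row_sets[[i]], col_sets[[j]], universe, "greater")
      dep <- fisher_overlap(row_sets[[i]], col_sets[[j]], universe, "less")
      ov[i, j] <- enr$n_overlap
      if (enr$n_overlap > enr$expected) {
        heat[i, j] <- -log2(enr$p)
        p[i, j] <- enr$p
      } else if (enr$n_overlap < enr$expected) {
        heat[i, j] <- log2(dep$p)
        p[i, j] <- dep$p
      } else {
        heat[i, j] <- 0
        p[i, j] <- min(1, min(enr$p, dep$p))
      }
    }
  }
  p_adj <- p
  ok <- !is.na(p)
  p_adj[ok] <- bh_adjust(p[ok])
  structure(list(heat = heat, p = p, p_adj = p_adj,
                 significant = !is.na(p_adj) & p_adj < alpha,
                 overlap = ov),
            class = "heat_matrix")
}

#' @export
print.heat_matrix <- function(x, ...) {
  cat(sprintf("Signed overlap heat matrix (%d sets x %d columns), %d significant cells\n",
              nrow(x$heat), ncol(x$heat), sum(x$significant, na.rm = TRUE)))
  print(round(x$heat, 2))
  invisible(x)
}

#' Fold-change distribution shift test
#'
#' Two-sided Wilcoxon rank-sum test comparing the fold-change distribution
#' of a gene subset against the genome-wide distribution: exact when the
#' combined sample size is at most 20, normal approximation with continuity
#' correction otherwise. Also reports the sign of the median difference.
#'
#' @param values_subset,values_genome Numeric vectors (finite).
#' @return List with \code{p}, \code{median_subset}, \code{median_genome},
#'   \code{median_shift_sign} (-1, 0, +1), \code{statistic}.
#' @export
fc_shift_test <- function(values_subset, values_genome) {
  if (length(values_subset) == 0 || length(values_genome) == 0) {
    stop_input("both samples must be non-empty")
  }
  if (any(!is.finite(values_subset)) || any(!is.finite(values_genome))) {
    stop_input("non-finite values in input")
  }
  exact <- (length(values_subset) + length(values_genome)) <= 20
  wt <- suppressWarnings(
    wilcox.test(values_subset, values_genome, alternative = "two.sided",
                exact = exact, correct = TRUE)
  )
  ms <- median(values_subset); mg <- median(values_genome)
  list(p = wt$p.value, median_subset = ms, median_genome = mg,
       median_shift_sign = sign(ms - mg), statistic = unname(wt$statistic))
}
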