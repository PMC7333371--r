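# Permutation null for multi-tissue differential-expression counts.
# Within each tissue the (adjusted p, fold change) pairs are scrambled
# uniformly across that tissue's genes; significance filtering is then
# re-applied and the number of tissues in which each catalog gene stays
# significant is recorded across simulations. A Poisson-binomial dynamic
# programme provides the analytic oracle for the same tail probabilities.

check_deg_table <- function(table) {
  need <- c("tissue", "gene", "p_adj", "effect")
  if (!all(need %in% names(table))) {
    stop_input("DEG table needs columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(table[c("tissue", "gene")])) {
    stop_input("(tissue, gene) pairs must be unique")
  }
  check_prob(table$p_adj, "p_adj")
  invisible(table)
}

#' Scramble a differential-expression table within tissues
#'
#' Within every tissue, the multiset of (adjusted p, effect) pairs is
#' permuted uniformly across that tissue's genes; pairs are never split and
#' tissues are permuted independently. This preserves each tissue's
#' significant-set sizes exactly while destroying any gene-level signal.
#'
#' @param table DEG \code{data.frame} with columns \code{tissue},
#'   \code{gene}, \code{p_adj}, \code{effect}.
#' @return A scrambled table of the same shape (row order by tissue).
#' @export
scramble_tissue <- function(table) {
  check_deg_table(table)
  parts <- split(table, table$tissue)
  out <- lapply(parts, function(d) {
    perm <- sample.int(nrow(d))
    d$p_adj <- d$p_adj[perm]
    d$effect <- d$effect[perm]
    d
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' Per-tissue significant up/down gene sets
#'
#' Applies the significance filter: adjusted p below \code{alpha} and
#' absolute effect above \code{effect_min} (default log2(1.5)), with the
#' sign of the effect deciding the direction. Input p-values are treated as
#' already multiplicity-adjusted.
#'
#' @param table DEG table (see \code{\link{scramble_tissue}}).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param effect_min Minimum absolute effect, log2 units (default
#'   \code{log2(1.5)}).
#' @return Named list per tissue, each a list with \code{up} and
#'   \code{down} character vectors.
#' @export
significant_sets <- function(table, alpha = 0.05, effect_min = log2(1.5)) {
  check_deg_table(table)
  if (alpha <= 0 || alpha >= 1) stop_input("'alpha' must be in (0, 1)")
  if (effect_min <= 0) stop_input("'effect_min' must be > 0")
  parts <- split(table, table$tissue)
  lapply(parts, function(d) {
    sig <- d$p_adj < alpha
    list(up = d$gene[sig & d$effect > effect_min],
         down = d$gene[sig & d$effect < -effect_min])
  })
}

#' Count tissues in which each gene is significant, per direction
#'
#' @param sets Per-tissue directional sets from
#'   \code{\link{significant_sets}}.
#' @param genes Character vector of catalog genes to count.
#' @return \code{data.frame} with \code{gene}, \code{n_up}, \code{n_down}.
#' @export
tissue_counts <- function(sets, genes) {
  genes <- clean_symbols(genes)
  in_sets <- function(field) {
    m <- vapply(sets, function(s) genes %in% s[[field]],
                logical(length(genes)))
    rowSums(matrix(m, nrow = length(genes)))
  }
  n_up <- in_sets("up")
  n_down <- in_sets("down")
  data.frame(gene = genes, n_up = as.integer(n_up),
             n_down = as.integer(n_down), stringsAsFactors = FALSE)
}

#' Permutation null for multi-tissue significance counts
#'
#' Runs \code{n_sim} scrambling rounds; in each, every tissue's (p, effect)
#' pairs are permuted, the significance filter is re-applied, and each
#' catalog gene's number of significant tissues is recorded per direction.
#' The tail probability P(count > k) is estimated as the fraction of
#' (simulation x gene) observations exceeding k, pooling over the catalog
#' genes' tissue-presence patterns (a gene absent from a tissue's table can
#' never be significant there). \code{k_star} is the smallest k at which
#' the tail probability drops below \code{tail_alpha}.
#'
#' @param table DEG table.
#' @param genes Catalog gene symbols (non-empty).
#' @param n_sim Number of scrambling rounds (default 10000).
#' @param seed Integer seed (mandatory).
#' @param alpha,effect_min Significance filter parameters (see
#'   \code{\link{significant_sets}}); \code{alpha = 0} is allowed and makes
#'   nothing significant.
#' @param tail_alpha Tail level defining \code{k_star} (default 0.05).
#' @return Object of class \code{null_tissue_distribution}: list with
#'   \code{tail_up}, \code{tail_down} (named numeric, P(count > k) for
#'   k = 0..T), \code{k_star_up}, \code{k_star_down}, \code{n_sim},
#'   \code{seed}, \code{tissues}.
#' @export
null_distribution <- function(table, genes, n_sim = 10000, seed,
                              alpha = 0.05, effect_min = log2(1.5),
                              tail_alpha = 0.05) {
  check_deg_table(table)
  genes <- clean_symbols(genes)
  if (length(genes) == 0) stop_input("empty catalog gene list")
  if (n_sim < 1) stop_input("'n_sim' must be >= 1")
  parts <- split(table, table$tissue)
  tissues <- names(parts)
  T_n <- length(tissues)
  # per tissue: which pair slots pass the filter, and where catalog genes sit
  pre <- lapply(parts, function(d) {
    sig <- d$p_adj < alpha & abs(d$effect) > effect_min
    list(n = nrow(d),
         up_slot = which(sig & d$effect > 0),
         down_slot = which(sig & d$effect < 0),
         gene_pos = match(genes, d$gene))
  })
  count_tab_up <- integer(T_n + 1)
  count_tab_down <- integer(T_n + 1)
  with_seed(seed, {
    for (s in seq_len(n_sim)) {
      n_up <- integer(length(genes))
      n_down <- integer(length(genes))
      for (t in seq_len(T_n)) {
        pt <- pre[[t]]
        perm <- sample.int(pt$n)
        # slot j receives pair perm[j]; gene at position pos is significant
        # when its received pair index is an up/down slot
        got <- perm[pt$gene_pos]
        n_up <- n_up + (!is.na(got) & got %in% pt$up_slot)
        n_down <- n_down + (!is.na(got) & got %in% pt$down_slot)
      }
      count_tab_up <- count_tab_up + tabulate(n_up + 1L, T_n + 1)
      count_tab_down <- count_tab_down + tabulate(n_down + 1L, T_n + 1)
    }
  })
  total <- n_sim * length(genes)
  tail_from_counts <- function(tab) {
    # P(count > k) for k = 0..T
    gt <- rev(cumsum(rev(tab)))  # P(count >= k)
    p <- c(gt[-1], 0) / total
    setNames(p, 0:T_n)
  }
  tail_up <- tail_from_counts(count_tab_up)
  tail_down <- tail_from_counts(count_tab_down)
  k_star <- function(tail) {
    idx <- which(tail < tail_alpha)
    if (length(idx) == 0) NA_integer_ else as.integer(names(tail)[idx[1]])
  }
  structure(list(tail_up = tail_up, tail_down = tail_down,
                 k_star_up = k_star(tail_up), k_star_down = k_star(tail_down),
                 n_sim = n_sim, seed = seed, tissues = tissues),
            class = "null_tissue_distribution")
}

#' @export
print.null_tissue_distribution <- function(x, ...) {
  cat(sprintf("Permutation null over %d tissues, %d simulations (seed %s)\n",
              length(x$tissues), x$n_sim, format(x$seed)))
  cat(sprintf("  k* up = %s, k* down = %s (P(count > k*) < 0.05)\n",
              format(x$k_star_up), format(x$k_star_down)))
  invisible(x)
}

#' Exact Poisson-binomial upper tail
#'
#' P(count > k) for a sum of independent Bernoulli trials with
#' per-tissue success probabilities, by dynamic programming over tissues.
#' This is the analytic counterpart of \code{\link{null_distribution}}:
#' under scrambling, a gene present in tissue t is significant-up there
#' with probability m_t / G_t independently across tissues.
#'
#' @param per_tissue_probs Numeric vector of probabilities.
#' @param k Non-negative integer.
#' @return P(count > k).
#' @export
poisson_binomial_tail <- function(per_tissue_probs, k) {
  check_prob(per_tissue_probs, "per_tissue_probs")
  if (k < 0) stop_input("'k' must be >= 0")
  pmf <- 1
  for (p in per_tissue_probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  if (k + 1 >= length(pmf)) return(0)
  sum(pmf[(k + 2):length(pmf)])
}

#' Flag genes significant in more tissues than expected by chance
#'
#' A gene is flagged in a direction when its observed tissue count strictly
#' exceeds that direction's \code{k_star} from the permutation null.
#'
#' @param observed \code{data.frame} from \code{\link{tissue_counts}}.
#' @param null A \code{\link{null_distribution}} result computed on the
#'   same tissue panel.
#' @param tissues Optional character vector naming the panel the counts
#'   were computed on; if given it must match the null's panel.
#' @return \code{observed} with added logical columns \code{flag_up},
#'   \code{flag_down}.
#' @export
call_multitissue <- function(observed, null, tissues = NULL) {
  if (!is.null(tissues) && !setequal(tissues, null$tissues)) {
    stop_input("tissue panels of observed counts and null do not match")
  }
  observed$flag_up <- if (is.na(null$k_star_up)) FALSE
                      else observed$n_up > null$k_star_up
  observed$flag_down <- if (is.na(null$k_star_down)) FALSE
                        else observed$n_down > null$k_star_down
  observed
}
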