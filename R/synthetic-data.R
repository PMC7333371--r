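# Synthetic-data generators. Each generator emulates the statistical
# structure one pipeline stage assumes (correlated co-expression modules,
# scale-free interaction graphs with a designated seed subset, per-tissue
# differential-expression tables with planted multi-tissue genes, Yule
# trees, screens with designed hits), so the whole pipeline can be built
# and tested without any external download.

#' Generate a gene-by-sample expression matrix with planted correlated modules
#'
#' Genes inside a module share a latent factor: each gene is
#' \code{sqrt(within_r) * factor + sqrt(1 - within_r) * noise}, which gives
#' an expected pairwise Pearson correlation of exactly \code{within_r}
#' between module mates. Noise genes are independent standard normals.
#'
#' @param n_modules Number of correlated modules.
#' @param genes_per_module Genes per module.
#' @param n_noise Number of independent noise genes.
#' @param n_samples Number of samples (columns); at least 3.
#' @param within_r Target expected within-module Pearson correlation, in
#'   \code{[0, 1)}.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class \code{synth_expression}: a list with
#'   \code{matrix} (genes x samples), \code{module_of} (named character
#'   vector mapping gene to module id or \code{"noise"}), and \code{params}.
#' @examples
#' sim <- gen_expression(2, 5, 10, 50, within_r = 0.8, seed = 1)
#' dim(sim$matrix)
#' table(sim$module_of)
#' @export
gen_expression <- function(n_modules, genes_per_module, n_noise, n_samples,
                           within_r, seed) {
  if (!is.numeric(within_r) || length(within_r) != 1 ||
      within_r < 0 || within_r >= 1) {
    stop_input("'within_r' must be a correlation in [0, 1)")
  }
  if (n_modules < 1 || genes_per_module < 1 || n_samples < 3) {
    stop_input("counts must be positive and n_samples >= 3")
  }
  n_mod_genes <- n_modules * genes_per_module
  n_genes <- n_mod_genes + n_noise
  with_seed(seed, {
    mat <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
    if (within_r > 0) {
      for (m in seq_len(n_modules)) {
        factor_m <- rnorm(n_samples)
        rows <- ((m - 1) * genes_per_module + 1):(m * genes_per_module)
        mat[rows, ] <- sqrt(within_r) * matrix(factor_m, nrow = genes_per_module,
                                               ncol = n_samples, byrow = TRUE) +
          sqrt(1 - within_r) * mat[rows, , drop = FALSE]
      }
    }
    genes <- sprintf("g%04d", seq_len(n_genes))
    rownames(mat) <- genes
    colnames(mat) <- sprintf("s%03d", seq_len(n_samples))
    module_of <- c(
      rep(sprintf("M%02d", seq_len(n_modules)), each = genes_per_module),
      rep("noise", n_noise)
    )
    names(module_of) <- genes
    structure(
      list(matrix = mat, module_of = module_of,
           params = list(n_modules = n_modules,
                         genes_per_module = genes_per_module,
                         n_noise = n_noise, n_samples = n_samples,
                         within_r = within_r, seed = seed)),
      class = "synth_expression"
    )
  })
}

#' Generate a scale-free graph with a designated seed-gene subset
#'
#' Preferential attachment starting from an \code{m_attach}-clique: each new
#' node attaches to \code{m_attach} distinct existing nodes with probability
#' proportional to current degree. With the clique start the edge count is
#' exactly \code{choose(m_attach, 2) + m_attach * (n_nodes - m_attach)}.
#' A random fraction of nodes is marked as seeds; optionally one extra
#' non-seed node is wired to 75\% of the seeds, a designed high
#' increased-connectivity node for recovery tests.
#'
#' @param n_nodes Number of preferential-attachment nodes.
#' @param m_attach Edges added per new node; must be < \code{n_nodes}.
#' @param seed_fraction Fraction of nodes marked as seeds, in (0, 1).
#' @param plant_seed_hub If \code{TRUE}, append one extra non-seed node
#'   connected to \code{ceiling(0.75 * n_seeds)} randomly chosen seeds.
#' @param seed Integer seed.
#' @return List with \code{graph} (an \pkg{igraph} undirected simple graph
#'   with named vertices), \code{seeds} (character vector), and
#'   \code{planted_hub} (node name or \code{NA}).
#' @examples
#' net <- gen_scalefree_graph(100, 3, seed_fraction = 0.2, seed = 1)
#' igraph::ecount(net$graph)
#' @export
gen_scalefree_graph <- function(n_nodes, m_attach, seed_fraction,
                                plant_seed_hub = FALSE, seed) {
  if (!is.numeric(seed_fraction) || seed_fraction <= 0 || seed_fraction >= 1) {
    stop_input("'seed_fraction' must be in (0, 1)")
  }
  if (m_attach >= n_nodes) stop_input("'m_attach' must be smaller than 'n_nodes'")
  with_seed(seed, {
    deg <- integer(n_nodes)
    # clique start
    clique <- t(combn(seq_len(m_attach), 2))
    from <- clique[, 1]
    to <- clique[, 2]
    deg[seq_len(m_attach)] <- m_attach - 1
    for (v in (m_attach + 1):n_nodes) {
      existing <- seq_len(v - 1)
      w <- deg[existing]
      targets <- sample(existing, m_attach, prob = w)
      from <- c(from, rep(v, m_attach))
      to <- c(to, targets)
      deg[targets] <- deg[targets] + 1
      deg[v] <- m_attach
    }
    nodes <- sprintf("n%04d", seq_len(n_nodes))
    n_seeds <- max(1, round(seed_fraction * n_nodes))
    seeds <- sort(sample(nodes, n_seeds))
    planted <- NA_character_
    el <- cbind(nodes[from], nodes[to])
    if (isTRUE(plant_seed_hub)) {
      planted <- sprintf("n%04d", n_nodes + 1)
      wired <- sample(seeds, ceiling(0.75 * length(seeds)))
      el <- rbind(el, cbind(planted, wired))
      nodes <- c(nodes, planted)
    }
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::simplify(g)
    list(graph = g, seeds = seeds, planted_hub = planted)
  })
}

#' Generate per-tissue differential-expression tables with planted genes
#'
#' Per tissue, exactly \code{tissue_sig_up[t]} genes receive an adjusted p
#' below 0.05 together with a 50-year-scaled log2 fold change above
#' log2(1.5), and \code{tissue_sig_down[t]} genes the mirrored
#' down-regulated pair. Planted genes occupy significant slots in their
#' stated tissues and direction; all remaining genes get p uniform on
#' (0.05, 1] and effect uniform inside (-log2(1.5), log2(1.5)), i.e. they
#' never pass the significance filter. The emitted p-values are taken as
#' already multiplicity-adjusted.
#'
#' @param n_genes Number of genes, shared across tissues.
#' @param tissue_sig_up Named integer vector: significant up count per tissue.
#' @param tissue_sig_down Named integer vector, same names: down counts.
#' @param planted Optional named list mapping gene name to
#'   \code{list(tissues = <character>, direction = "up"|"down")}.
#' @param seed Integer seed.
#' @return A \code{data.frame} with columns \code{tissue}, \code{gene},
#'   \code{p_adj}, \code{effect} (log2 units on the 50-year scale).
#' @export
gen_deg_tables <- function(n_genes, tissue_sig_up, tissue_sig_down,
                           planted = list(), seed) {
  tissues <- names(tissue_sig_up)
  if (is.null(tissues) || !identical(sort(tissues), sort(names(tissue_sig_down)))) {
    stop_input("'tissue_sig_up' and 'tissue_sig_down' must be named by the same tissues")
  }
  if (any(tissue_sig_up + tissue_sig_down[tissues] > n_genes)) {
    stop_input("per-tissue significant counts exceed 'n_genes'")
  }
  for (g in names(planted)) {
    if (length(planted[[g]]$tissues) > length(tissues)) {
      stop_input("planted gene '%s' assigned to more tissues than exist", g)
    }
    if (!all(planted[[g]]$tissues %in% tissues)) {
      stop_input("planted gene '%s' assigned to unknown tissues", g)
    }
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  fc_min <- log2(1.5)
  with_seed(seed, {
    out <- vector("list", length(tissues))
    for (i in seq_along(tissues)) {
      t <- tissues[i]
      up_planted <- names(planted)[vapply(planted, function(p)
        t %in% p$tissues && identical(p$direction, "up"), logical(1))]
      down_planted <- names(planted)[vapply(planted, function(p)
        t %in% p$tissues && identical(p$direction, "down"), logical(1))]
      n_up <- tissue_sig_up[[t]]
      n_down <- tissue_sig_down[[t]]
      if (length(up_planted) > n_up || length(down_planted) > n_down) {
        stop_input("tissue '%s': planted genes exceed its significant count", t)
      }
      pool <- setdiff(genes, c(up_planted, down_planted))
      extra_up <- sample(pool, n_up - length(up_planted))
      pool <- setdiff(pool, extra_up)
      extra_down <- sample(pool, n_down - length(down_planted))
      up_genes <- c(up_planted, extra_up)
      down_genes <- c(down_planted, extra_down)
      rest <- setdiff(genes, c(up_genes, down_genes))
      p_adj <- c(runif(n_up + n_down, 0, 0.05),
                 runif(length(rest), 0.05, 1))
      effect <- c(runif(n_up, fc_min + 1e-6, 3),
                  runif(n_down, -3, -fc_min - 1e-6),
                  runif(length(rest), -fc_min + 1e-6, fc_min - 1e-6))
      out[[i]] <- data.frame(
        tissue = t,
        gene = c(up_genes, down_genes, rest),
        p_adj = p_adj,
        effect = effect,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Describe the ground truth of a synthetic siRNA screen
#'
#' @param designed_hit Named list mapping siRNA name to the character vector
#'   of markers it shifts (in the senescence-associated direction).
#' @param shift_sd_units Size of the designed shift in control-SD units
#'   (non-negative).
#' @param control_mean,control_sd Named numeric vectors (one entry per
#'   marker) of the negative-control well distribution.
#' @return An object of class \code{screen_truth}.
#' @export
screen_truth <- function(designed_hit = list(), shift_sd_units = 3,
                         control_mean = NULL, control_sd = NULL) {
  markers <- names(SENESCENCE_DIRECTION)
  if (is.null(control_mean)) control_mean <- setNames(rep(100, 8), markers)
  if (is.null(control_sd)) control_sd <- setNames(rep(10, 8), markers)
  if (shift_sd_units < 0) stop_input("'shift_sd_units' must be >= 0")
  bad <- unlist(designed_hit)[!unlist(designed_hit) %in% markers]
  if (length(bad)) stop_input("unknown markers in designed_hit: %s",
                              paste(unique(bad), collapse = ", "))
  structure(list(designed_hit = designed_hit,
                 shift_sd_units = shift_sd_units,
                 control_mean = control_mean[markers],
                 control_sd = control_sd[markers]),
            class = "screen_truth")
}

#' Generate a synthetic siRNA screen measurement table
#'
#' Negative-control wells are drawn from the stated per-marker control
#' distribution independently per experiment; target wells follow the same
#' distribution except for designed hits, which are shifted by
#' \code{shift_sd_units} control SDs in the senescence-associated direction
#' of each designed marker (Ki67 and cell number down, the rest up).
#'
#' @param n_targets Number of target siRNAs (named sirna01, sirna02, ...).
#'   Names used in \code{truth$designed_hit} are honoured if they follow
#'   this scheme.
#' @param truth A \code{\link{screen_truth}} object.
#' @param n_experiments Number of independent experiments (>= 2).
#' @param wells_per_condition Replicate wells per siRNA per experiment (>= 3).
#' @param seed Integer seed.
#' @return \code{data.frame} with columns \code{experiment}, \code{well},
#'   \code{sirna}, \code{role} (\code{neg_control} or \code{target}) and the
#'   eight marker columns.
#' @export
gen_screen <- function(n_targets, truth = screen_truth(), n_experiments = 2,
                       wells_per_condition = 3, seed) {
  if (n_experiments < 2) stop_input("'n_experiments' must be >= 2")
  if (wells_per_condition < 3) stop_input("'wells_per_condition' must be >= 3")
  markers <- names(SENESCENCE_DIRECTION)
  targets <- sprintf("sirna%02d", seq_len(n_targets))
  unknown <- setdiff(names(truth$designed_hit), targets)
  if (length(unknown)) stop_input("designed_hit names not among targets: %s",
                                  paste(unknown, collapse = ", "))
  with_seed(seed, {
    rows <- list()
    for (e in seq_len(n_experiments)) {
      conds <- c("cyclophilinB", targets)
      for (s in conds) {
        m <- matrix(rnorm(wells_per_condition * length(markers)),
                    nrow = wells_per_condition)
        m <- sweep(m, 2, truth$control_sd, "*")
        m <- sweep(m, 2, truth$control_mean, "+")
        colnames(m) <- markers
        hit_markers <- truth$designed_hit[[s]]
        if (length(hit_markers)) {
          for (mk in hit_markers) {
            m[, mk] <- m[, mk] + SENESCENCE_DIRECTION[[mk]] *
              truth$shift_sd_units * truth$control_sd[[mk]]
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          experiment = sprintf("exp%d", e),
          well = sprintf("%s_e%d_w%d", s, e, seq_len(wells_per_condition)),
          sirna = s,
          role = if (s == "cyclophilinB") "neg_control" else "target",
          m,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate a random Yule (pure-birth) tree
#'
#' Topology grows by repeatedly splitting a uniformly chosen extant tip, the
#' standard pure-birth construction; every branch gets an independent
#' exponential(1) length. Tips are labelled \code{t1 ... tn}.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An \pkg{ape} \code{phylo} object, rooted, with branch lengths.
#' @export
gen_tree <- function(n_tips, seed) {
  if (n_tips < 2) stop_input("'n_tips' must be >= 2")
  with_seed(seed, {
    # children[[i]] holds the two daughter ids of internal node i (0 = tip)
    children <- list(c(2L, 3L))
    tips <- c(2L, 3L)
    n_node <- 3L
    while (length(tips) < n_tips) {
      pick <- tips[sample.int(length(tips), 1)]
      kids <- c(n_node + 1L, n_node + 2L)
      children[[pick]] <- kids
      n_node <- n_node + 2L
      tips <- c(setdiff(tips, pick), kids)
    }
    lens <- rexp(n_node)
    tip_counter <- 0
    to_newick <- function(id) {
      kids <- if (id <= length(children)) children[[id]] else NULL
      if (is.null(kids)) {
        tip_counter <<- tip_counter + 1
        sprintf("t%d:%s", tip_counter, format(lens[id], digits = 10))
      } else {
        inner <- paste(vapply(kids, to_newick, character(1)), collapse = ",")
        if (id == 1) sprintf("(%s);", inner)
        else sprintf("(%s):%s", inner, format(lens[id], digits = 10))
      }
    }
    nwk <- to_newick(1L)
    ape::read.tree(text = nwk)
  })
}
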