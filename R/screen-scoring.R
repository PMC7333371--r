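# siRNA high-content screen scoring: per-experiment Z-scores against the
# negative control, senescence-direction marker flags, and top-hit
# classification with the screen summary percentages.

#' Per-siRNA per-marker Z-scores against the negative control
#'
#' Per experiment and marker, Z = (mean of the target siRNA's wells - mean
#' of the negative-control wells) / SD of the negative-control wells; the
#' reported Z is the unweighted mean across experiments. Every experiment
#' must carry at least three negative-control wells with nonzero SD.
#'
#' @param measurements Screen \code{data.frame} with columns
#'   \code{experiment}, \code{well}, \code{sirna}, \code{role}, and the
#'   eight marker columns (\code{cell_number}, \code{ki67},
#'   \code{cell_area}, \code{nuclear_area}, \code{p16}, \code{p21},
#'   \code{il6}, \code{sabgal}).
#' @param negative_control siRNA label of the reference (default
#'   \code{"cyclophilinB"}).
#' @return Object of class \code{screen_ztable}: \code{data.frame} with
#'   \code{sirna}, \code{marker}, \code{z} (mean across experiments),
#'   \code{n_experiments}; the per-experiment values are kept in the
#'   \code{"per_experiment"} attribute.
#' @export
zscores <- function(measurements, negative_control = "cyclophilinB") {
  need <- c("experiment", "sirna", SCREEN_MARKERS)
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols)) {
    stop_input("measurements missing columns: %s",
               paste(missing_cols, collapse = ", "))
  }
  if (!negative_control %in% measurements$sirna) {
    stop_input("negative control '%s' not present", negative_control)
  }
  per_exp <- list()
  for (e in unique(measurements$experiment)) {
    d <- measurements[measurements$experiment == e, , drop = FALSE]
    ctrl <- d[d$sirna == negative_control, SCREEN_MARKERS, drop = FALSE]
    if (nrow(ctrl) < 3) {
      stop_input("experiment %s: fewer than 3 negative-control wells", e)
    }
    cm <- colMeans(ctrl)
    csd <- apply(ctrl, 2, sd)
    zero <- SCREEN_MARKERS[csd == 0]
    if (length(zero)) {
      stop_input("experiment %s: zero control SD for marker(s) %s",
                 e, paste(zero, collapse = ", "))
    }
    for (s in setdiff(unique(d$sirna), negative_control)) {
      tm <- colMeans(d[d$sirna == s, SCREEN_MARKERS, drop = FALSE])
      per_exp[[length(per_exp) + 1]] <- data.frame(
        experiment = e, sirna = s, marker = SCREEN_MARKERS,
        z = (tm - cm) / csd, row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  long <- do.call(rbind, per_exp)
  agg <- stats::aggregate(z ~ sirna + marker, data = long, FUN = mean)
  nexp <- stats::aggregate(z ~ sirna + marker, data = long, FUN = length)
  agg$n_experiments <- nexp$z
  agg <- agg[order(agg$sirna, match(agg$marker, SCREEN_MARKERS)), ]
  rownames(agg) <- NULL
  if (any(agg$n_experiments < 2)) {
    warning("some siRNAs measured in fewer than 2 experiments")
  }
  attr(agg, "per_experiment") <- long
  class(agg) <- c("screen_ztable", "data.frame")
  agg
}

#' @export
print.screen_ztable <- function(x, ...) {
  cat(sprintf("Screen Z-table: %d siRNAs x %d markers (mean of %d experiment(s))\n",
              length(unique(x$sirna)), length(unique(x$marker)),
              max(x$n_experiments)))
  wide <- zscore_matrix(x)
  print(round(utils::head(wide, 8), 2))
  invisible(x)
}

#' Z-score table as a siRNA-by-marker matrix
#'
#' @param z A \code{\link{zscores}} result.
#' @return Numeric matrix, rows = siRNAs, columns = the eight markers.
#' @export
zscore_matrix <- function(z) {
  sirnas <- unique(z$sirna)
  m <- matrix(NA_real_, length(sirnas), length(SCREEN_MARKERS),
              dimnames = list(sirnas, SCREEN_MARKERS))
  m[cbind(z$sirna, z$marker)] <- z$z
  m
}

#' Senescence-direction marker flags
#'
#' A marker is flagged when the mean Z moves at least \code{threshold}
#' Z-scores in the senescence-associated direction: decreases for Ki67 and
#' cell number, increases for cell area, nuclear area, p16, p21, IL-6 and
#' SA-beta-galactosidase. Ki67 uses a strict inequality ("greater than 1
#' Z-score"); all other markers flag at the boundary (>=).
#'
#' @param z A \code{\link{zscores}} result (or a siRNA-by-marker matrix).
#' @param threshold Z threshold (default 1).
#' @param direction_map Named vector of -1/+1 senescence directions per
#'   marker; defaults to the standard map.
#' @return Logical matrix, rows = siRNAs, columns = markers.
#' @export
marker_flags <- function(z, threshold = 1,
                         direction_map = SENESCENCE_DIRECTION) {
  m <- if (is.matrix(z)) z else zscore_matrix(z)
  unknown <- setdiff(colnames(m), names(direction_map))
  if (length(unknown)) {
    stop_input("unknown marker(s): %s", paste(unknown, collapse = ", "))
  }
  flags <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (mk in colnames(m)) {
    dirn <- direction_map[[mk]]
    flags[, mk] <- if (mk == "ki67") {
      dirn * m[, mk] > threshold
    } else {
      dirn * m[, mk] >= threshold
    }
  }
  flags
}

#' Classify top hits and summarise the screen
#'
#' A siRNA is a top hit when it decreases Ki67 and cell number and alters
#' at least one morphological measure in the senescence direction (cell or
#' nuclear area increase). The summary reports, as percentages rounded
#' half-up to one decimal: the fraction of all candidates flagged per
#' marker; of the Ki67-flagged candidates, the fraction classified top
#' hits; and of the top hits, the fractions with both p16 and p21 flags,
#' with the IL-6 flag, and with the SA-beta-gal flag.
#'
#' @param flags Logical siRNA-by-marker matrix from
#'   \code{\link{marker_flags}}.
#' @return Object of class \code{hit_report}: list with \code{flags},
#'   \code{top_hit} (named logical), \code{counts}, \code{percentages}.
#' @examples
#' f <- matrix(TRUE, 2, 8,
#'             dimnames = list(c("a", "b"),
#'                             c("cell_number", "ki67", "cell_area",
#'                               "nuclear_area", "p16", "p21", "il6",
#'                               "sabgal")))
#' classify_top_hits(f)$top_hit
#' @export
classify_top_hits <- function(flags) {
  need <- c("ki67", "cell_number", "cell_area", "nuclear_area")
  if (!all(need %in% colnames(flags))) {
    stop_input("flags must include columns %s", paste(need, collapse = ", "))
  }
  top <- flags[, "ki67"] & flags[, "cell_number"] &
    (flags[, "cell_area"] | flags[, "nuclear_area"])
  n <- nrow(flags)
  n_ki67 <- sum(flags[, "ki67"])
  n_top <- sum(top)
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  per_marker <- vapply(colnames(flags), function(mk)
    pct(sum(flags[, mk]), n), numeric(1))
  counts <- list(
    n_candidates = n, n_ki67 = n_ki67, n_top_hits = n_top,
    n_top_p16_p21 = sum(top & flags[, "p16"] & flags[, "p21"]),
    n_top_il6 = sum(top & flags[, "il6"]),
    n_top_sabgal = sum(top & flags[, "sabgal"])
  )
  percentages <- c(
    per_marker,
    top_hits_of_ki67 = pct(n_top, n_ki67),
    top_p16_p21 = pct(counts$n_top_p16_p21, n_top),
    top_il6 = pct(counts$n_top_il6, n_top),
    top_sabgal = pct(counts$n_top_sabgal, n_top)
  )
  structure(list(flags = flags, top_hit = top, counts = counts,
                 percentages = percentages),
            class = "hit_report")
}

#' @export
print.hit_report <- function(x, ...) {
  cat(sprintf("Screen hit report: %d candidates, %d Ki67-flagged, %d top hits\n",
              x$counts$n_candidates, x$counts$n_ki67, x$counts$n_top_hits))
  if (x$counts$n_top_hits > 0) {
    cat(sprintf("  top hits: %s\n",
                paste(names(x$top_hit)[x$top_hit], collapse = ", ")))
  }
  cat("  percentages:\n")
  print(x$percentages)
  invisible(x)
}
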