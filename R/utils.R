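#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dhyper phyper p.adjust pnorm rnorm runif rexp
#'   setNames quantile wilcox.test median sd lm coef
#' @importFrom utils read.csv write.csv read.delim combn head
NULL

# Round half away from zero to `digits` decimals. base round() uses
# banker's rounding, which turns 12/13*100 = 92.30769 into the right value
# but 0.5-boundaries (e.g. 96.15 -> 96.2 vs 96.1) the wrong way for
# reporting percentages.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# trimmed, case-sensitive gene identifiers
clean_symbols <- function(x) {
  trimws(as.character(x))
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_input("'%s' must contain probabilities in [0, 1]", name)
  }
  invisible(x)
}

# seed handling: all exported generators/simulators take an integer seed and
# restore the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_input("'seed' must be a single finite integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
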