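# Internal helpers shared across modules.

# ggplot2 NSE column names used in render_heatmap()
utils::globalVariables(c("col", "row", "side", "fill", "label"))

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (5.65 -> 5.7), the
#' convention used for all printed percentages and risk ratios in this
#' package. Base R's `round()` rounds half to even, which disagrees with the
#' usual clinical-table style on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NULL runs on the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
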