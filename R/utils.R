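#' @importFrom stats phyper rbinom rnbinom rpois rnorm median setNames
#' @importFrom utils read.table write.table modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed seed without disturbing the caller's RNG
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Weighted median
#'
#' Lower weighted median: smallest value whose cumulative weight reaches half
#' of the total. Used for the segment-size-sorted copy-number baseline.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @return numeric scalar.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Round half away from zero
#'
#' Reporting convention for percentages (base `round` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_bad <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
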