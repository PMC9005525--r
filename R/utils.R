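#' @importFrom stats p.adjust phyper pnorm prcomp rbinom rgeom rnbinom rpois
#' @importFrom stats aov loess median na.omit pairwise.t.test predict pt qnorm
#' @importFrom stats quantile rnorm runif sd setNames t.test var aggregate
#' @importFrom utils combn read.delim write.table head
#' @importFrom methods as
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous global RNG
#' state on exit, so package functions never leak RNG state into the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
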