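#' @keywords internal
"_PACKAGE"

## Canonical amino-acid alphabet, alphabetical order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so that seeded operations (SMOTE, generators, bootstrap, forests) are
#' reproducible without clobbering the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## stop() with a condition class so the CLI can map data errors to exit 2.
data_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("profam_data_error", "error")))
}

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
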