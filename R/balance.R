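#' SMOTE configuration
#'
#' @param percent Synthetic instances to add, as a percentage of the minority
#'   count (Weka filter semantics: `percent = 700` adds 7n synthetic rows so
#'   the minority grows from 100% to 800% of its original size). Multiples of
#'   100 recommended; `floor(percent / 100) * n` rows are produced.
#' @param k Number of nearest neighbors (Euclidean); default 5. When the
#'   minority has fewer than `k + 1` rows, `n - 1` neighbors are used.
#' @param seed Integer seed for reproducibility.
#' @return A list of class `smote_config`.
#' @export
smote_config <- function(percent = 700, k = 5, seed = 1) {
  stopifnot(is_count1(percent), is_count1(k), k >= 1)
  structure(list(percent = percent, k = k, seed = seed), class = "smote_config")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Generates `floor(percent / 100) * n` synthetic rows. Each synthetic row is
#' `x + u * (z - x)` where `x` is a minority row, `z` one of its `k` nearest
#' minority neighbors under the Euclidean metric on raw feature values, and
#' `u ~ Uniform(0, 1)`. Deterministic for a fixed seed.
#'
#' @param minority_rows Numeric matrix (n x d) of minority-class rows, n >= 2.
#' @param config A [smote_config()].
#' @return Numeric matrix of synthetic rows (possibly 0-row).
#' @export
smote <- function(minority_rows, config = smote_config()) {
  x <- as.matrix(minority_rows)
  n <- nrow(x); d <- ncol(x)
  if (n < 2L) data_error("SMOTE needs at least 2 minority rows")
  stopifnot(d >= 1L, inherits(config, "smote_config"))
  reps <- floor(config$percent / 100)
  if (reps == 0L) return(x[0, , drop = FALSE])
  k <- min(config$k, n - 1L)
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  ## k nearest neighbor indices per row; ties broken by lower index
  nn <- t(apply(dm, 1, function(r) order(r)[seq_len(k)]))
  with_rng_seed(config$seed, {
    out <- matrix(NA_real_, nrow = reps * n, ncol = d,
                  dimnames = list(NULL, colnames(x)))
    row <- 0L
    for (i in seq_len(n)) {
      for (r in seq_len(reps)) {
        z <- x[nn[i, sample.int(k, 1L)], ]
        u <- stats::runif(1)
        row <- row + 1L
        out[row, ] <- x[i, ] + u * (z - x[i, ])
      }
    }
    out
  })
}

#' Rebalance a labeled dataset by oversampling the minority class
#'
#' Original rows are preserved in order; synthetic rows are appended with the
#' minority label.
#'
#' @param X Numeric feature matrix.
#' @param y Label vector (length `nrow(X)`, two or more classes present).
#' @param config A [smote_config()].
#' @param minority_label Label of the class to oversample; defaults to the
#'   least frequent label (ties broken by label order of appearance).
#' @return List with elements `X`, `y` and `synthetic` (logical mask).
#' @export
rebalance_dataset <- function(X, y, config = smote_config(), minority_label = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) data_error("both classes must be present")
  if (is.null(minority_label)) {
    cnt <- table(factor(y, levels = unique(y)))
    minority_label <- names(cnt)[which.min(cnt)]
  }
  if (!minority_label %in% y) data_error("minority label '%s' absent from y", minority_label)
  syn <- smote(X[y == minority_label, , drop = FALSE], config)
  list(X = rbind(X, syn),
       y = c(y, rep(minority_label, nrow(syn))),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(syn))))
}
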