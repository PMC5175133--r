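#' Relative expression by the comparative-Ct method
#'
#' `delta Ct = ct_target - ct_reference` within the same sample (the
#' reference being a housekeeping gene), and relative expression is
#' `2^(-delta Ct)`.
#'
#' @param ct_target,ct_reference Finite threshold-cycle values (may be
#'   vectors of equal length).
#' @return `2^-(ct_target - ct_reference)`.
#' @examples
#' relative_expression(25, 20)  # 0.03125
#' relative_expression(18, 20)  # 4
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference)))
    data_error("Ct values must be finite")
  2^(-(ct_target - ct_reference))
}

#' Read a Ct table from CSV
#'
#' Expected columns: `sample_id`, `group` (`case` / `control`), `gene`,
#' `ct_target`, `ct_reference`. Ct values must lie in (0, 60) and each
#' (sample_id, gene) pair must be unique.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "ct_target", "ct_reference")
  miss <- setdiff(need, names(tab))
  if (length(miss)) data_error("Ct table missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(tab$group %in% c("case", "control")))
    data_error("group must be 'case' or 'control'")
  ct <- c(tab$ct_target, tab$ct_reference)
  if (!all(is.finite(ct)) || any(ct <= 0) || any(ct >= 60))
    data_error("Ct values must lie in (0, 60)")
  key <- paste(tab$sample_id, tab$gene)
  if (anyDuplicated(key))
    data_error("duplicate (sample_id, gene) pair(s): %s",
               paste(unique(key[duplicated(key)]), collapse = "; "))
  tab
}

## U statistic: #{x_i > y_j} + 0.5 #{ties}, via midranks.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test (exact or normal approximation)
#'
#' `U = #{(i, j): x_i > y_j} + 0.5 #{ties}`. The exact two-sided p-value is
#' computed by full enumeration of all `choose(m + n, m)` group labelings of
#' the pooled sample (valid under ties), used automatically when
#' `m + n <= 16`; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used. Two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param method `"auto"`, `"exact"` or `"normal-approx"`.
#' @return List with elements `U` and `p`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal-approx")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y))
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) data_error("both groups must be non-empty")
  u <- u_statistic(x, y)
  if (method == "auto") method <- if (m + n <= 16) "exact" else "normal-approx"
  if (method == "exact") {
    pool <- c(x, y)
    idx <- utils::combn(m + n, m)
    us <- apply(idx, 2, function(sel) u_statistic(pool[sel], pool[-sel]))
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
  } else {
    N <- m + n
    t <- table(c(x, y))
    mu <- m * n / 2
    sigma2 <- m * n / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1))
    ## continuity correction toward the mean
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    if (abs(u - mu) < 0.5) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u, p = p)
}

#' Two-group comparison of relative expression for one gene
#'
#' Computes per-sample `2^-dCt` relative expression, summarizes each group by
#' mean and standard error, and compares case vs control with the
#' Mann-Whitney U test. Stars follow the usual convention: `*` for p < 0.05,
#' `**` for p < 0.01, `NS` otherwise.
#'
#' @param table Ct table (see [read_ct_table()]).
#' @param gene Gene name to analyze; must appear in both groups.
#' @param method Passed to [mann_whitney_u()].
#' @return List of class `expression_result`.
#' @export
compare_groups <- function(table, gene, method = "auto") {
  rows <- table[table$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0L) data_error("gene '%s' not present", gene)
  expr <- relative_expression(rows$ct_target, rows$ct_reference)
  case <- expr[rows$group == "case"]
  control <- expr[rows$group == "control"]
  if (length(case) == 0L || length(control) == 0L)
    data_error("gene '%s' missing in one group", gene)
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  mw <- mann_whitney_u(case, control, method = method)
  structure(list(gene = gene,
                 n_case = length(case), n_control = length(control),
                 mean_case = mean(case), se_case = se(case),
                 mean_control = mean(control), se_control = se(control),
                 U = mw$U, p = mw$p,
                 stars = if (mw$p < 0.01) "**" else if (mw$p < 0.05) "*" else "NS",
                 direction = if (mean(case) > mean(control)) "up" else
                             if (mean(case) < mean(control)) "down" else "equal"),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("%s: case %.4g +/- %.3g (n=%d), control %.4g +/- %.3g (n=%d), U=%.1f, p=%.4g %s\n",
              x$gene, x$mean_case, x$se_case, x$n_case,
              x$mean_control, x$se_control, x$n_control, x$U, x$p, x$stars))
  invisible(x)
}

#' GC content of a primer
#'
#' @param sequence DNA sequence over A/C/G/T (case-insensitive).
#' @return Percent GC, `100 * (#G + #C) / length` (full precision; round to
#'   one decimal for display).
#' @examples
#' primer_gc("GAAGCAGTGGATTGGCTTTATG")  # 45.45...
#' @export
primer_gc <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(s)) data_error("empty primer sequence")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    data_error("non-DNA character(s): %s",
               paste(unique(ch[!(ch %in% c("A", "C", "G", "T"))]), collapse = ", "))
  100 * sum(ch %in% c("G", "C")) / length(ch)
}
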