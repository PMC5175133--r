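## Independent brute-force oracles. These are deliberately written in a
## different style from the package code (explicit loops, string scans, no
## shared lookup tables) so they can serve as second implementations.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

## LCS length by dynamic programming = max matches of a global alignment
## with match +1, mismatch 0, free gaps.
oracle_lcs <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  prev <- integer(length(y) + 1)
  for (i in seq_along(x)) {
    cur <- integer(length(y) + 1)
    for (j in seq_along(y)) {
      cur[j + 1] <- if (x[i] == y[j]) prev[j] + 1 else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[length(y) + 1]
}

## group membership (1, 2 or 3) of a residue by scanning the group strings
oracle_group_of <- function(res, grouping) {
  for (g in 1:3) if (res %in% grouping[[g]]) return(g)
  stop("residue not in grouping")
}

oracle_188d <- function(seq, groupings = ctd_groupings()) {
  n <- nchar(seq)
  out <- numeric(0)
  for (aa in AA) {
    cnt <- 0
    for (i in 1:n) if (substr(seq, i, i) == aa) cnt <- cnt + 1
    out <- c(out, cnt / n)
  }
  for (gp in groupings) {
    g <- integer(n)
    for (i in 1:n) g[i] <- oracle_group_of(substr(seq, i, i), gp)
    comp <- c(sum(g == 1), sum(g == 2), sum(g == 3)) / n
    t12 <- t13 <- t23 <- 0
    for (i in 1:(n - 1)) {
      pair <- sort(c(g[i], g[i + 1]))
      if (all(pair == c(1, 2))) t12 <- t12 + 1
      if (all(pair == c(1, 3))) t13 <- t13 + 1
      if (all(pair == c(2, 3))) t23 <- t23 + 1
    }
    trans <- c(t12, t13, t23) / (n - 1)
    dist <- numeric(0)
    for (grp in 1:3) {
      pos <- integer(0)
      for (i in 1:n) if (g[i] == grp) pos <- c(pos, i)
      if (length(pos) == 0) {
        dist <- c(dist, rep(0, 5))
      } else {
        ng <- length(pos)
        picks <- c(1, ceiling(0.25 * ng), ceiling(0.5 * ng), ceiling(0.75 * ng), ng)
        dist <- c(dist, pos[picks] / n)
      }
    }
    out <- c(out, comp, trans, dist)
  }
  out
}

## AUC by all-pairs comparison
oracle_auc <- function(scores, labels, positive = 1) {
  ps <- scores[labels == positive]
  ns <- scores[labels != positive]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

## AUC by tie-aware trapezoidal integration of the empirical ROC curve
oracle_auc_trapezoid <- function(scores, labels, positive = 1) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == positive
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

## Mann-Whitney U by double loop
oracle_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

## exact two-sided p by enumerating all label arrangements
oracle_mw_p <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  uobs <- oracle_u(x, y)
  sel <- utils::combn(length(pool), m)
  us <- numeric(ncol(sel))
  for (i in seq_len(ncol(sel))) us[i] <- oracle_u(pool[sel[, i]], pool[-sel[, i]])
  min(1, 2 * min(mean(us <= uobs + 1e-9), mean(us >= uobs - 1e-9)))
}

## leaf-to-leaf path-length matrix of a phylo tree
tree_leaf_dists <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}
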