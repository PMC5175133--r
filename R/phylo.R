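#' Pairwise p-distances from a protein alignment
#'
#' `d[i, j]` is the proportion of differing sites among sites where both
#' sequences are ungapped (`pairwise-deletion`, default). Under
#' `complete-deletion` every column containing a gap in any row is removed
#' first.
#'
#' @param aln Character matrix alignment from [read_alignment()] (rows =
#'   sequences, gap = `-`), at least 3 rows.
#' @param gap_policy `"pairwise-deletion"` or `"complete-deletion"`.
#' @return Symmetric numeric matrix with zero diagonal and the alignment row
#'   names as dimnames.
#' @export
p_distance <- function(aln, gap_policy = c("pairwise-deletion", "complete-deletion")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(is.matrix(aln))
  n <- nrow(aln)
  if (n < 3L) data_error("p-distance matrix needs at least 3 sequences")
  if (gap_policy == "complete-deletion") {
    keep <- colSums(aln == "-") == 0L
    if (!any(keep)) data_error("no gap-free columns under complete deletion")
    aln <- aln[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  ok <- aln != "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      data_error("no comparable sites between '%s' and '%s'",
                 rownames(aln)[i], rownames(aln)[j])
    d[i, j] <- d[j, i] <- sum(aln[i, comp] != aln[j, comp]) / nc
  }
  d
}

## Convert a recursive (children / edge-length) node structure rooted at a
## trifurcation into an ape "phylo" object, numbering internal nodes in
## preorder starting at ntip + 1 (ape's convention for the root).
nodes_to_phylo <- function(center) {
  count_tips <- function(nd) if (!is.null(nd$tip)) 1L else sum(vapply(nd$children, count_tips, integer(1)))
  ntip <- count_tips(center)
  env <- new.env()
  env$tip <- 0L; env$node <- ntip + 1L
  env$edge <- matrix(0L, 0, 2); env$len <- numeric(0); env$labels <- character(ntip)
  walk <- function(nd) {
    if (!is.null(nd$tip)) {
      env$tip <- env$tip + 1L
      env$labels[env$tip] <- nd$tip
      return(env$tip)
    }
    me <- env$node
    env$node <- env$node + 1L
    for (i in seq_along(nd$children)) {
      ## reserve the edge row before recursing to keep cladewise order
      row <- nrow(env$edge) + 1L
      env$edge <- rbind(env$edge, c(me, 0L))
      env$len <- c(env$len, nd$lengths[i])
      env$edge[row, 2] <- walk(nd$children[[i]])
    }
    me
  }
  walk(center)
  tr <- list(edge = env$edge, edge.length = env$len,
             tip.label = env$labels, Nnode = env$node - ntip - 1L)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined, branch lengths assigned by the rate-corrected
#' three-point formulas, and the matrix reduced. Ties are broken by the
#' lowest (i, j) index pair. Negative branch lengths are clamped to zero
#' with the deficit moved to the sister edge, preserving the path length
#' through the join. The result is unrooted (root trifurcation).
#'
#' @param D Symmetric numeric distance matrix with at least 3 taxa and
#'   taxon names as dimnames.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) data_error("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    data_error("distance matrix must be symmetric")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  nodes <- lapply(rownames(D), function(nm) list(tip = nm))
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_node <- list(children = list(nodes[[i]], nodes[[j]]), lengths = c(li, lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    n <- n - 1L
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  center <- list(children = nodes, lengths = lens)
  nodes_to_phylo(center)
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' The two ends of the tree diameter end up equidistant from the root. When
#' every branch length is zero the midpoint is undefined; the tree is then
#' rooted deterministically on the edge leading to the first tip.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return A rooted `ape::phylo` tree (root with 2 children).
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) data_error("midpoint rooting requires branch lengths")
  if (all(tree$edge.length == 0))
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  phangorn::midpoint(tree)
}

## Canonical string key for the unrooted bipartition induced by a tip set:
## the side not containing the first taxon (alphabetically), sorted.
split_key <- function(tips, all_taxa) {
  anchor <- min(all_taxa)
  side <- sort(tips)
  if (anchor %in% side) side <- sort(setdiff(all_taxa, side))
  paste(side, collapse = "|")
}

#' Non-trivial bipartitions (splits) of a tree
#'
#' @param tree An `ape::phylo` tree.
#' @return Named character vector: for each internal node other than the
#'   root, the canonical split key; names are the node numbers.
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  taxa <- tree$tip.label
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- taxa[i]
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  keys <- vapply(internal, function(nd) {
    side <- sets[[nd]]
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    split_key(side, taxa)
  }, character(1))
  names(keys) <- internal
  keys[!is.na(keys)]
}

#' Bootstrap supports for a neighbor-joining p-distance tree
#'
#' Alignment columns are resampled with replacement (same width) for each
#' replicate; p-distances and the NJ tree are recomputed and each internal
#' edge of the reference tree is scored by the fraction of replicates whose
#' tree contains the same leaf bipartition. Replicates in which some pair
#' has no comparable sites are dropped and counted.
#'
#' @param aln Alignment matrix (see [read_alignment()]).
#' @param replicates Number of bootstrap replicates; default 500.
#' @param gap_policy Passed to [p_distance()].
#' @param seed Integer seed.
#' @return List: `tree` (reference NJ tree with supports as `node.label`,
#'   fractions in `[0, 1]`), `supports` (named by split key), `dropped`
#'   (failed replicate count), `replicates_used`.
#' @export
bootstrap_support <- function(aln, replicates = 500, gap_policy = "pairwise-deletion",
                              seed = 1) {
  stopifnot(is_count1(replicates), replicates >= 1)
  ref <- nj_tree(p_distance(aln, gap_policy))
  keys <- tree_bipartitions(ref)
  counts <- stats::setNames(numeric(length(keys)), keys)
  L <- ncol(aln)
  dropped <- 0L
  with_rng_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_keys <- tryCatch(tree_bipartitions(nj_tree(p_distance(aln[, cols, drop = FALSE],
                                                                gap_policy))),
                           profam_data_error = function(e) NULL)
      if (is.null(rep_keys)) { dropped <- dropped + 1L; next }
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  used <- replicates - dropped
  if (used == 0L) data_error("all bootstrap replicates degenerate")
  supports <- counts / used
  names(supports) <- keys
  ref <- assign_supports(ref, supports)
  if (dropped > 0L)
    warning(sprintf("%d of %d bootstrap replicates dropped (pair with no comparable sites)",
                    dropped, replicates))
  list(tree = ref, supports = supports, dropped = dropped, replicates_used = used)
}

#' Attach bipartition supports to a tree as internal-node labels
#'
#' Useful after re-rooting: supports indexed by unrooted split keys are
#' looked up for every internal node of `tree` (root and trivial splits get
#' an empty label).
#'
#' @param tree An `ape::phylo` tree.
#' @param supports Named numeric vector keyed by canonical split strings, as
#'   returned by [bootstrap_support()].
#' @param digits Rounding for the printed labels; default 3.
#' @return The tree with `node.label` set.
#' @export
assign_supports <- function(tree, supports, digits = 3) {
  ntip <- length(tree$tip.label)
  keys <- tree_bipartitions(tree)
  lab <- rep("", tree$Nnode)
  for (k in seq_along(keys)) {
    nd <- as.integer(names(keys)[k])
    val <- supports[keys[k]]
    if (!is.na(val)) lab[nd - ntip] <- format(round(val, digits))
  }
  tree$node.label <- lab
  tree
}
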