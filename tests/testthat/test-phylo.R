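aln_from <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- paste0("t", seq_along(rows))
  m
}

test_that("p-distance counts differing sites over comparable columns", {
  a <- aln_from("AAAA", "AAAT", "AAAA")
  d <- p_distance(a)
  expect_equal(d["t1", "t2"], 0.25)
  expect_equal(d["t1", "t3"], 0)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d, t(d))

  g <- aln_from("AA-A", "AATA", "AAAA")
  expect_equal(p_distance(g, "pairwise-deletion")["t1", "t2"], 0)
  # complete deletion removes the gapped column: 3 comparable sites, 0 diffs
  expect_equal(p_distance(g, "complete-deletion")["t1", "t2"], 0)
  expect_equal(ncol(a) - 1, 3)
})

test_that("a pair with no comparable sites is an error", {
  a <- aln_from("A--A", "-AA-", "AAAA")
  expect_error(p_distance(a, "pairwise-deletion"), "comparable")
})

test_that("p-distance is invariant to row order", {
  set.seed(3)
  a <- gen_alignment(3, 2, 80, 0.05, 0.3, seed = 5)
  d1 <- p_distance(a)
  perm <- sample(nrow(a))
  d2 <- p_distance(a[perm, ])
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(length(tr$tip.label), 3L)
  dd <- tree_leaf_dists(tr)
  expect_equal(dd["a", "b"], 3)
  expect_equal(dd["a", "c"], 4)
  expect_equal(dd["b", "c"], 5)
  # closed form: la = (3 + 4 - 5) / 2 = 1, lb = 2, lc = 3
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(la, 1)
})

test_that("NJ recovers the generating four-taxon tree exactly", {
  gen <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  D <- ape::cophenetic.phylo(gen)
  tr <- nj_tree(D)
  expect_equal(tree_leaf_dists(tr), D[order(rownames(D)), order(colnames(D))],
               tolerance = 1e-9)
  # topology: {a,b} | {c,d} is a split of the NJ tree
  keys <- tree_bipartitions(tr)
  expect_true(profam:::split_key(c("a", "b"), tr$tip.label) %in% keys)
})

test_that("NJ reproduces path lengths of random additive matrices", {
  set.seed(101)
  for (i in 1:15) {
    k <- sample(4:12, 1)
    gen <- ape::rtree(k, br = runif)
    D <- ape::cophenetic.phylo(gen)
    tr <- nj_tree(D)
    expect_equal(length(tr$tip.label), k)
    expect_lt(max(abs(tree_leaf_dists(tr) - D[order(rownames(D)), order(colnames(D))])),
              1e-9)
  }
})

test_that("NJ topology agrees with an established implementation on additive input", {
  set.seed(55)
  gen <- ape::rtree(8, br = runif)
  D <- ape::cophenetic.phylo(gen)
  mine <- nj_tree(D)
  ref <- ape::nj(as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("midpoint rooting makes the diameter endpoints equidistant from the root", {
  two <- ape::read.tree(text = "(a:1,b:3);")
  r2 <- midpoint_root(two)
  dd <- ape::dist.nodes(r2)
  root <- length(r2$tip.label) + 1
  expect_equal(dd[1, root], 2)
  expect_equal(dd[2, root], 2)

  set.seed(9)
  for (i in 1:10) {
    tr <- ape::unroot(ape::rtree(sample(4:10, 1), br = runif))
    rooted <- midpoint_root(tr)
    ntip <- length(rooted$tip.label)
    dd <- ape::dist.nodes(rooted)
    leaf_d <- dd[1:ntip, 1:ntip]
    diam <- max(leaf_d)
    ends <- which(leaf_d == diam, arr.ind = TRUE)[1, ]
    root <- ntip + 1
    expect_equal(dd[ends[1], root], diam / 2, tolerance = 1e-9)
    expect_equal(dd[ends[2], root], diam / 2, tolerance = 1e-9)
    expect_equal(sum(rooted$edge[, 1] == root), 2)
  }
})

test_that("an all-zero-length tree is rooted deterministically", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  tr <- ape::unroot(tr)
  r1 <- midpoint_root(tr)
  r2 <- midpoint_root(tr)
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
  expect_equal(sum(r1$edge[, 1] == length(r1$tip.label) + 1), 2)
})

test_that("bootstrap supports are high on a strong-signal alignment and {0,1} for one replicate", {
  aln <- gen_alignment(4, 2, 200, 0.02, 0.4, seed = 3)
  one <- bootstrap_support(aln, replicates = 1, seed = 2)
  expect_true(all(one$supports %in% c(0, 1)))

  bs1 <- bootstrap_support(aln, replicates = 60, seed = 4)
  bs2 <- bootstrap_support(aln, replicates = 60, seed = 4)
  expect_identical(bs1$supports, bs2$supports)
  clade_keys <- grep("^clade(\\d)_leaf1\\|clade\\1_leaf2$", names(bs1$supports))
  expect_true(all(bs1$supports[clade_keys] >= 0.9))
})

test_that("bipartition keys are invariant to a consistent leaf renaming up to the mapping", {
  aln <- gen_alignment(3, 2, 100, 0.03, 0.35, seed = 8)
  tr <- nj_tree(p_distance(aln))
  keys <- sort(unname(tree_bipartitions(tr)))
  # apply a reversible renaming to the alignment rows
  map <- setNames(paste0("X", seq_len(nrow(aln))), rownames(aln))
  aln2 <- aln
  rownames(aln2) <- map[rownames(aln)]
  tr2 <- nj_tree(p_distance(aln2))
  keys2 <- sort(unname(tree_bipartitions(tr2)))
  rename_key <- function(k) {
    parts <- sort(unname(map[strsplit(k, "|", fixed = TRUE)[[1]]]))
    paste(parts, collapse = "|")
  }
  # same splits after pushing the renaming through (canonical side may flip)
  canon <- function(keys, taxa) {
    vapply(keys, function(k)
      profam:::split_key(strsplit(k, "|", fixed = TRUE)[[1]], taxa), character(1))
  }
  expect_setequal(canon(vapply(keys, rename_key, character(1)), unname(map)), keys2)
})

test_that("supports survive midpoint rooting via bipartition matching", {
  aln <- gen_alignment(4, 2, 150, 0.02, 0.4, seed = 6)
  bs <- bootstrap_support(aln, replicates = 40, seed = 1)
  rooted <- assign_supports(midpoint_root(bs$tree), bs$supports)
  have <- rooted$node.label[nzchar(rooted$node.label)]
  expect_gte(length(have), length(bs$supports) - 1)
  expect_true(all(as.numeric(have) >= 0 & as.numeric(have) <= 1))
})

test_that("asymmetric distance input is rejected", {
  D <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_tree(D), "symmetric")
})
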