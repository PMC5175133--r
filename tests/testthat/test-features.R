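test_that("the shipped property groupings partition the alphabet", {
  gps <- ctd_groupings()
  expect_length(gps, 8L)
  for (gp in gps) {
    all_aa <- unname(unlist(gp))
    expect_setequal(all_aa, AA)
    expect_length(all_aa, 20L)
    expect_equal(anyDuplicated(all_aa), 0L)
  }
})

test_that("amino-acid composition matches counting", {
  v <- aac20("AAAA")
  expect_equal(v[["A"]], 1.0)
  expect_equal(sum(v), 1.0)
  expect_equal(unname(aac20("ACDEFGHIKLMNPQRSTVWY")), rep(0.05, 20))
  set.seed(5)
  s <- random_seq(200)
  counts <- vapply(AA, function(a) sum(strsplit(s, "")[[1]] == a), numeric(1))
  expect_equal(unname(aac20(s)), unname(counts / 200))
})

test_that("CTD composition, transition and distribution match their definitions", {
  hp <- ctd_groupings()$hydrophobicity
  # homopolymer: K is in group 1 (polar)
  expect_equal(ctd_composition("KKKK", hp), c(1, 0, 0))
  expect_equal(ctd_transition("KKKK", hp), c(0, 0, 0))
  # alternating between groups 1 (K) and 3 (C)
  expect_equal(ctd_composition("KCKC", hp), c(0.5, 0, 0.5))
  expect_equal(ctd_transition("KC", hp), c(0, 1, 0))
  # "AAAA": A is hydrophobicity group 2
  d <- ctd_distribution("AAAA", hp)
  expect_equal(d[6:10], c(0.25, 0.25, 0.50, 0.75, 1.0))
  expect_equal(d[c(1:5, 11:15)], rep(0, 10))
  # single residue: transitions zero, all five distribution picks at its position
  expect_equal(ctd_transition("K", hp), c(0, 0, 0))
  expect_equal(ctd_distribution("K", hp)[1:5], rep(1, 5))
})

test_that("188D extraction agrees with an independently coded brute-force extractor", {
  expect_length(extract_188d("ACDEFGHIKLMNPQRSTVWY"), 188L)
  set.seed(99)
  lens <- c(2, 3, 5, sample(2:500, 97, replace = TRUE))
  for (L in lens) {
    s <- random_seq(L)
    expect_equal(unname(extract_188d(s)), oracle_188d(s), tolerance = 1e-12)
  }
})

test_that("feature blocks satisfy their structural invariants", {
  set.seed(21)
  gps <- ctd_groupings()
  for (i in 1:20) {
    v <- extract_188d(random_seq(sample(2:300, 1)))
    expect_equal(sum(v[1:20]), 1.0)
    expect_true(all(v >= 0))
    for (p in seq_along(gps)) {
      block <- v[20 + (p - 1) * 21 + 1:21]
      expect_equal(sum(block[1:3]), 1.0)        # composition
      expect_lte(sum(block[4:6]), 1.0)          # transition
      expect_true(all(block[7:21] >= 0 & block[7:21] <= 1))
      for (g in 1:3) {
        db <- block[6 + (g - 1) * 5 + 1:5]
        expect_true(all(diff(db) >= -1e-12))    # non-decreasing quantile positions
      }
    }
  }
})

`%+%` <- paste0

test_that("composition is permutation-invariant but transition is not", {
  set.seed(8)
  s <- random_seq(60)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(aac20(s), aac20(perm))
  hp <- ctd_groupings()$hydrophobicity
  # a homopolymer-block vs alternating arrangement of the same residues
  expect_false(isTRUE(all.equal(ctd_transition(strrep("K", 10) %+% strrep("C", 10), hp),
                                ctd_transition(strrep("KC", 10), hp))))
})

test_that("homopolymers have all transition features zero in the 188D vector", {
  v <- extract_188d(strrep("K", 30))
  trans_idx <- unlist(lapply(0:7, function(p) 20 + p * 21 + 4:6))
  expect_equal(unname(v[trans_idx]), rep(0, 24))
})

test_that("feature matrices keep labels and round-trip through TSV", {
  set.seed(4)
  recs <- data.frame(id = paste0("q", 1:3), desc = "",
                     seq = replicate(3, random_seq(50)))
  fm <- extract_matrix(recs, mode = "20d", label = "neg")
  expect_equal(dim(fm), c(3L, 22L))
  expect_equal(fm$label, rep("neg", 3))

  fm188 <- extract_matrix(recs, mode = "188d", label = "pos")
  both <- rbind(fm188, extract_matrix(recs, mode = "188d", label = "neg"))
  expect_equal(as.vector(table(both$label)), c(3L, 3L))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm188, f)
  back <- read_feature_matrix(f)
  expect_equal(names(back), names(fm188))
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(fm188[, -(1:2)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("records too short for 188D extraction fail with the offending id", {
  recs <- data.frame(id = c("ok", "short"), desc = "", seq = c("ACDEF", "A"))
  expect_error(extract_matrix(recs, mode = "188d"), "short")
})
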