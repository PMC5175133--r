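test_that("pairwise identity matches its definition on worked examples", {
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 1.0)
  expect_equal(pairwise_identity("ACDEF", "ACDEG"), 0.8)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  # shorter-sequence denominator: perfect substring
  expect_equal(pairwise_identity("ACDEFGHIKL", "DEFG"), 1.0)
})

test_that("identity equals the brute-force LCS oracle on random pairs", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    expect_equal(pairwise_identity(a, b),
                 oracle_lcs(a, b) / min(nchar(a), nchar(b)))
  }
})

make_records <- function(seqs) {
  data.frame(id = paste0("r", seq_along(seqs)), desc = "", seq = seqs,
             stringsAsFactors = FALSE)
}

test_that("greedy clustering merges near-identical sequences and separates unrelated ones", {
  s <- random_seq(100)
  # 5 substitutions => identity 0.95 >= 0.90
  mut <- strsplit(s, "")[[1]]
  for (p in c(3, 20, 50, 77, 99)) mut[p] <- setdiff(AA, mut[p])[1]
  variant <- paste(mut, collapse = "")
  cl <- cluster_sequences(make_records(c(s, variant)), 0.90)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 2L)

  cl2 <- cluster_sequences(make_records(c(s, s)), 0.9)
  expect_length(cl2, 1L)

  set.seed(7)
  cl3 <- cluster_sequences(make_records(c(random_seq(100), random_seq(100))), 0.9)
  expect_length(cl3, 2L)
})

test_that("representatives are the longest members and pairwise below threshold", {
  set.seed(3)
  base <- replicate(5, random_seq(80))
  fams <- unlist(lapply(base, function(s) {
    ch <- strsplit(s, "")[[1]]
    v <- vapply(1:3, function(k) {
      m <- ch
      for (p in sample(80, 4)) m[p] <- setdiff(AA, m[p])[1]
      paste(m[1:(80 - k + 1)], collapse = "")   # shorter variants
    }, character(1))
    c(s, v)
  }))
  thr <- 0.9
  cl <- cluster_sequences(make_records(fams), thr)
  reps <- vapply(cl, function(x) x$representative$seq, character(1))
  for (x in cl) {
    expect_true(all(nchar(x$members$seq) <= nchar(x$representative$seq)))
    expect_true(all(x$identities >= thr))
  }
  if (length(reps) > 1) {
    for (i in 1:(length(reps) - 1)) for (j in (i + 1):length(reps))
      expect_lt(pairwise_identity(reps[i], reps[j]), thr)
  }
})

test_that("nonredundant keeps one representative per family; threshold 1 keeps distinct sequences", {
  recs <- make_records(c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(nrow(nonredundant(recs, 0.9)), 1L)

  distinct <- make_records(c("ACDEFGHIKL", "ACDEFGHIKV", "ACDEFGHIVV"))
  expect_equal(nrow(nonredundant(distinct, 1.0)), 3L)
})

test_that("cluster count is monotone non-increasing as the threshold decreases", {
  set.seed(12)
  base <- replicate(4, random_seq(60))
  recs <- make_records(unlist(lapply(base, function(s) {
    ch <- strsplit(s, "")[[1]]
    c(s, vapply(1:2, function(k) {
      m <- ch; for (p in sample(60, 6)) m[p] <- setdiff(AA, m[p])[1]
      paste(m, collapse = "")
    }, character(1)))
  })))
  counts <- vapply(c(1.0, 0.95, 0.9, 0.7, 0.4, 0.05),
                   function(t) length(cluster_sequences(recs, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the composition prefilter never changes the clustering", {
  set.seed(19)
  base <- replicate(3, random_seq(70))
  recs <- make_records(c(unlist(lapply(base, function(s) {
    ch <- strsplit(s, "")[[1]]
    c(s, {
      m <- ch; for (p in sample(70, 5)) m[p] <- setdiff(AA, m[p])[1]
      paste(m, collapse = "")
    })
  })), replicate(6, random_seq(sample(40:90, 1)))))
  for (thr in c(0.5, 0.8, 0.9)) {
    a <- cluster_sequences(recs, thr, prefilter = TRUE)
    b <- cluster_sequences(recs, thr, prefilter = FALSE)
    expect_identical(a, b)
  }
})

test_that("cluster table lists every member with its representative and identity", {
  recs <- make_records(c("ACDEFGHIKL", "ACDEFGHIKV", "WWWWYYYYWWYY"))
  tab <- cluster_table(cluster_sequences(recs, 0.9))
  expect_setequal(tab$member_id, recs$id)
  expect_true(all(tab$identity >= 0.9))
})
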