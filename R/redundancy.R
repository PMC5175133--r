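## match=+1, mismatch=0, gap=0 scoring: the optimal global-alignment score
## equals the maximum number of identical aligned pairs (the LCS length).
identity_submat <- local({
  m <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  diag(m) <- 1
  m
})

## Max number of identical aligned residue pairs between one subject and a
## set of patterns, in a single vectorized alignment call.
match_counts <- function(patterns, subject) {
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = Biostrings::AAString(subject),
    substitutionMatrix = identity_submat,
    gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE))
}

#' Fractional sequence identity between two proteins
#'
#' Identity is the maximum number of identical aligned residue pairs under a
#' global alignment with match = +1, mismatch = 0 and free gaps, divided by
#' the length of the shorter sequence — the convention used by greedy
#' incremental clustering tools such as CD-HIT.
#'
#' @param a,b Amino-acid sequences (character scalars, canonical alphabet).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACDEF", "ACDEF")  # 1
#' pairwise_identity("ACDEF", "ACDEG")  # 0.8
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  match_counts(a, b) / min(nchar(a), nchar(b))
}

#' Greedy incremental clustering at an identity threshold
#'
#' Records are sorted by length (longest first, stable for ties); each record
#' joins the first existing cluster whose representative it matches at or
#' above `threshold`, otherwise it founds a new cluster. Only representatives
#' are ever compared, as in CD-HIT, so representatives are pairwise below the
#' threshold.
#'
#' A composition screen skips alignments that cannot reach the threshold:
#' the number of identical aligned pairs is at most the per-letter count
#' overlap of the two sequences, so the bound `sum_a min(n_a, m_a) /
#' min(L_a, L_b)` is an upper bound on identity. The screen only prunes
#' provably hopeless comparisons and never changes the clustering.
#'
#' @param records Data frame of protein records (see [read_fasta()]).
#' @param threshold Identity cut-off in `(0, 1]`; default 0.90.
#' @param prefilter Apply the composition screen; results are identical
#'   either way (exposed for testing).
#' @return A list of clusters, each a list with elements `representative`
#'   (row index into the length-sorted input is resolved for you: it is a
#'   one-row data frame), `members` (data frame, representative first) and
#'   `identities` (identity of each member to the representative).
#' @export
cluster_sequences <- function(records, threshold = 0.90, prefilter = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (!(threshold > 0 && threshold <= 1)) data_error("threshold must be in (0, 1]")
  ord <- order(-nchar(records$seq))   # stable: ties keep input order
  recs <- records[ord, , drop = FALSE]
  counts <- t(vapply(recs$seq, function(s)
    as.integer(table(factor(strsplit(s, "", fixed = TRUE)[[1]], levels = AA20))),
    integer(20), USE.NAMES = FALSE))
  reps <- character(0)                # representative sequences
  rep_counts <- matrix(0L, 0, 20)
  cl_members <- list()
  cl_ident <- list()
  for (i in seq_len(nrow(recs))) {
    s <- recs$seq[i]
    placed <- FALSE
    if (length(reps)) {
      minlen <- pmin(nchar(reps), nchar(s))
      cand <- seq_along(reps)
      if (prefilter) {
        overlap <- rowSums(pmin(rep_counts, rep(counts[i, ], each = nrow(rep_counts))))
        cand <- cand[overlap / minlen >= threshold]
      }
      if (length(cand)) {
        ident <- match_counts(reps[cand], s) / minlen[cand]
        hit <- which(ident >= threshold)
        if (length(hit)) {
          j <- cand[hit[1]]
          cl_members[[j]] <- c(cl_members[[j]], i)
          cl_ident[[j]] <- c(cl_ident[[j]], ident[hit[1]])
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      rep_counts <- rbind(rep_counts, counts[i, ])
      cl_members[[length(reps)]] <- i
      cl_ident[[length(reps)]] <- 1
    }
  }
  lapply(seq_along(cl_members), function(j) {
    idx <- cl_members[[j]]
    list(representative = recs[idx[1], , drop = FALSE],
         members = recs[idx, , drop = FALSE],
         identities = cl_ident[[j]])
  })
}

#' Non-redundant representatives of a sequence set
#'
#' Convenience wrapper over [cluster_sequences()] returning one
#' representative per cluster, in cluster-creation order.
#'
#' @inheritParams cluster_sequences
#' @return Data frame of representative records.
#' @export
nonredundant <- function(records, threshold = 0.90) {
  cl <- cluster_sequences(records, threshold)
  do.call(rbind, lapply(cl, `[[`, "representative"))
}

#' Cluster membership table
#'
#' @param clusters Result of [cluster_sequences()].
#' @return Data frame with columns `member_id`, `representative_id`,
#'   `identity`.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(member_id = cl$members$id,
               representative_id = cl$representative$id,
               identity = cl$identities,
               stringsAsFactors = FALSE)
  }))
}
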