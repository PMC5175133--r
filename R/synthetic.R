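#' Specification of a synthetic protein family
#'
#' Describes an i.i.d. compositional model from which a family of sequences
#' is drawn: a background residue distribution, an optional shift of
#' probability mass toward a designated residue subset (compositional bias),
#' and an optional fixed motif embedded once at a random position.
#'
#' @param n Number of sequences.
#' @param length_range Integer pair `(min, max)` of sequence lengths.
#' @param background Named length-20 frequency vector over the amino-acid
#'   alphabet, summing to 1; default uniform.
#' @param motif Optional peptide (canonical letters) inserted once per
#'   sequence; `min(length_range)` must be at least its length.
#' @param bias_residues Residue subset receiving extra probability mass.
#' @param bias_strength Total probability mass moved onto `bias_residues`
#'   (their target total is the background total plus this amount, capped at
#'   1); other residues are scaled down proportionally.
#' @param seed Integer seed.
#' @return List of class `family_spec`.
#' @export
family_spec <- function(n, length_range = c(100, 300), background = NULL,
                        motif = NULL, bias_residues = NULL, bias_strength = 0,
                        seed = 1) {
  stopifnot(is_count1(n), n >= 1, length(length_range) == 2L,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            bias_strength >= 0)
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), AA20)
  stopifnot(setequal(names(background), AA20),
            abs(sum(background) - 1) < 1e-9, all(background >= 0))
  background <- background[AA20]
  if (!is.null(bias_residues) && bias_strength > 0) {
    stopifnot(all(bias_residues %in% AA20))
    tgt <- min(1, sum(background[bias_residues]) + bias_strength)
    other <- setdiff(AA20, bias_residues)
    background[bias_residues] <- background[bias_residues] *
      (tgt / sum(background[bias_residues]))
    background[other] <- background[other] * ((1 - tgt) / sum(background[other]))
  }
  if (!is.null(motif)) {
    stopifnot(is.character(motif), nzchar(motif))
    if (!all(strsplit(motif, "")[[1]] %in% AA20))
      data_error("motif must use canonical residues")
    if (length_range[1] < nchar(motif))
      data_error("minimum length %d shorter than motif (%d)",
                 length_range[1], nchar(motif))
  }
  structure(list(n = n, length_range = as.integer(length_range),
                 background = background, motif = motif, seed = seed),
            class = "family_spec")
}

#' Generate a synthetic protein family
#'
#' @param spec A [family_spec()].
#' @param prefix Id prefix; records are named `<prefix>1 ... <prefix>n`.
#' @return Data frame of protein records (columns `id`, `desc`, `seq`).
#' @export
gen_family <- function(spec, prefix = "seq") {
  stopifnot(inherits(spec, "family_spec"))
  with_rng_seed(spec$seed, {
    seqs <- vapply(seq_len(spec$n), function(i) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1)
      s <- sample(AA20, L, replace = TRUE, prob = spec$background)
      if (!is.null(spec$motif)) {
        mlen <- nchar(spec$motif)
        at <- sample.int(L - mlen + 1L, 1)
        s[at:(at + mlen - 1L)] <- strsplit(spec$motif, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    data.frame(id = paste0(prefix, seq_len(spec$n)), desc = "synthetic",
               seq = seqs, stringsAsFactors = FALSE)
  })
}

#' Generate a gap-free synthetic alignment with clade structure
#'
#' A random root sequence is mutated at rate `between_divergence` to form one
#' ancestor per clade, and each ancestor is mutated at rate
#' `within_divergence` to form its leaves. Mutation replaces a site with a
#' uniformly random different residue; there are no indels.
#'
#' @param n_clades,leaves_per_clade Clade structure.
#' @param length Alignment width.
#' @param within_divergence,between_divergence Per-site substitution
#'   probabilities in `[0, 1)`, within strictly less than between.
#' @param seed Integer seed.
#' @return Character matrix alignment; rows named `cladeC_leafL`.
#' @export
gen_alignment <- function(n_clades, leaves_per_clade, length = 200,
                          within_divergence = 0.05, between_divergence = 0.4,
                          seed = 1) {
  stopifnot(is_count1(n_clades), is_count1(leaves_per_clade),
            n_clades >= 2, leaves_per_clade >= 1, length >= 1)
  if (!(within_divergence >= 0 && within_divergence < 1 &&
        between_divergence > 0 && between_divergence < 1))
    data_error("divergence rates must lie in [0, 1)")
  if (between_divergence <= within_divergence)
    data_error("between_divergence must exceed within_divergence")
  mutate <- function(s, rate) {
    hit <- which(stats::runif(length(s)) < rate)
    for (p in hit) s[p] <- sample(setdiff(AA20, s[p]), 1)
    s
  }
  with_rng_seed(seed, {
    root <- sample(AA20, length, replace = TRUE)
    rows <- list()
    for (cl in seq_len(n_clades)) {
      anc <- mutate(root, between_divergence)
      for (lf in seq_len(leaves_per_clade))
        rows[[paste0("clade", cl, "_leaf", lf)]] <- mutate(anc, within_divergence)
    }
    m <- do.call(rbind, rows)
    rownames(m) <- names(rows)
    m
  })
}

#' Generate a synthetic Ct table for qPCR power tests
#'
#' Control delta-Ct values are drawn from `Normal(base_dct, noise_sd)`; case
#' values are shifted by `effect_dct` per gene (negative values mean
#' up-regulation in cases). The reference-gene Ct is fixed at 20 so
#' `ct_target = 20 + delta Ct`.
#'
#' @param n_per_group Samples per group.
#' @param genes Character vector of gene names.
#' @param effect_dct Per-gene delta-Ct shift (scalar recycled, or named by
#'   gene).
#' @param noise_sd Biological noise standard deviation (cycles), >= 0.
#' @param base_dct Baseline delta-Ct; default 5.
#' @param seed Integer seed.
#' @return Ct table data frame (see [read_ct_table()] for the schema).
#' @export
gen_ct_table <- function(n_per_group, genes, effect_dct = 0, noise_sd = 0.5,
                         base_dct = 5, seed = 1) {
  stopifnot(is_count1(n_per_group), n_per_group >= 1, noise_sd >= 0,
            length(genes) >= 1)
  eff <- if (is.null(names(effect_dct))) stats::setNames(rep_len(effect_dct, length(genes)), genes)
         else effect_dct[genes]
  with_rng_seed(seed, {
    out <- list()
    for (g in genes) {
      dct_control <- stats::rnorm(n_per_group, base_dct, noise_sd)
      dct_case <- stats::rnorm(n_per_group, base_dct + eff[[g]], noise_sd)
      out[[g]] <- data.frame(
        sample_id = c(paste0("control", seq_len(n_per_group)),
                      paste0("case", seq_len(n_per_group))),
        group = rep(c("control", "case"), each = n_per_group),
        gene = g,
        ct_target = 20 + c(dct_control, dct_case),
        ct_reference = 20,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
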