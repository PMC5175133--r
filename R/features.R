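## Canonical 3-class partitions of the 20 amino acids for the eight
## physicochemical properties used by the 188D CTD descriptor set.
## Groupings follow the classic composition/transition/distribution
## literature (Dubchak et al. 1995, PNAS 92:8700; Cai et al. 2003, NAR
## 31:3692) plus the surface-tension partition used by the 188D descriptor
## family. Published variants differ slightly in the surface-tension
## partition; the one shipped here is the most common and can be overridden
## by passing a custom grouping.
CTD_GROUPINGS <- list(
  hydrophobicity = list(
    g1 = c("R","K","E","D","Q","N"),                       # polar
    g2 = c("G","A","S","T","P","H","Y"),                   # neutral
    g3 = c("C","L","V","I","M","F","W")),                  # hydrophobic
  normalized.vdw.volume = list(
    g1 = c("G","A","S","T","P","D","C"),                   # 0 - 2.78
    g2 = c("N","V","E","Q","I","L"),                       # 2.95 - 4.0
    g3 = c("M","H","K","F","R","Y","W")),                  # 4.03 - 8.08
  polarity = list(
    g1 = c("L","I","F","W","C","M","V","Y"),               # 4.9 - 6.2
    g2 = c("P","A","T","G","S"),                           # 8.0 - 9.2
    g3 = c("H","Q","R","K","N","E","D")),                  # 10.4 - 13.0
  polarizability = list(
    g1 = c("G","A","S","D","T"),                           # 0 - 0.108
    g2 = c("C","P","N","V","E","Q","I","L"),               # 0.128 - 0.186
    g3 = c("K","M","H","F","R","Y","W")),                  # 0.219 - 0.409
  charge = list(
    g1 = c("K","R"),                                       # positive
    g2 = c("A","N","C","Q","G","H","I","L","M","F","P","S","T","W","Y","V"),
    g3 = c("D","E")),                                      # negative
  secondary.structure = list(
    g1 = c("E","A","L","M","Q","K","R","H"),               # helix
    g2 = c("V","I","Y","C","W","F","T"),                   # strand
    g3 = c("G","N","P","S","D")),                          # coil
  solvent.accessibility = list(
    g1 = c("A","L","F","C","G","I","V","W"),               # buried
    g2 = c("P","K","Q","E","N","D"),                       # exposed
    g3 = c("M","R","S","T","H","Y")),                      # intermediate
  surface.tension = list(
    g1 = c("G","Q","D","N","A","H","R"),                   # -0.20 - 0.16
    g2 = c("K","T","S","E","C"),                           # -0.30 - -0.52
    g3 = c("I","L","M","F","P","W","Y","V")))              # -0.98 - -2.46

#' Physicochemical groupings behind the 188D CTD features
#'
#' Returns the eight named 3-class partitions of the amino-acid alphabet
#' (hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, secondary structure, solvent accessibility,
#' surface tension) used to compute composition, transition and
#' distribution descriptors. Each element is a list of three disjoint
#' character vectors whose union is the 20 canonical letters.
#'
#' @return Named list of 8 groupings.
#' @export
ctd_groupings <- function() CTD_GROUPINGS

## 1/2/3 group membership lookup named by residue.
grouping_index <- function(grouping) {
  stopifnot(length(grouping) == 3L)
  all_aa <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(all_aa) || !setequal(all_aa, AA20))
    data_error("grouping must partition the 20-letter alphabet into 3 classes")
  idx <- integer(20)
  names(idx) <- AA20
  for (g in 1:3) idx[grouping[[g]]] <- g
  idx
}

seq_chars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) data_error("empty sequence")
  if (!all(ch %in% AA20)) data_error("sequence contains non-canonical residues; sanitize first")
  ch
}

#' Amino-acid composition (20D)
#'
#' @param seq Sanitized amino-acid sequence.
#' @return Named numeric vector of length 20 (A..Y, alphabetical):
#'   per-residue frequency `count / length`; sums to 1.
#' @export
aac20 <- function(seq) {
  ch <- seq_chars(seq)
  tab <- table(factor(ch, levels = AA20))
  v <- as.numeric(tab) / length(ch)
  names(v) <- AA20
  v
}

#' CTD composition for one property grouping
#'
#' @param seq Sanitized sequence.
#' @param grouping One element of [ctd_groupings()] (a 3-class partition).
#' @return Fraction of residues in groups 1, 2, 3; sums to 1.
#' @export
ctd_composition <- function(seq, grouping) {
  g <- grouping_index(grouping)[seq_chars(seq)]
  as.numeric(tabulate(g, nbins = 3)) / length(g)
}

#' CTD transition for one property grouping
#'
#' Frequencies of adjacent residue pairs crossing between two different
#' groups, for the unordered pairs (1,2), (1,3), (2,3), each divided by
#' `L - 1`. A single-residue sequence returns zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of length 3.
#' @export
ctd_transition <- function(seq, grouping) {
  g <- grouping_index(grouping)[seq_chars(seq)]
  L <- length(g)
  if (L < 2L) return(c(0, 0, 0))
  a <- g[-L]; b <- g[-1]
  c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
    sum((a == 1 & b == 3) | (a == 3 & b == 1)),
    sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (L - 1)
}

#' CTD distribution for one property grouping
#'
#' For each group, the 1-based sequence positions of its first occurrence
#' and of the residues at the ceiling of 25%, 50%, 75% and 100% of the
#' group's occurrence count, each divided by the sequence length. Groups
#' with no occurrence contribute five zeros. Values are fractions in
#' `[0, 1]`.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of length 15 (group 1 block, then 2, then 3).
#' @export
ctd_distribution <- function(seq, grouping) {
  g <- grouping_index(grouping)[seq_chars(seq)]
  L <- length(g)
  out <- numeric(0)
  for (grp in 1:3) {
    pos <- which(g == grp)
    n <- length(pos)
    if (n == 0L) {
      out <- c(out, rep(0, 5))
    } else {
      idx <- c(1L, ceiling(0.25 * n), ceiling(0.50 * n), ceiling(0.75 * n), n)
      out <- c(out, unname(pos[idx]) / L)
    }
  }
  out
}

ctd_feature_names <- function() {
  unlist(lapply(names(CTD_GROUPINGS), function(p)
    paste(p, c("C1", "C2", "C3", "T12", "T13", "T23",
               paste0("G", rep(1:3, each = 5), ".D",
                      rep(c("first", "25", "50", "75", "100"), 3))),
          sep = ".")), use.names = FALSE)
}

#' Extract the 188-dimensional feature vector
#'
#' Concatenates the 20 amino-acid composition features with, for each of the
#' eight physicochemical groupings, 3 composition + 3 transition + 15
#' distribution descriptors (8 x 21 = 168), for 188 features in a fixed,
#' documented order.
#'
#' @param seq Sanitized sequence of length at least 2.
#' @param groupings Property groupings; defaults to [ctd_groupings()].
#' @return Named numeric vector of length 188.
#' @export
extract_188d <- function(seq, groupings = ctd_groupings()) {
  ch <- seq_chars(seq)
  if (length(ch) < 2L) data_error("188D extraction needs sequence length >= 2")
  ctd <- unlist(lapply(groupings, function(gp)
    c(ctd_composition(seq, gp), ctd_transition(seq, gp), ctd_distribution(seq, gp))),
    use.names = FALSE)
  v <- c(aac20(seq), ctd)
  names(v) <- c(paste0("AAC.", AA20), ctd_feature_names())
  v
}

#' Extract the 20-dimensional (composition-only) feature vector
#'
#' @param seq Sanitized sequence.
#' @return Named numeric vector of length 20.
#' @export
extract_20d <- function(seq) {
  v <- aac20(seq)
  names(v) <- paste0("AAC.", AA20)
  v
}

#' Feature matrix for a set of protein records
#'
#' @param records Data frame of protein records (see [read_fasta()]).
#' @param mode `"188d"` or `"20d"`.
#' @param label Class tag attached to every row (e.g. `"pos"`, `"neg"`).
#' @return Data frame with columns `id`, `label`, then the named features,
#'   one row per record in input order.
#' @export
extract_matrix <- function(records, mode = c("188d", "20d"), label = "pos") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(
      if (mode == "188d") extract_188d(records$seq[i]) else extract_20d(records$seq[i]),
      error = function(e) data_error("record '%s': %s", records$id[i],
                                     conditionMessage(e)))
  })
  m <- do.call(rbind, rows)
  cbind(data.frame(id = records$id, label = label, stringsAsFactors = FALSE),
        as.data.frame(m))
}

#' Write / read a feature matrix as TSV
#'
#' @param fm Feature matrix from [extract_matrix()] (or several `rbind`ed).
#' @param path File path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns the data frame.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.table(fm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) data_error("file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

## numeric feature block of a feature matrix
feature_values <- function(fm) as.matrix(fm[, setdiff(names(fm), c("id", "label")), drop = FALSE])
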