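#' Sanitize a raw amino-acid sequence
#'
#' Restricts a sequence to the 20 canonical amino-acid letters. Database
#' entries frequently contain ambiguity or rare-residue codes (B, Z, X, U,
#' O, J) that downstream composition features cannot use.
#'
#' @param raw Non-empty character scalar; case is ignored, whitespace removed.
#' @param policy One of:
#'   * `"map-common"` (default): map B to N, Z to Q, U to C, O to K, J to L,
#'     then drop any remaining X or `*`;
#'   * `"drop-residue"`: delete every non-canonical letter;
#'   * `"error"`: fail on the first non-canonical letter.
#' @return The sanitized uppercase sequence.
#' @examples
#' sanitize_sequence("ACDX", "drop-residue")  # "ACD"
#' sanitize_sequence("ABZ", "map-common")     # "ANQ"
#' @export
sanitize_sequence <- function(raw, policy = c("map-common", "drop-residue", "error")) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(s)) data_error("sequence is empty")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  canon <- ch %in% AA20
  if (policy == "error") {
    if (!all(canon))
      data_error("non-canonical residue(s): %s",
                 paste(unique(ch[!canon]), collapse = ", "))
  } else if (policy == "drop-residue") {
    ch <- ch[canon]
  } else {
    map <- c(B = "N", Z = "Q", U = "C", O = "K", J = "L")
    hit <- ch %in% names(map)
    ch[hit] <- map[ch[hit]]
    ch <- ch[!(ch %in% c("X", "*"))]
    bad <- !(ch %in% AA20)
    if (any(bad))
      data_error("unrecognized character(s) in sequence: %s",
                 paste(unique(ch[bad]), collapse = ", "))
  }
  if (length(ch) == 0L) data_error("sequence empty after sanitization")
  paste(ch, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param policy Sanitization policy passed to [sanitize_sequence()].
#' @return A data frame with columns `id` (first whitespace-delimited header
#'   token), `desc` (remainder of the header) and `seq` (sanitized sequence).
#' @export
read_fasta <- function(path, policy = "map-common") {
  if (!file.exists(path)) data_error("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) data_error("cannot parse FASTA '%s': %s",
                                                 path, conditionMessage(e)))
  if (length(set) == 0L) data_error("no sequences in %s", path)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers))))
    data_error("FASTA record with empty header in %s", path)
  id <- sub("\\s.*$", "", trimws(headers))
  desc <- trimws(sub("^\\S+\\s*", "", trimws(headers)))
  dup <- id[duplicated(id)]
  if (length(dup))
    data_error("duplicate sequence id(s): %s", paste(unique(dup), collapse = ", "))
  raw <- as.character(set)
  empty <- !nzchar(raw)
  if (any(empty))
    data_error("record(s) with empty sequence: %s", paste(id[empty], collapse = ", "))
  seq <- vapply(raw, sanitize_sequence, character(1), policy = policy, USE.NAMES = FALSE)
  data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  nm <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- nm
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or CLUSTAL `.aln` input and returns the alignment
#' as a character matrix (one row per sequence, one column per site,
#' residues uppercase, gaps as `-`). Dots are treated as gaps.
#'
#' @param path Input path.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return Character matrix with sequence ids as row names.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) data_error("file not found: %s", path)
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", trimws(names(set)))
    rows <- as.character(set)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
      data_error("'%s' does not look like a CLUSTAL file (missing header)", path)
    chunks <- list()
    for (ln in lines[-1]) {
      ## sequence lines are "name  block"; consensus lines start with space
      if (!grepl("^\\S", ln)) next
      m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.*-]+)\\s*\\d*$", ln))[[1]]
      if (length(m) != 3L) next
      chunks[[m[2]]] <- paste0(if (is.null(chunks[[m[2]]])) "" else chunks[[m[2]]], m[3])
    }
    if (length(chunks) == 0L) data_error("no sequence blocks found in '%s'", path)
    ids <- names(chunks)
    rows <- unlist(chunks, use.names = FALSE)
  }
  if (length(rows) < 2L) data_error("alignment needs at least 2 rows")
  rows <- chartr(".", "-", toupper(rows))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    data_error("ragged alignment: row lengths %s", paste(unique(lens), collapse = ", "))
  if (lens[1] < 1L) data_error("alignment has zero columns")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bad <- !(m %in% c(AA20, "-"))
  if (any(bad))
    data_error("alignment contains non amino-acid character(s): %s",
               paste(unique(m[bad]), collapse = ", "))
  rownames(m) <- ids
  m
}

## Quote a Newick label when it contains metacharacters.
newick_quote <- function(x) {
  needs <- grepl("[][(){}:;,'[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a phylogenetic tree to Newick
#'
#' Writes branch lengths and, when present, internal-node labels (used by
#' this package for bootstrap supports). Leaf names containing Newick
#' metacharacters are single-quoted.
#'
#' @param tree An `ape::phylo` tree with at least 2 leaves.
#' @param path Output path.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2L) data_error("tree must have at least 2 leaves")
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- newick_quote(tree$tip.label)
  nlab <- tree$node.label
  fmt_len <- function(x) {
    if (is.null(x) || is.na(x)) "" else paste0(":", sprintf("%.10g", x))
  }
  rec <- function(node, len) {
    if (node <= ntip) return(paste0(lab[node], fmt_len(len)))
    ed <- kids[[as.character(node)]]
    inner <- vapply(ed, function(e)
      rec(tree$edge[e, 2], if (is.null(tree$edge.length)) NA_real_
          else tree$edge.length[e]), character(1))
    nl <- if (!is.null(nlab)) {
      l <- nlab[node - ntip]
      if (is.na(l) || !nzchar(l)) "" else newick_quote(l)
    } else ""
    paste0("(", paste(inner, collapse = ","), ")", nl, fmt_len(len))
  }
  root <- ntip + 1L
  s <- paste0(rec(root, NA_real_), ";")
  writeLines(s, path)
  invisible(s)
}
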