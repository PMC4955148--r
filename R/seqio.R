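# seqio: FASTA / aligned-FASTA input-output and validation.
# Parsing is delegated to Biostrings; the validation layer on top enforces the
# toolkit's alphabet and identifier contracts.

#' Construct a protein sequence collection
#'
#' An `aa_seqs` object is a data frame with columns `id`, `desc` and `seq`
#' holding unaligned protein sequences over the 20 standard amino-acid
#' letters plus `X` (unknown). Ids must be unique non-empty tokens.
#'
#' @param id character vector of unique sequence identifiers (no whitespace).
#' @param seq character vector of residue strings (upper-cased on input).
#' @param desc character vector of free-text descriptions (default `""`).
#' @return An object of class `aa_seqs` (a data frame).
#' @examples
#' aa_seqs(c("s1", "s2"), c("ACDEF", "GHIKL"))
#' @export
aa_seqs <- function(id, seq, desc = "") {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  desc <- rep_len(as.character(desc), length(id))
  stopifnot(length(id) == length(seq))
  if (length(id)) {
    if (any(!nzchar(id)) || any(grepl("\\s", id)))
      stop("sequence ids must be non-empty tokens without whitespace")
    dup <- unique(id[duplicated(id)])
    if (length(dup))
      stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
    for (i in seq_along(seq)) .check_residues(seq[i], id[i], gaps = FALSE)
  }
  structure(data.frame(id = id, desc = desc, seq = seq,
                       stringsAsFactors = FALSE),
            class = c("aa_seqs", "data.frame"))
}

#' Construct a protein multiple sequence alignment
#'
#' An `aa_msa` holds equal-length aligned rows over the amino-acid alphabet
#' plus the gap character `-`. De-gapping a row recovers the member's
#' unaligned residues.
#'
#' @param id character vector of unique row identifiers.
#' @param seq character vector of aligned rows (equal lengths; `.` is
#'   normalized to `-`).
#' @param desc optional descriptions.
#' @return An object of class `aa_msa` with fields `id`, `desc`, `seq` and
#'   `width` (number of columns).
#' @examples
#' aa_msa(c("a", "b"), c("AC-D", "ACED"))
#' @export
aa_msa <- function(id, seq, desc = "") {
  id <- as.character(id)
  seq <- gsub(".", "-", toupper(as.character(seq)), fixed = TRUE)
  desc <- rep_len(as.character(desc), length(id))
  if (length(id) < 1L) stop("an alignment needs at least one member")
  if (any(!nzchar(id)) || any(grepl("\\s", id)))
    stop("sequence ids must be non-empty tokens without whitespace")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  w <- nchar(seq)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    stop("ragged alignment: row '", id[bad], "' has length ", w[bad],
         " but row '", id[1L], "' has length ", w[1L])
  }
  for (i in seq_along(seq)) .check_residues(seq[i], id[i], gaps = TRUE)
  structure(list(id = id, desc = desc, seq = seq, width = w[1L]),
            class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat("aa_msa: ", length(x$id), " sequences x ", x$width, " columns\n",
      sep = "")
  invisible(x)
}

#' Remove gap characters from aligned rows
#'
#' @param x an `aa_msa` object.
#' @return An `aa_seqs` with the de-gapped member sequences.
#' @export
degap <- function(x) {
  stopifnot(inherits(x, "aa_msa"))
  aa_seqs(x$id, gsub("-", "", x$seq, fixed = TRUE), x$desc)
}

.check_residues <- function(s, id, gaps = FALSE) {
  if (!nzchar(s)) stop("sequence '", id, "' is empty")
  allowed <- c(AA_ALPHABET, "X", if (gaps) "-")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!(ch %in% allowed))
  if (length(bad))
    stop("illegal residue character '", ch[bad[1L]], "' at position ",
         bad[1L], " in sequence '", id, "'")
  invisible(TRUE)
}

.parse_fasta_names <- function(nm) {
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  list(id = id, desc = desc)
}

.read_raw_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L ||
      !any(startsWith(readLines(path, n = 50L, warn = FALSE), ">")))
    return(list(id = character(), desc = character(), seq = character()))
  set <- Biostrings::readBStringSet(path)
  nm <- .parse_fasta_names(names(set))
  list(id = nm$id, desc = nm$desc, seq = toupper(as.character(set)))
}

#' Read protein sequences from a FASTA file
#'
#' Residues are upper-cased and a terminal `*` (stop) is stripped. The id is
#' the first whitespace-delimited token of the header, the description the
#' remainder. The ambiguity letters B, Z, J, U, O are rejected by default;
#' with `map_ambiguous = TRUE` they are mapped to `X`.
#'
#' @param path path to a FASTA file.
#' @param map_ambiguous map B/Z/J/U/O to `X` instead of erroring.
#' @return An [aa_seqs] collection (empty for an empty file).
#' @export
read_fasta <- function(path, map_ambiguous = FALSE) {
  raw <- .read_raw_fasta(path)
  s <- sub("\\*$", "", raw$seq)
  if (map_ambiguous)
    s <- chartr(paste(AA_AMBIGUOUS, collapse = ""),
                strrep("X", length(AA_AMBIGUOUS)), s)
  aa_seqs(raw$id, s, raw$desc)
}

#' Write protein sequences to a FASTA file
#'
#' `read_fasta(write_fasta(x, path))` is the identity on
#' (id, description, residues).
#'
#' @param records an [aa_seqs] collection.
#' @param path output path.
#' @param wrap sequence line width (default 60 columns).
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(inherits(records, "aa_seqs"), wrap >= 1L)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' Rows must have equal aligned length; `.` gaps are normalized to `-`.
#'
#' @param path path to an aligned FASTA file.
#' @param map_ambiguous map B/Z/J/U/O to `X` instead of erroring.
#' @return An [aa_msa] object.
#' @export
read_alignment <- function(path, map_ambiguous = FALSE) {
  raw <- .read_raw_fasta(path)
  if (!length(raw$id)) stop("empty alignment file: ", path)
  s <- sub("\\*$", "", raw$seq)
  if (map_ambiguous)
    s <- chartr(paste(AA_AMBIGUOUS, collapse = ""),
                strrep("X", length(AA_AMBIGUOUS)), s)
  aa_msa(raw$id, s, raw$desc)
}

#' Write an alignment to aligned FASTA
#'
#' @param msa an [aa_msa] object.
#' @param path output path.
#' @param wrap line width.
#' @return The path, invisibly.
#' @export
write_alignment <- function(msa, path, wrap = 60L) {
  stopifnot(inherits(msa, "aa_msa"))
  set <- Biostrings::BStringSet(msa$seq)
  names(set) <- ifelse(nzchar(msa$desc), paste(msa$id, msa$desc), msa$id)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(path)
}

# alignment rows as a character matrix (rows = members, cols = columns)
.msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seq, "", fixed = TRUE))
  rownames(m) <- msa$id
  m
}
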