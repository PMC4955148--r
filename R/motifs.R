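# motifs: substrate-discriminating motif matching and classification,
# residue-conservation reporting across an alignment, and promoter scanning
# for regulator binding sites (IUPAC DNA motifs, both strands).

# Motif pattern language: amino-acid letters match themselves, X matches any
# residue, and '/' joins adjacent letters into a single-position alternation
# (e.g. "GGLXXGYD/N": the eighth position is D or N).
.parse_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  tokens <- list()
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "/") {
      if (!length(tokens) || i == length(ch))
        stop("malformed alternation in motif pattern: ", pattern)
      tokens[[length(tokens)]] <- c(tokens[[length(tokens)]], ch[i + 1L])
      i <- i + 2L
    } else {
      tokens[[length(tokens) + 1L]] <- ch[i]
      i <- i + 1L
    }
  }
  ok <- vapply(tokens, function(t) all(t %in% c(AA_ALPHABET, "X")), TRUE)
  if (!all(ok)) stop("illegal letters in motif pattern: ", pattern)
  if (length(tokens) < 2L) stop("motif pattern must span at least 2 positions")
  tokens
}

.motif_regex <- function(tokens) {
  paste0(vapply(tokens, function(t) {
    if (identical(t, "X")) "."
    else if (length(t) == 1L) t
    else paste0("[", paste(t, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Find all occurrences of a motif in a protein sequence
#'
#' Occurrences may overlap; coordinates are 1-based inclusive on the
#' (de-gapped) sequence, ascending by start.
#'
#' @param seq residue string or single-row [aa_seqs].
#' @param pattern motif pattern: amino-acid letters, `X` for any residue,
#'   `/` for a single-position alternation (e.g. `"GGLXXGYD/N"`).
#' @return Data frame with columns `start`, `end`, `match`.
#' @export
find_motif <- function(seq, pattern) {
  s <- toupper(.as_single_seq(seq))
  tokens <- .parse_motif(pattern)
  len <- length(tokens)
  rx <- paste0("(?=(", .motif_regex(tokens), "))")
  m <- gregexpr(rx, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  data.frame(start = starts, end = starts + len - 1L,
             match = substring(s, starts, starts + len - 1L),
             stringsAsFactors = FALSE)
}

# the three substrate-class 8-mers and the generic first-TM-span motif
TRANSPORTER_CLASS_PATTERNS <- c(xylose    = "GGLXXGYD/N",
                                arabinose = "XGXXFGFD",
                                glucose   = "GGFXFGWG")

#' Classify a transporter first-transmembrane-span motif window
#'
#' Tests the three substrate-class 8-mer patterns (xylose `GGLXXGYD/N`,
#' arabinose `XGXXFGFD`, glucose `GGFXFGWG`) anchored at the window start;
#' if none matches, tests the generic `GG/FXXXG` motif (position 1 G,
#' position 2 G or F, position 6 G) and returns `"generic"` or `"none"`.
#'
#' @param window residue string of length at least 6.
#' @return One of `"xylose"`, `"arabinose"`, `"glucose"`, `"generic"`,
#'   `"none"`.
#' @export
classify_transporter_motif <- function(window) {
  stopifnot(is.character(window), length(window) == 1L)
  window <- toupper(window)
  if (nchar(window) < 6L)
    stop("motif window must be at least 6 residues, got ", nchar(window))
  for (cls in names(TRANSPORTER_CLASS_PATTERNS)) {
    tokens <- .parse_motif(TRANSPORTER_CLASS_PATTERNS[[cls]])
    if (nchar(window) < length(tokens)) next
    rx <- paste0("^", .motif_regex(tokens))
    if (grepl(rx, window, perl = TRUE)) return(cls)
  }
  if (grepl("^G[GF]...G", window, perl = TRUE)) return("generic")
  "none"
}

# fixed residue-class convention: methionine counts as aliphatic (its
# sulfur is unreactive); histidine is placed with the polar residues.
RESIDUE_CLASSES <- c(
  setNames(rep("aromatic", 3), c("F", "W", "Y")),
  setNames(rep("aliphatic", 6), c("A", "G", "I", "L", "V", "M")),
  setNames(rep("polar", 10), c("S", "T", "N", "Q", "C", "H", "D", "E",
                               "K", "R")),
  P = "other",  # proline: conformationally special, neither class
  X = "other")

#' Physicochemical class of an amino-acid letter
#'
#' Aromatic \{F, W, Y\}; aliphatic \{A, G, I, L, V, M\} (methionine by the
#' usual convention); polar \{S, T, N, Q, C, H, D, E, K, R\}; proline and
#' `X` are `"other"`.
#'
#' @param aa character vector of single amino-acid letters.
#' @return Character vector of classes.
#' @export
residue_class <- function(aa) {
  aa <- toupper(aa)
  bad <- setdiff(aa, names(RESIDUE_CLASSES))
  if (length(bad))
    stop("not an amino-acid letter: ", paste(unique(bad), collapse = ", "))
  unname(RESIDUE_CLASSES[aa])
}

# column index of the ref_pos-th residue of member `id` in the alignment
.residue_column <- function(msa, id, pos) {
  i <- match(id, msa$id)
  if (is.na(i)) stop("unknown sequence id: ", id)
  ch <- strsplit(msa$seq[i], "", fixed = TRUE)[[1L]]
  res <- which(ch != "-")
  if (pos < 1L || pos > length(res))
    stop("position ", pos, " out of range for sequence '", id,
         "' (", length(res), " residues)")
  res[pos]
}

#' Map a residue position between alignment members
#'
#' Locates the alignment column holding residue `ref_pos` of `ref_id` and
#' returns the 1-based residue index of `target_id` at that column, or `NA`
#' if the target has a gap there.
#'
#' @param msa an [aa_msa].
#' @param ref_id,target_id member ids.
#' @param ref_pos 1-based residue index on the de-gapped reference.
#' @return Integer target residue index, or `NA` for a gap.
#' @export
map_aligned_position <- function(msa, ref_id, ref_pos, target_id) {
  stopifnot(inherits(msa, "aa_msa"))
  col <- .residue_column(msa, ref_id, ref_pos)
  t <- match(target_id, msa$id)
  if (is.na(t)) stop("unknown sequence id: ", target_id)
  ch <- strsplit(msa$seq[t], "", fixed = TRUE)[[1L]]
  if (ch[col] == "-") return(NA_integer_)
  sum(ch[seq_len(col)] != "-")
}

#' Residue/motif conservation report across an alignment
#'
#' For each anchor (a reference residue or window given on a reference
#' member's de-gapped coordinates) and each alignment member, reports the
#' aligned text at the anchored columns, its per-position residue classes,
#' whether the reference residue(s) are conserved, and for windows of at
#' least 6 columns the substrate-class call of
#' [classify_transporter_motif()].
#'
#' @param msa an [aa_msa].
#' @param anchors data frame with columns `name`, `ref_id`, `start` and
#'   optionally `end` (defaults to `start`), positions 1-based on the
#'   de-gapped reference member.
#' @return Data frame with one row per anchor x member: `anchor`, `id`,
#'   `text` (gaps as `-`), `classes` (comma-separated), `conserved`
#'   (identical to the reference text), `class_call`.
#' @export
conservation_report <- function(msa, anchors) {
  stopifnot(inherits(msa, "aa_msa"), is.data.frame(anchors))
  if (nrow(anchors) == 0L)
    return(data.frame(anchor = character(), id = character(),
                      text = character(), classes = character(),
                      conserved = logical(), class_call = character(),
                      stringsAsFactors = FALSE))
  if (!all(c("name", "ref_id", "start") %in% names(anchors)))
    stop("anchors need columns name, ref_id, start")
  if (is.null(anchors$end)) anchors$end <- anchors$start
  anchors$end[is.na(anchors$end)] <- anchors$start[is.na(anchors$end)]
  mat <- .msa_matrix(msa)
  rows <- list()
  for (a in seq_len(nrow(anchors))) {
    an <- anchors[a, ]
    cols <- vapply(an$start:an$end,
                   function(p) .residue_column(msa, an$ref_id, p), 0L)
    ref_text <- paste(mat[an$ref_id, cols], collapse = "")
    for (i in seq_along(msa$id)) {
      txt <- paste(mat[i, cols], collapse = "")
      cl <- vapply(strsplit(txt, "")[[1L]], function(ch) {
        if (ch == "-") "gap" else residue_class(ch)
      }, "", USE.NAMES = FALSE)
      call <- if (length(cols) >= 6L && !grepl("-", txt, fixed = TRUE))
        classify_transporter_motif(txt) else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        anchor = an$name, id = msa$id[i], text = txt,
        classes = paste(cl, collapse = ","),
        conserved = identical(txt, ref_text), class_call = call,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Scan a promoter/upstream region for a DNA motif
#'
#' Scans the final `region` bases (or the whole sequence, if shorter) of an
#' upstream region on both strands for an IUPAC DNA motif. Reverse-strand
#' hits are reported with strand `-` at the forward (leftmost) coordinate
#' of the matched bases. Coordinates are 1-based on the given sequence.
#'
#' @param upstream DNA string over A/C/G/T/N (or a `DNAString`).
#' @param motif IUPAC DNA motif string (e.g. the XlnR-binding consensus
#'   `"GGCTAAA"`).
#' @param region number of 3'-terminal bases to scan (default 1000).
#' @param id optional gene id recorded in the output.
#' @return Data frame with columns `id`, `start`, `strand`, `match`.
#' @export
scan_promoter <- function(upstream, motif, region = 1000L, id = NA_character_) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("motif must be a non-empty IUPAC DNA string")
  subject <- Biostrings::DNAString(toupper(as.character(upstream)))
  L <- length(subject)
  offset <- max(0L, L - as.integer(region))
  win <- Biostrings::subseq(subject, start = offset + 1L, end = L)
  empty <- data.frame(id = character(), start = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE)
  if (length(win) < nchar(motif)) return(empty)
  pat <- Biostrings::DNAString(toupper(motif))
  fwd <- Biostrings::matchPattern(pat, win, fixed = FALSE)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), win,
                                  fixed = FALSE)
  mk <- function(m, strand) {
    if (length(m) == 0L) return(empty)
    data.frame(id = id, start = Biostrings::start(m) + offset,
               strand = strand, match = as.character(m),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(fwd, "+"), mk(rev, "-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan several upstream regions for a DNA motif
#'
#' @param regions named character vector or list of DNA strings (names are
#'   gene ids), e.g. from a DNA FASTA read with
#'   `Biostrings::readDNAStringSet()`.
#' @inheritParams scan_promoter
#' @return Row-bound data frame of [scan_promoter()] results.
#' @export
scan_promoters <- function(regions, motif, region = 1000L) {
  regions <- as.list(regions)
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("upstream regions must be named by gene id")
  out <- lapply(names(regions), function(g)
    scan_promoter(as.character(regions[[g]]), motif, region, id = g))
  do.call(rbind, out)
}
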