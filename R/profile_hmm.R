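# profile_hmm: build a profile hidden Markov model from a curated alignment
# and score/rank proteome sequences by Forward/Viterbi log-odds (bits).

#' Profile-HMM build configuration
#'
#' @param match_gap_threshold a column becomes a match column iff its gap
#'   fraction is at most this value (default 0.5).
#' @param pseudocount_alpha Laplace-style pseudocount weight, > 0 (default
#'   0.5). Emission pseudocount for residue a is `alpha * 20 * q_a`
#'   (i.e. add-alpha under a uniform background); transition pseudocount is
#'   `alpha` per allowed transition.
#' @param weighting `"position"` for Henikoff position-based sequence
#'   weights, `"uniform"` for equal weights.
#' @param mode `"local"` (uniform entry/exit over match states, the default,
#'   appropriate for mining whole proteomes) or `"glocal"` (the model must
#'   align end to end).
#' @param background `"uniform"` (1/20 per residue, default), `"alignment"`
#'   (estimated from the training alignment), or a 20-vector of residue
#'   frequencies in the order `A C D E F G H I K L M N P Q R S T V W Y`.
#' @return A list of class `hmm_config`.
#' @export
hmm_config <- function(match_gap_threshold = 0.5, pseudocount_alpha = 0.5,
                       weighting = c("position", "uniform"),
                       mode = c("local", "glocal"),
                       background = "uniform") {
  stopifnot(match_gap_threshold >= 0, match_gap_threshold <= 1,
            pseudocount_alpha > 0)
  structure(list(match_gap_threshold = match_gap_threshold,
                 pseudocount_alpha = pseudocount_alpha,
                 weighting = match.arg(weighting),
                 mode = match.arg(mode),
                 background = background),
            class = "hmm_config")
}

#' Label alignment columns as match or insert
#'
#' A column is a match column iff its fraction of gap characters is at most
#' `threshold`; the number of match columns is the model length M.
#'
#' @param msa an [aa_msa].
#' @param threshold gap-fraction threshold in \[0, 1\].
#' @return Character vector of length `msa$width`, `"match"` or `"insert"`.
#' @export
assign_match_columns <- function(msa, threshold = 0.5) {
  stopifnot(inherits(msa, "aa_msa"), threshold >= 0, threshold <= 1)
  m <- .msa_matrix(msa)
  gapfrac <- colMeans(m == "-")
  ifelse(gapfrac <= threshold, "match", "insert")
}

#' Henikoff position-based sequence weights
#'
#' Per column, each distinct residue type shares one unit of weight equally
#' among the sequences carrying it (gaps carry none); per-sequence weights
#' are averaged over columns and normalized to sum to 1. Redundant
#' near-duplicate members are down-weighted relative to divergent ones.
#'
#' @param msa an [aa_msa].
#' @return Named numeric vector of weights summing to 1.
#' @export
sequence_weights <- function(msa) {
  stopifnot(inherits(msa, "aa_msa"))
  m <- .msa_matrix(msa)
  n <- nrow(m)
  w <- numeric(n)
  for (k in seq_len(ncol(m))) {
    col <- m[, k]
    res <- col != "-"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    w[res] <- w[res] + 1 / (r * as.numeric(tab[col[res]]))
  }
  w <- w / ncol(m)
  if (sum(w) == 0) w <- rep(1, n)  # degenerate all-gap alignment
  w <- w / sum(w)
  names(w) <- msa$id
  w
}

.resolve_background <- function(background, msa) {
  if (is.numeric(background)) {
    stopifnot(length(background) == 20, all(background > 0))
    q <- background / sum(background)
  } else if (identical(background, "uniform")) {
    q <- rep(1 / 20, 20)
  } else if (identical(background, "alignment")) {
    ch <- unlist(strsplit(msa$seq, "", fixed = TRUE))
    ch <- ch[ch %in% AA_ALPHABET]
    cnt <- table(factor(ch, levels = AA_ALPHABET)) + 1  # add-one smoothing
    q <- as.numeric(cnt) / sum(cnt)
  } else stop("unknown background specification")
  names(q) <- AA_ALPHABET
  q
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Match-state emissions are weighted residue counts plus background-
#' proportional pseudocounts, normalized per match column; insert emissions
#' default to the background distribution; transition probabilities come
#' from weighted observed state-path counts with pseudocounts. The model
#' uses the full profile architecture (match/insert/delete states per node,
#' all nine transition types), so every observed path is representable.
#'
#' @param msa an [aa_msa] training alignment.
#' @param config an [hmm_config] (defaults used when omitted).
#' @return An object of class `profile_hmm` with fields `M`,
#'   `match_emissions` (M x 20), `insert_emissions` ((M+1) x 20), `trans`
#'   (list of transition-probability vectors indexed by source node 0..M),
#'   `background`, `alphabet`, `config`, and `match_columns`.
#' @export
build_profile <- function(msa, config = hmm_config()) {
  stopifnot(inherits(msa, "aa_msa"), inherits(config, "hmm_config"))
  mat <- .msa_matrix(msa)
  n <- nrow(mat)
  labels <- assign_match_columns(msa, config$match_gap_threshold)
  M <- sum(labels == "match")
  if (M < 1L)
    stop("model degenerate: alignment has no match columns at gap threshold ",
         config$match_gap_threshold)
  q <- .resolve_background(config$background, msa)
  alpha <- config$pseudocount_alpha

  w <- if (config$weighting == "position") sequence_weights(msa)
       else setNames(rep(1 / n, n), msa$id)
  w <- w * n  # scale so that uniform weighting counts each sequence once

  # --- emissions ------------------------------------------------------------
  match_cols <- which(labels == "match")
  ecount <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(M)) {
    col <- mat[, match_cols[j]]
    keep <- col %in% AA_ALPHABET  # gaps and X carry no emission count
    if (any(keep))
      ecount[j, ] <- vapply(AA_ALPHABET,
                            function(a) sum(w[keep][col[keep] == a]), 0)
  }
  pseudo <- alpha * 20 * q
  me <- sweep(ecount, 2, pseudo, "+")
  me <- me / rowSums(me)
  ie <- matrix(rep(q, each = M + 1), nrow = M + 1,
               dimnames = list(NULL, AA_ALPHABET))

  # --- transitions ----------------------------------------------------------
  # counts indexed by source node j (0..M); node 0 holds begin + I_0
  types <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DD", "DI")
  cnt <- setNames(lapply(types, function(t) numeric(M + 1)), types)
  node_of_col <- cumsum(labels == "match")  # node index after each column
  for (i in seq_len(n)) {
    prev <- "M"; pnode <- 0L
    for (k in seq_len(ncol(mat))) {
      ch <- mat[i, k]
      if (labels[k] == "match") {
        cur <- if (ch == "-") "D" else "M"
        cnode <- node_of_col[k]
      } else {
        if (ch == "-") next
        cur <- "I"; cnode <- node_of_col[k]
      }
      t <- paste0(prev, cur)
      cnt[[t]][pnode + 1L] <- cnt[[t]][pnode + 1L] + w[i]
      prev <- cur; pnode <- cnode
    }
    t <- paste0(prev, "M")  # transition to end state E
    cnt[[t]][pnode + 1L] <- cnt[[t]][pnode + 1L] + w[i]
  }
  trans <- .normalize_transitions(cnt, M, alpha)

  structure(list(M = M, match_emissions = me, insert_emissions = ie,
                 trans = trans, background = q, alphabet = AA_ALPHABET,
                 config = config, match_columns = match_cols),
            class = "profile_hmm")
}

# normalize transition counts + pseudocounts into per-source distributions.
# Allowed targets: nodes 0..M-1: M->{M,I,D}, I->{M,I,D}, D->{M,D,I} (D only
# for j>=1); node M: {E(M), I} from each source.
.normalize_transitions <- function(cnt, M, alpha) {
  out <- lapply(cnt, function(x) numeric(M + 1))
  for (j in 0:M) {
    k <- j + 1L
    has_d <- j < M          # a D_{j+1} target exists
    for (src in c("M", "I", "D")) {
      if (src == "D" && j == 0L) next  # D_0 does not exist
      tm <- cnt[[paste0(src, "M")]][k] + alpha
      ti <- cnt[[paste0(src, "I")]][k] + alpha
      td <- if (has_d) cnt[[paste0(src, "D")]][k] + alpha else 0
      tot <- tm + ti + td
      out[[paste0(src, "M")]][k] <- tm / tot
      out[[paste0(src, "I")]][k] <- ti / tot
      if (has_d) out[[paste0(src, "D")]][k] <- td / tot
    }
  }
  out
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm: M =", x$M, "match states; mode =", x$config$mode,
      "; alpha =", x$config$pseudocount_alpha, "\n")
  invisible(x)
}

.encode_seq <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  code <- match(ch, AA_ALPHABET) - 1L
  code[ch == "X"] <- 20L
  if (anyNA(code))
    stop("illegal residue character '", ch[which(is.na(code))[1L]],
         "' at position ", which(is.na(code))[1L])
  code
}

.log_odds_tables <- function(model) {
  lq <- log(model$background)
  list(le_m = sweep(log(model$match_emissions), 2, lq, "-"),
       le_i = sweep(log(model$insert_emissions), 2, lq, "-"),
       lt = lapply(model$trans, log))
}

.dp_args <- function(model, seq) {
  tab <- .log_odds_tables(model)
  s <- if (is.character(seq)) seq else seq$seq
  list(tab$le_m, tab$le_i,
       tab$lt$MM, tab$lt$MI, tab$lt$MD,
       tab$lt$IM, tab$lt$II, tab$lt$ID,
       tab$lt$DM, tab$lt$DD, tab$lt$DI,
       .encode_seq(s), if (model$config$mode == "local") 1L else 0L)
}

.as_single_seq <- function(seq) {
  if (inherits(seq, "aa_seqs")) {
    stopifnot(nrow(seq) == 1L)
    return(seq$seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("cannot score an empty sequence")
  seq
}

#' Forward log-odds score of a sequence against a profile HMM
#'
#' Computes `log2 P(seq | model) / P(seq | null)` by the Forward algorithm
#' in log space. The null model emits each residue i.i.d. from the model
#' background. In local mode entry/exit is uniform over match-state pairs
#' and flanking residues are emitted at background.
#'
#' @param model a [build_profile()] model.
#' @param seq a residue string or single-row [aa_seqs].
#' @return Log-odds score in bits (finite for any non-empty sequence).
#' @export
forward_score <- function(model, seq) {
  stopifnot(inherits(model, "profile_hmm"))
  s <- .as_single_seq(seq)
  do.call(hmm_forward_cpp, .dp_args(model, s)) / log(2)
}

#' Viterbi (best-path) log-odds score and state path
#'
#' @inheritParams forward_score
#' @return List with `bits` (max-over-paths log-odds) and `path` (character
#'   vector of visited states, e.g. `"M1"`, `"I2"`, `"D3"`). Score ties are
#'   broken preferring match over delete over insert.
#' @export
viterbi_score <- function(model, seq) {
  stopifnot(inherits(model, "profile_hmm"))
  s <- .as_single_seq(seq)
  res <- do.call(hmm_viterbi_cpp, .dp_args(model, s))
  list(bits = res$logodds / log(2), path = as.character(res$path))
}

#' Score and rank a proteome against a profile HMM
#'
#' Every sequence is scored with [forward_score()]; records are sorted by
#' descending score with ties broken by ascending id, and the `top_n`
#' highest-scoring records are returned.
#'
#' @param model a [build_profile()] model.
#' @param proteome an [aa_seqs] collection.
#' @param top_n number of records to keep (default 15; all if fewer).
#' @return Data frame with columns `rank`, `id`, `bits`.
#' @export
scan_proteome <- function(model, proteome, top_n = 15L) {
  stopifnot(inherits(model, "profile_hmm"), inherits(proteome, "aa_seqs"),
            top_n >= 1L)
  if (nrow(proteome) == 0L)
    return(data.frame(rank = integer(), id = character(), bits = numeric()))
  bits <- vapply(proteome$seq, function(s) forward_score(model, s), 0,
                 USE.NAMES = FALSE)
  ord <- order(-bits, proteome$id)
  out <- data.frame(rank = seq_along(ord), id = proteome$id[ord],
                    bits = bits[ord], stringsAsFactors = FALSE)
  head(out, n = top_n)
}

#' Serialize a profile HMM to a versioned JSON file
#'
#' @param model a `profile_hmm`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_profile <- function(model, path) {
  stopifnot(inherits(model, "profile_hmm"))
  obj <- list(format = "spminer-profile", version = 1L, M = model$M,
              alphabet = model$alphabet,
              config = unclass(model$config),
              background = unname(model$background),
              match_emissions = unname(model$match_emissions),
              insert_emissions = unname(model$insert_emissions),
              transitions = model$trans,
              match_columns = model$match_columns)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a profile HMM written by [write_profile()]
#'
#' @param path path to a serialized profile.
#' @return A `profile_hmm` object.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "spminer-profile"))
    stop("not an spminer profile file: ", path)
  cfg <- do.call(hmm_config, obj$config[c("match_gap_threshold",
                                          "pseudocount_alpha", "weighting",
                                          "mode", "background")])
  me <- matrix(obj$match_emissions, ncol = 20,
               dimnames = list(NULL, AA_ALPHABET))
  ie <- matrix(obj$insert_emissions, ncol = 20,
               dimnames = list(NULL, AA_ALPHABET))
  structure(list(M = obj$M, match_emissions = me, insert_emissions = ie,
                 trans = lapply(obj$transitions, as.numeric),
                 background = setNames(as.numeric(obj$background),
                                       AA_ALPHABET),
                 alphabet = AA_ALPHABET, config = cfg,
                 match_columns = as.integer(obj$match_columns)),
            class = "profile_hmm")
}
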