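# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation: path probabilities are enumerated in
# linear space, Michaelis-Menten fits are checked by grid search, motif hits
# by a naive sliding window.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- brute-force profile-HMM path enumeration -------------------------------

# odds contribution of emitting residue code x (1-based, 21 = X) from a
# 20-probability row against background q
.oracle_emit <- function(row, q, x) if (x > 20) 1 else unname(row[x] / q[x])

# Enumerate all state paths of `model` for integer-coded `seq` and return
# list(total = sum of path odds, best = max path odds). Glocal: paths run
# begin -> ... -> end over the full sequence. Local: uniform entry/exit over
# ordered match-state pairs with probability 2/(M(M+1)); flanking residues
# contribute odds 1.
oracle_path_odds <- function(model, seq_codes) {
  M <- model$M
  q <- model$background
  me <- model$match_emissions
  ie <- model$insert_emissions
  tr <- model$trans
  L <- length(seq_codes)
  local <- model$config$mode == "local"
  total <- 0
  best <- -Inf

  # st in c("M","I","D"); j = node; i = residues consumed; odds accumulated
  recurse_glocal <- function(st, j, i, odds) {
    k <- j + 1L
    # to end state (target "M" at node M)
    tM <- tr[[paste0(st, "M")]][k]
    if (j == M) {
      if (i == L && tM > 0) {
        o <- odds * tM
        total <<- total + o
        best <<- max(best, o)
      }
    } else if (tM > 0 && i < L) {
      x <- seq_codes[i + 1L]
      recurse_glocal("M", j + 1L, i + 1L,
                     odds * tM * .oracle_emit(me[j + 1L, ], q, x))
    }
    tI <- tr[[paste0(st, "I")]][k]
    if (tI > 0 && i < L) {
      x <- seq_codes[i + 1L]
      recurse_glocal("I", j, i + 1L,
                     odds * tI * .oracle_emit(ie[k, ], q, x))
    }
    if (j < M) {
      tD <- tr[[paste0(st, "D")]][k]
      if (tD > 0) recurse_glocal("D", j + 1L, i, odds * tD)
    }
  }

  recurse_local <- function(st, j, i, odds) {
    if (st == "M") {  # exit option: remaining residues are flank
      total <<- total + odds
      best <<- max(best, odds)
    }
    k <- j + 1L
    if (j < M) {
      tM <- tr[[paste0(st, "M")]][k]
      if (tM > 0 && i < L) {
        x <- seq_codes[i + 1L]
        recurse_local("M", j + 1L, i + 1L,
                      odds * tM * .oracle_emit(me[j + 1L, ], q, x))
      }
      tD <- tr[[paste0(st, "D")]][k]
      if (tD > 0) recurse_local("D", j + 1L, i, odds * tD)
    }
    tI <- tr[[paste0(st, "I")]][k]
    if (tI > 0 && i < L)
      recurse_local("I", j, i + 1L,
                    odds * tI * .oracle_emit(ie[k, ], q, seq_codes[i + 1L]))
  }

  if (!local) {
    recurse_glocal("M", 0L, 0L, 1)
  } else {
    entry <- 2 / (M * (M + 1))
    for (j1 in seq_len(M)) for (i1 in seq_len(L)) {
      x <- seq_codes[i1]
      recurse_local("M", j1, i1, entry * .oracle_emit(me[j1, ], q, x))
    }
  }
  list(total = total, best = best)
}

oracle_encode <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  ifelse(ch == "X", 21L, match(ch, spminer:::AA_ALPHABET))
}

# random toy model with the package's architecture, built directly (not via
# build_profile) so model construction and scoring are tested independently
random_toy_model <- function(M, mode = "local", seed = 1L) {
  withr::with_seed(seed, {
    rdir <- function(n) { x <- stats::rexp(n) + 0.05; x / sum(x) }
    me <- t(vapply(seq_len(M), function(j) rdir(20), numeric(20)))
    ie <- t(vapply(seq_len(M + 1), function(j) rdir(20), numeric(20)))
    colnames(me) <- colnames(ie) <- spminer:::AA_ALPHABET
    types <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DD", "DI")
    tr <- setNames(lapply(types, function(t) numeric(M + 1)), types)
    for (j in 0:M) {
      k <- j + 1L
      for (src in c("M", "I", "D")) {
        if (src == "D" && j == 0L) next
        if (j < M) {
          p <- rdir(3)
          tr[[paste0(src, "M")]][k] <- p[1]
          tr[[paste0(src, "I")]][k] <- p[2]
          tr[[paste0(src, "D")]][k] <- p[3]
        } else {
          p <- rdir(2)
          tr[[paste0(src, "M")]][k] <- p[1]
          tr[[paste0(src, "I")]][k] <- p[2]
        }
      }
    }
    structure(list(M = M, match_emissions = me, insert_emissions = ie,
                   trans = tr,
                   background = setNames(rep(1 / 20, 20),
                                         spminer:::AA_ALPHABET),
                   alphabet = spminer:::AA_ALPHABET,
                   config = hmm_config(mode = mode),
                   match_columns = seq_len(M)),
              class = "profile_hmm")
  })
}

random_aa_string <- function(len, seed) {
  withr::with_seed(seed,
    paste(sample(spminer:::AA_ALPHABET, len, replace = TRUE),
          collapse = ""))
}

# ---- Michaelis-Menten grid-search oracle ------------------------------------

# coarse log-spaced grid over (Vmax, Km) with iterative zoom; independent of
# the nonlinear least-squares route
oracle_mm_grid <- function(obs, n = 100, rounds = 4) {
  rss <- function(vmax, km)
    sum((obs$rate - vmax * obs$substrate_mM / (km + obs$substrate_mM))^2)
  vr <- c(max(obs$rate) / 4, max(obs$rate) * 4)
  kr <- range(obs$substrate_mM) * c(0.02, 50)
  best <- c(NA, NA, Inf)
  for (r in seq_len(rounds)) {
    vg <- exp(seq(log(vr[1]), log(vr[2]), length.out = n))
    kg <- exp(seq(log(kr[1]), log(kr[2]), length.out = n))
    m <- outer(vg, kg, Vectorize(rss))
    ij <- which(m == min(m), arr.ind = TRUE)[1, ]
    best <- c(vg[ij[1]], kg[ij[2]], m[ij[1], ij[2]])
    shrink <- function(g, i) {
      lo <- g[max(1, i - 2)]; hi <- g[min(length(g), i + 2)]
      c(lo, hi)
    }
    vr <- shrink(vg, ij[1]); kr <- shrink(kg, ij[2])
  }
  list(Vmax = best[1], Km = best[2], rss = best[3])
}

# ---- naive motif recount ----------------------------------------------------

# sliding-window motif matcher over parsed token sets
oracle_motif_starts <- function(s, pattern) {
  tokens <- spminer:::.parse_motif(pattern)
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  L <- length(ch); k <- length(tokens)
  starts <- integer()
  if (L >= k) for (i in seq_len(L - k + 1L)) {
    ok <- TRUE
    for (p in seq_len(k)) {
      t <- tokens[[p]]
      if (!identical(t, "X") && !(ch[i + p - 1L] %in% t)) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
  }
  starts
}

# ---- random additive trees --------------------------------------------------

# random unrooted topology with positive branch lengths; returns the tree and
# its exact path-length (additive) distance matrix, label-sorted
random_additive_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
    tr <- ape::unroot(tr)
    D <- ape::cophenetic.phylo(tr)
    D <- D[order(rownames(D)), order(colnames(D))]
    list(tree = tr, D = D)
  })
}

# bipartition set of a tree as canonical strings (side not containing the
# alphabetically smallest tip)
oracle_bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  sp <- phangorn::as.splits(tree)
  out <- character()
  for (s in sp) {
    side <- attr(sp, "labels")[s]
    if (labs[1] %in% side) side <- setdiff(attr(sp, "labels"), side)
    if (length(side) >= 2 && length(side) <= length(labs) - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  sort(unique(out))
}

# small deterministic fixture alignment used across files
fixture_msa <- function() {
  aa_msa(c("t1", "t2", "t3", "t4"),
         c("GGLMFGYDACDEFYFFYYK-",
           "GGLQFGYNACDEFYFFYYKL",
           "AGCDFGFDACD-FYFFYYKL",
           "GGFAFGWGACDEFYFFYYKL"))
}
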