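# phylo: pairwise distances, neighbor joining, bootstrap support and
# low-support collapsing. Trees are ape "phylo" objects throughout; Newick
# I/O goes through ape.

#' Pairwise distances from a protein alignment
#'
#' p-distance with pairwise deletion: for each pair of rows, the fraction of
#' mismatching residues among columns where neither member has a gap. The
#' Poisson correction `-log(1 - p)` is available for multiple substitutions.
#'
#' @param msa an [aa_msa] with at least 2 members.
#' @param model `"p"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, labeled by sequence
#'   id.
#' @export
pairwise_distances <- function(msa, model = c("p", "poisson")) {
  stopifnot(inherits(msa, "aa_msa"))
  model <- match.arg(model)
  if (length(msa$id) < 2L) stop("need at least 2 sequences for distances")
  m <- .msa_matrix(msa)
  n <- nrow(m)
  res <- m != "-"
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- res[i, ] & res[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop("no comparable columns between '", msa$id[i], "' and '",
           msa$id[j], "'")
    p <- sum(m[i, comp] != m[j, comp]) / nc
    if (model == "poisson") {
      if (p >= 1) stop("Poisson correction undefined at p = 1 for pair '",
                       msa$id[i], "', '", msa$id[j], "'")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

.validate_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || is.null(rownames(d)))
    stop("distance matrix must be a square labeled matrix")
  if (!all(is.finite(d))) stop("distance matrix has non-finite entries")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distance matrix has negative entries")
  invisible(TRUE)
}

.fmt_len <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively join the pair minimizing the
#' Q-criterion, with branch lengths from the standard NJ formulas. On
#' additive input the generating tree is recovered exactly. Q ties are
#' broken by the lexicographically smallest pair of subtree labels (a
#' subtree is labeled by its smallest leaf id). Negative branch-length
#' estimates are clamped to 0 with the deficit moved to the sister branch.
#'
#' @param d symmetric labeled distance matrix (see [pairwise_distances()]).
#' @return An unrooted `phylo` tree (for 2 taxa, a single edge split at its
#'   midpoint).
#' @export
neighbor_joining <- function(d) {
  .validate_dist(d)
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    h <- .fmt_len(d[1, 2] / 2)
    return(ape::read.tree(text = paste0("(", labs[1], ":", h, ",",
                                        labs[2], ":", h, ");")))
  }
  frag <- labs                 # newick fragment per active node
  minlab <- labs               # smallest leaf label per active node
  dd <- d
  while (nrow(dd) > 3L) {
    m <- nrow(dd)
    r <- rowSums(dd)
    q <- (m - 2) * dd - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pl <- apply(cand, 1, function(ij) {
      p <- sort(c(minlab[ij[1]], minlab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pl)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- dd[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dd[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", .fmt_len(li), ",",
                      frag[j], ":", .fmt_len(lj), ")")
    newlab <- min(minlab[i], minlab[j])
    du <- (dd[i, ] + dd[j, ] - dd[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dd2 <- rbind(cbind(dd[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    frag <- c(frag[keep], newfrag)
    minlab <- c(minlab[keep], newlab)
    rownames(dd2) <- colnames(dd2) <- seq_len(m - 1L)
    dd <- dd2
  }
  # final trifurcation
  l1 <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  l2 <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  l3 <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  txt <- paste0("(", frag[1], ":", .fmt_len(l1), ",",
                frag[2], ":", .fmt_len(l2), ",",
                frag[3], ":", .fmt_len(l3), ");")
  ape::read.tree(text = txt)
}

# canonical bipartition keys for the internal edges of a phylo tree.
# Returns a character vector indexed by internal node number (as character);
# the root has no entry. The canonical side of a split is the side NOT
# containing the alphabetically smallest tip label.
.bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  ref <- min(labels)
  root <- ntip + 1L
  keys <- character(0)
  for (k in seq_along(pp)) {
    node <- ntip + k
    if (node == root) next
    side <- labels[pp[[k]]]
    if (ref %in% side) side <- setdiff(labels, side)
    keys[as.character(node)] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement per replicate; the
#' distance matrix and NJ tree are rebuilt, and the support of each internal
#' edge of the full-alignment tree is the percentage of replicate trees that
#' contain the same leaf bipartition. Deterministic for a fixed seed.
#'
#' @param msa an [aa_msa].
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed integer RNG seed (required for reproducibility).
#' @param model distance model passed to [pairwise_distances()].
#' @return A `phylo` tree whose `node.label` holds supports rounded to the
#'   nearest integer percent; exact supports are kept in the
#'   `node.support` element (NA for the root).
#' @export
bootstrap_support <- function(msa, replicates = 100L, seed,
                              model = c("p", "poisson")) {
  stopifnot(inherits(msa, "aa_msa"), replicates >= 1L)
  if (missing(seed)) stop("bootstrap_support requires an explicit seed")
  model <- match.arg(model)
  tree <- neighbor_joining(pairwise_distances(msa, model))
  keys <- .bipartitions(tree)
  counts <- setNames(numeric(length(keys)), unname(keys))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(replicates)) {
      cols <- sample.int(msa$width, msa$width, replace = TRUE)
      mat <- .msa_matrix(msa)[, cols, drop = FALSE]
      bmsa <- aa_msa(msa$id, apply(mat, 1, paste, collapse = ""))
      btree <- neighbor_joining(pairwise_distances(bmsa, model))
      bkeys <- unique(unname(.bipartitions(btree)))
      hit <- names(counts) %in% bkeys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / replicates
  ntip <- length(tree$tip.label)
  node.support <- rep(NA_real_, tree$Nnode)
  lab <- rep("", tree$Nnode)
  for (nd in names(keys)) {
    idx <- as.integer(nd) - ntip
    node.support[idx] <- support[[keys[[nd]]]]
    lab[idx] <- as.character(round(support[[keys[[nd]]]]))
  }
  tree$node.label <- lab
  tree$node.support <- node.support
  tree
}

#' Collapse poorly supported internal edges into polytomies
#'
#' Every internal edge whose bootstrap support is strictly below `threshold`
#' is contracted (its child's subtrees are attached to the parent); edges
#' with support at or above the threshold are kept. Idempotent.
#'
#' @param tree a `phylo` with supports (from [bootstrap_support()], or
#'   numeric `node.label`).
#' @param threshold percent support below which an edge is collapsed
#'   (default 75; strict `<`).
#' @return The collapsed `phylo` tree.
#' @export
collapse_low_support <- function(tree, threshold = 75) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  support <- tree$node.support
  if (is.null(support)) {
    support <- suppressWarnings(as.numeric(tree$node.label))
  }
  if (is.null(support)) stop("tree carries no support values")
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- tree$edge.length
  edge_of <- setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])
  lab_of <- function(node) {
    idx <- node - ntip
    s <- support[idx]
    if (is.na(s)) "" else as.character(round(s))
  }
  # returns one or more "fragment:length" strings as seen by the parent
  emit <- function(node) {
    if (node <= ntip)
      return(paste0(tree$tip.label[node],
                    ":", .fmt_len(elen[edge_of[[as.character(node)]]])))
    kids <- unlist(lapply(children[[as.character(node)]], emit))
    s <- support[node - ntip]
    len <- elen[edge_of[[as.character(node)]]]
    if (!is.na(s) && s < threshold)
      return(kids)  # contract: hoist children, drop this edge
    paste0("(", paste(kids, collapse = ","), ")", lab_of(node),
           ":", .fmt_len(len))
  }
  kids <- unlist(lapply(children[[as.character(root)]], emit))
  out <- ape::read.tree(text = paste0("(", paste(kids, collapse = ","),
                                      ");"))
  ns <- suppressWarnings(as.numeric(out$node.label))
  out$node.support <- ns
  out
}

#' Write a tree to a Newick file
#'
#' Supports are written as internal-node labels; branch lengths with 6
#' significant digits.
#'
#' @param tree a `phylo`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
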