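# synth: seeded generators for synthetic protein families, planted-homolog
# proteomes, uptake-assay data and growth curves. Every generator is a pure
# function of its parameters plus an explicit seed.

#' Specification of a synthetic protein family
#'
#' @param length ancestor sequence length.
#' @param n_members number of family members.
#' @param sub_prob per-site substitution probability in each member.
#' @param del_prob per-site deletion probability (gap in the member; the
#'   true alignment stays in ancestor coordinates, so insertions are not
#'   simulated).
#' @param motifs optional list of `list(pattern = <residue string>,
#'   position = <1-based start>)` planted verbatim in the ancestor and
#'   protected from mutation in every member.
#' @param seed integer RNG seed.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(length = 200L, n_members = 24L, sub_prob = 0.1,
                        del_prob = 0.02, motifs = list(), seed = 1L) {
  stopifnot(length >= 1L, n_members >= 1L,
            sub_prob >= 0, sub_prob <= 1, del_prob >= 0, del_prob <= 1)
  for (m in motifs) {
    stopifnot(is.character(m$pattern), m$position >= 1L)
    if (m$position + nchar(m$pattern) - 1L > length)
      stop("planted motif '", m$pattern, "' at position ", m$position,
           " exceeds sequence length ", length)
  }
  structure(list(length = as.integer(length),
                 n_members = as.integer(n_members),
                 sub_prob = sub_prob, del_prob = del_prob,
                 motifs = motifs, seed = as.integer(seed)),
            class = "family_spec")
}

#' Simulate a protein family with a known true alignment
#'
#' An ancestor sequence is drawn uniformly over the 20 amino acids, planted
#' motifs are written in verbatim, and each member is derived independently
#' by per-site substitution and deletion (motif sites are protected). The
#' true alignment is in ancestor coordinates. Deterministic per seed.
#'
#' @param spec a [family_spec()].
#' @return List with `alignment` (an [aa_msa]), `sequences` (de-gapped
#'   [aa_seqs]) and `ancestor` (residue string).
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, {
    anc <- sample(AA_ALPHABET, spec$length, replace = TRUE)
    protected <- logical(spec$length)
    for (m in spec$motifs) {
      idx <- m$position:(m$position + nchar(m$pattern) - 1L)
      anc[idx] <- strsplit(toupper(m$pattern), "")[[1L]]
      protected[idx] <- TRUE
    }
    rows <- vapply(seq_len(spec$n_members), function(i) {
      s <- anc
      mut <- runif(spec$length) < spec$sub_prob & !protected
      if (any(mut))
        s[mut] <- vapply(s[mut], function(a)
          sample(setdiff(AA_ALPHABET, a), 1L), "")
      del <- runif(spec$length) < spec$del_prob & !protected
      s[del] <- "-"
      paste(s, collapse = "")
    }, "")
    ids <- sprintf("fam%02d", seq_len(spec$n_members))
    msa <- aa_msa(ids, rows)
    list(alignment = msa, sequences = degap(msa),
         ancestor = paste(anc, collapse = ""))
  })
}

#' Plant one family member in a decoy proteome
#'
#' Generates i.i.d. decoy sequences (uniform over the 20 residues by
#' default, or from a supplied background frequency vector) and mixes in one
#' held-out member of the family (the last alignment row, de-gapped). Order
#' is shuffled; deterministic per seed.
#'
#' @param family an [aa_msa] family alignment (e.g. from
#'   [simulate_family()]).
#' @param decoys number of decoy sequences (>= 0).
#' @param decoy_length_range integer range `c(min, max)` of decoy lengths.
#' @param seed integer RNG seed.
#' @param background optional 20-vector of residue frequencies for decoys.
#' @return An [aa_seqs] proteome; the planted sequence id is in
#'   `attr(, "planted_id")`.
#' @export
plant_homolog_proteome <- function(family, decoys = 100L,
                                   decoy_length_range = c(150L, 400L),
                                   seed = 1L, background = NULL) {
  stopifnot(inherits(family, "aa_msa"), decoys >= 0L,
            length(decoy_length_range) == 2L,
            decoy_length_range[1] >= 1L,
            decoy_length_range[1] <= decoy_length_range[2])
  prob <- if (is.null(background)) rep(1 / 20, 20) else {
    stopifnot(length(background) == 20, all(background >= 0))
    background / sum(background)
  }
  withr::with_seed(as.integer(seed), {
    planted_id <- family$id[length(family$id)]
    planted <- gsub("-", "", family$seq[length(family$id)], fixed = TRUE)
    lens <- if (decoys > 0L)
      sample(decoy_length_range[1]:decoy_length_range[2], decoys,
             replace = TRUE) else integer()
    dseq <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = prob),
            collapse = ""), "")
    ids <- c(sprintf("decoy%03d", seq_len(decoys)), planted_id)
    seqs <- c(dseq, planted)
    ord <- sample.int(length(ids))
    out <- aa_seqs(ids[ord], seqs[ord])
    attr(out, "planted_id") <- planted_id
    out
  })
}

#' Simulate Michaelis-Menten uptake observations
#'
#' Rates are drawn as `Vmax*S/(Km+S) * (1 + Normal(0, noise_sd_fraction))`,
#' truncated at 0. Deterministic per seed.
#'
#' @param Vmax maximal rate, nmol min^-1 mgDW^-1 (> 0).
#' @param Km half-saturation concentration, mM (> 0).
#' @param concentrations substrate concentrations, mM.
#' @param noise_sd_fraction multiplicative noise SD (0 = exact model
#'   values).
#' @param replicates replicate measurements per concentration.
#' @param seed integer RNG seed.
#' @return Data frame with columns `substrate_mM`, `rate`, `replicate`.
#' @export
simulate_uptake_data <- function(Vmax, Km, concentrations,
                                 noise_sd_fraction = 0, replicates = 1L,
                                 seed = 1L) {
  stopifnot(Vmax > 0, Km > 0, all(concentrations > 0),
            noise_sd_fraction >= 0, replicates >= 1L)
  s <- rep(concentrations, each = replicates)
  v <- Vmax * s / (Km + s)
  withr::with_seed(as.integer(seed), {
    if (noise_sd_fraction > 0)
      v <- pmax(0, v * (1 + rnorm(length(v), 0, noise_sd_fraction)))
  })
  data.frame(substrate_mM = s, rate = v,
             replicate = rep(seq_len(replicates), times =
                               length(concentrations)))
}

#' Simulate an OD growth curve
#'
#' Exponential growth `OD(t) = od0 e^{mu t}` saturating at a carrying-
#' capacity plateau (`OD = min(od0 e^{mu t}, capacity)`; default `Inf`,
#' pure exponential), with optional multiplicative noise. Deterministic per
#' seed.
#'
#' @param od0 initial OD (> 0).
#' @param mu specific growth rate, h^-1.
#' @param t_end final time, h.
#' @param step sampling interval, h (> 0).
#' @param noise_sd multiplicative noise SD on OD (0 = exact).
#' @param seed integer RNG seed.
#' @param capacity carrying-capacity OD plateau (default `Inf`).
#' @return Data frame with columns `time_h`, `od`.
#' @export
simulate_od_curve <- function(od0, mu, t_end, step, noise_sd = 0, seed = 1L,
                              capacity = Inf) {
  stopifnot(od0 > 0, step > 0, t_end >= 0, noise_sd >= 0, capacity > od0)
  t <- seq(0, t_end, by = step)
  od <- pmin(od0 * exp(mu * t), capacity)
  withr::with_seed(as.integer(seed), {
    if (noise_sd > 0)
      od <- pmax(od0 * 1e-6, od * (1 + rnorm(length(od), 0, noise_sd)))
  })
  data.frame(time_h = t, od = od)
}
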