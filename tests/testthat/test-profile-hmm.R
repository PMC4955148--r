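test_that("match columns follow the gap-fraction threshold", {
  m <- aa_msa(c("a", "b", "c", "d"),
              c("ACDEF", "AC-EF", "A--EF", "A-D-F"))
  lab <- assign_match_columns(m, 0.5)
  # col2 has 2/4 gaps (match at 0.5), col3 has 2/4, col4 has 1/4
  expect_equal(lab, c("match", "match", "match", "match", "match"))
  m2 <- aa_msa(c("a", "b", "c", "d"), c("A-A", "A-A", "A-A", "AAA"))
  expect_equal(assign_match_columns(m2, 0.5),
               c("match", "insert", "match"))
  # all-gap column is insert at any threshold < 1
  m3 <- aa_msa(c("a", "b"), c("A-A", "C-C"))
  expect_equal(assign_match_columns(m3, 0.99)[2], "insert")
  # lightly gapped alignment at the default threshold: everything match
  expect_equal(unique(assign_match_columns(fixture_msa(), 0.5)), "match")
})

test_that("Henikoff weights share column weight among residue types", {
  m <- aa_msa(c("a", "b", "c"), c("AA", "AA", "CC"))
  w <- sequence_weights(m)
  expect_equal(unname(w), c(0.25, 0.25, 0.5))
  # identical sequences get 1/n
  m2 <- aa_msa(c("a", "b", "c", "d"), rep("ACDE", 4))
  expect_equal(unname(sequence_weights(m2)), rep(0.25, 4))
  # single sequence gets weight 1
  expect_equal(unname(sequence_weights(aa_msa("a", "ACD"))), 1)
  expect_equal(sum(sequence_weights(fixture_msa())), 1)
})

test_that("profile construction matches hand-computed counts", {
  # single gapless sequence, alpha -> 0: indicator emissions
  m <- build_profile(aa_msa("a", "ACD"),
                     hmm_config(pseudocount_alpha = 1e-12))
  expect_equal(m$M, 3L)
  expect_equal(unname(m$match_emissions[1, "A"]), 1, tolerance = 1e-9)
  expect_equal(unname(m$match_emissions[2, "C"]), 1, tolerance = 1e-9)
  expect_equal(unname(m$match_emissions[3, "D"]), 1, tolerance = 1e-9)

  # 3-row toy, alpha = 1, uniform weighting: hand arithmetic
  # column 1 residues A,A,C; pseudocount alpha*20*q_a = 1 per letter
  # e(A) = (2+1)/(3+20) ; e(C) = (1+1)/23 ; e(G) = 1/23
  toy <- aa_msa(c("a", "b", "c"), c("AG", "AG", "CG"))
  mt <- build_profile(toy, hmm_config(pseudocount_alpha = 1,
                                      weighting = "uniform"))
  expect_equal(unname(mt$match_emissions[1, "A"]), 3 / 23)
  expect_equal(unname(mt$match_emissions[1, "C"]), 2 / 23)
  expect_equal(unname(mt$match_emissions[1, "G"]), 1 / 23)
  expect_equal(unname(mt$match_emissions[2, "G"]), 4 / 23)

  # transition hand-check: all 3 paths are M1->M2->E, alpha = 1
  # from node1 M: counts MM=3; targets {M,I,D}: p(MM) = (3+1)/(3+3)
  expect_equal(mt$trans$MM[2], 4 / 6)
  expect_equal(mt$trans$MI[2], 1 / 6)
  expect_equal(mt$trans$MD[2], 1 / 6)
  # node 2 (last): targets {E, I}: p(E) = (3+1)/(3+2)
  expect_equal(mt$trans$MM[3], 4 / 5)

  # probability rows normalize for any build
  fam <- simulate_family(family_spec(length = 60, n_members = 8, seed = 4,
                                     del_prob = 0.1))
  mm <- build_profile(fam$alignment)
  expect_equal(rowSums(mm$match_emissions), rep(1, mm$M), tolerance = 1e-9)
  expect_equal(rowSums(mm$insert_emissions), rep(1, mm$M + 1),
               tolerance = 1e-9)
  for (j in 0:mm$M) {
    k <- j + 1
    expect_equal(mm$trans$MM[k] + mm$trans$MI[k] + mm$trans$MD[k], 1,
                 tolerance = 1e-9)
    expect_equal(mm$trans$IM[k] + mm$trans$II[k] + mm$trans$ID[k], 1,
                 tolerance = 1e-9)
    if (j > 0)
      expect_equal(mm$trans$DM[k] + mm$trans$DD[k] + mm$trans$DI[k], 1,
                   tolerance = 1e-9)
  }

  # all-insert alignment is degenerate
  gappy <- aa_msa(c("a", "b", "c"), c("A--", "-C-", "--D"))
  expect_error(build_profile(gappy, hmm_config(match_gap_threshold = 0.1)),
               "degenerate")
})

test_that("forward score matches the closed-form single-state model", {
  msa <- aa_msa(c("a", "b", "c"), c("A", "A", "A"))
  for (mode in c("local", "glocal")) {
    m <- build_profile(msa, hmm_config(pseudocount_alpha = 1e-12,
                                       mode = mode))
    expect_equal(forward_score(m, "A"), log2(20), tolerance = 1e-6)
  }
  expect_error(forward_score(build_profile(msa), ""), "empty")
})

test_that("forward and viterbi agree with exhaustive path enumeration", {
  cases <- expand.grid(M = 1:3, L = 1:4, mode = c("local", "glocal"),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    M <- cases$M[r]; L <- cases$L[r]; mode <- cases$mode[r]
    model <- random_toy_model(M, mode, seed = 100 + r)
    s <- random_aa_string(L, seed = 200 + r)
    oracle <- oracle_path_odds(model, oracle_encode(s))
    expect_equal(forward_score(model, s), log2(oracle$total),
                 tolerance = 1e-9,
                 label = sprintf("forward M=%d L=%d %s", M, L, mode))
    expect_equal(viterbi_score(model, s)$bits, log2(oracle$best),
                 tolerance = 1e-9,
                 label = sprintf("viterbi M=%d L=%d %s", M, L, mode))
    expect_gte(forward_score(model, s) - viterbi_score(model, s)$bits,
               -1e-9)
  }
})

test_that("viterbi path of a planted consensus uses only match states", {
  fam <- simulate_family(family_spec(length = 40, n_members = 12,
                                     sub_prob = 0.05, del_prob = 0,
                                     seed = 5))
  m <- build_profile(fam$alignment, hmm_config(mode = "glocal"))
  v <- viterbi_score(m, fam$ancestor)
  expect_true(all(grepl("^M", v$path)))
  expect_equal(length(v$path), m$M)
})

test_that("log-space scoring stays finite on very long sequences", {
  fam <- simulate_family(family_spec(length = 80, n_members = 6, seed = 2))
  m <- build_profile(fam$alignment)
  long <- random_aa_string(10000, seed = 31)
  expect_true(is.finite(forward_score(m, long)))
  expect_true(is.finite(viterbi_score(m, long)$bits))
})

test_that("emissions approach background as pseudocounts grow", {
  msa <- aa_msa(c("a", "b"), c("AAAA", "AAAA"))
  kl <- vapply(c(0.5, 5, 50, 500), function(alpha) {
    m <- build_profile(msa, hmm_config(pseudocount_alpha = alpha))
    p <- m$match_emissions[1, ]
    sum(p * log(p / m$background))
  }, 0)
  expect_true(all(diff(kl) < 0))
  expect_lt(kl[4], 1e-3)
})

test_that("proteome scanning ranks deterministically with id tie-breaks", {
  fam <- simulate_family(family_spec(length = 100, n_members = 10, seed = 1))
  model <- build_profile(fam$alignment)
  prot <- plant_homolog_proteome(fam$alignment, decoys = 30, seed = 2)
  rk <- scan_proteome(model, prot, top_n = 15)
  expect_equal(nrow(rk), 15L)
  expect_equal(rk$rank, 1:15)
  expect_true(all(diff(rk$bits) <= 0))
  # permutation invariance
  perm <- prot[rev(seq_len(nrow(prot))), ]
  class(perm) <- class(prot)
  expect_equal(scan_proteome(model, perm, top_n = 15), rk)
  # fewer sequences than top_n
  small <- aa_seqs(c("x", "y"), c("ACDEF", "GHIKL"))
  expect_equal(nrow(scan_proteome(model, small, top_n = 15)), 2L)
  # bit-identical scores order by ascending id
  twin <- aa_seqs(c("zz", "aa"), c("ACDEF", "ACDEF"))
  rk2 <- scan_proteome(model, twin, top_n = 2)
  expect_equal(rk2$id, c("aa", "zz"))
  expect_equal(nrow(scan_proteome(model, aa_seqs(character(), character()),
                                  5)), 0L)
})

test_that("profile serialization round-trips scores exactly", {
  fam <- simulate_family(family_spec(length = 60, n_members = 8, seed = 12))
  m <- build_profile(fam$alignment)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile(m, f)
  m2 <- read_profile(f)
  s <- random_aa_string(80, seed = 77)
  expect_equal(forward_score(m2, s), forward_score(m, s), tolerance = 1e-12)
  expect_equal(m2$M, m$M)
})
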