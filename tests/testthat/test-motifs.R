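test_that("motif search reports 1-based overlapping occurrences", {
  s <- paste0("ACDEFG", "YFFYY", "KLMNP")
  hits <- find_motif(s, "YFFYY")
  expect_equal(hits$start, 7L)
  expect_equal(hits$end, 11L)
  expect_equal(hits$match, "YFFYY")

  over <- find_motif("YYYYY", "YY")
  expect_equal(over$start, 1:4)

  expect_equal(nrow(find_motif("ACD", "YFFYY")), 0L)

  # X wildcard and terminal alternation
  expect_equal(find_motif("GGLMFGYN", "GGLXXGYD/N")$start, 1L)
  expect_equal(find_motif("GGLMFGYD", "GGLXXGYD/N")$start, 1L)
  expect_equal(nrow(find_motif("GGLMFGYQ", "GGLXXGYD/N")), 0L)

  # naive recount oracle over random sequences and patterns
  pats <- c("YY", "GXG", "AC/DD", "YFFYY", "XGX")
  for (i in 1:10) {
    s <- random_aa_string(60, seed = 500 + i)
    for (p in pats)
      expect_equal(find_motif(s, p)$start, oracle_motif_starts(s, p),
                   label = paste("pattern", p, "seed", 500 + i))
  }
})

test_that("first-TM-span windows classify into substrate classes", {
  expect_equal(classify_transporter_motif("GGLMFGYD"), "xylose")
  expect_equal(classify_transporter_motif("GGLMFGYN"), "xylose")
  expect_equal(classify_transporter_motif("AGCDFGFD"), "arabinose")
  expect_equal(classify_transporter_motif("GGFAFGWG"), "glucose")
  # GXS1 wild-type motif GGVLFG: generic GG/FXXXG only
  expect_equal(classify_transporter_motif("GGVLFGWG"), "generic")
  expect_equal(classify_transporter_motif("GGVLFG"), "generic")
  expect_equal(classify_transporter_motif("AAAAAA"), "none")
  expect_error(classify_transporter_motif("GGLMF"), "at least 6")

  # the three 8-mer classes are mutually exclusive on any window
  for (i in 1:30) {
    w <- random_aa_string(8, seed = 900 + i)
    calls <- vapply(spminer:::TRANSPORTER_CLASS_PATTERNS, function(p)
      grepl(paste0("^", spminer:::.motif_regex(spminer:::.parse_motif(p))),
            w, perl = TRUE), TRUE)
    expect_lte(sum(calls), 1L)
  }
  # exclusivity on every 8-mer window of the fixture alignment members
  for (s in degap(fixture_msa())$seq) {
    for (st in seq_len(nchar(s) - 7L)) {
      w <- substr(s, st, st + 7L)
      cls <- classify_transporter_motif(w)
      expect_length(cls, 1L)
      expect_true(cls %in% c("xylose", "arabinose", "glucose", "generic",
                             "none"))
    }
  }
})

test_that("residue classes follow the fixed convention", {
  expect_equal(residue_class("M"), "aliphatic")  # by the usual convention
  expect_equal(residue_class("N"), "polar")
  expect_equal(residue_class("F"), "aromatic")
  expect_equal(residue_class("H"), "polar")
  expect_equal(residue_class("X"), "other")
  expect_equal(residue_class(c("F", "W", "Y")), rep("aromatic", 3))
  expect_equal(residue_class("P"), "other")
  expect_error(residue_class("1"), "not an amino-acid")
  # total over the alphabet: every residue classified
  expect_setequal(unique(residue_class(spminer:::AA_ALPHABET)),
                  c("aromatic", "aliphatic", "polar", "other"))
})

test_that("aligned-position mapping crosses gaps correctly", {
  m <- aa_msa(c("r", "t"), c("A-CD", "AECD"))
  # residue 2 of r is C, in column 3; t's residue there is index 3
  expect_equal(map_aligned_position(m, "r", 2, "t"), 3L)
  expect_equal(map_aligned_position(m, "t", 3, "r"), 2L)
  # identical ungapped sequences map to the same position
  m2 <- aa_msa(c("a", "b"), c("ACDEF", "ACDEF"))
  expect_equal(map_aligned_position(m2, "a", 4, "b"), 4L)
  # gap in target
  m3 <- aa_msa(c("r", "t"), c("ACD", "A-D"))
  expect_true(is.na(map_aligned_position(m3, "r", 2, "t")))
  expect_error(map_aligned_position(m, "nope", 1, "t"), "unknown")
  expect_error(map_aligned_position(m, "r", 9, "t"), "out of range")

  # composition with its inverse is the identity where no gap intervenes
  fam <- simulate_family(family_spec(length = 40, n_members = 4,
                                     del_prob = 0.1, seed = 21))
  al <- fam$alignment
  for (p in c(1, 5, 17, 30)) {
    q <- map_aligned_position(al, "fam01", p, "fam03")
    if (!is.na(q))
      expect_equal(map_aligned_position(al, "fam03", q, "fam01"), p)
  }
})

test_that("conservation reports map anchors across all members", {
  m <- fixture_msa()
  anchors <- data.frame(name = c("tm1_motif", "Y_anchor"),
                        ref_id = c("t1", "t1"),
                        start = c(1L, 14L), end = c(8L, NA))
  rep <- conservation_report(m, anchors)
  expect_equal(nrow(rep), 8L)  # 2 anchors x 4 members
  tm1 <- rep[rep$anchor == "tm1_motif", ]
  expect_equal(tm1$class_call,
               c("xylose", "xylose", "arabinose", "glucose"))
  expect_equal(tm1$conserved, c(TRUE, FALSE, FALSE, FALSE))
  ya <- rep[rep$anchor == "Y_anchor", ]
  expect_equal(unique(ya$text), "Y")
  expect_equal(unique(ya$classes), "aromatic")

  expect_equal(nrow(conservation_report(m, anchors[0, ])), 0L)
  bad <- data.frame(name = "a", ref_id = "missing", start = 1L)
  expect_error(conservation_report(m, bad), "unknown")
})

test_that("promoter scanning covers both strands of the trailing window", {
  withr::with_seed(77, {
    bg <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                collapse = "")
  })
  # avoid accidental motif occurrences
  bg <- gsub("GGCTAA", "GGATAA", bg)
  bg <- gsub("TTAGCC", "TTAGGC", bg)
  up <- paste0(substr(bg, 1, 300), "GGCTAA", substr(bg, 307, 1200))
  hits <- scan_promoter(up, "GGCTAA", region = 1000)
  expect_equal(hits$start, 301L)
  expect_equal(hits$strand, "+")

  # reverse-complement occurrence reported on the minus strand
  up2 <- paste0(substr(bg, 1, 500), "TTAGCC", substr(bg, 507, 1200))
  h2 <- scan_promoter(up2, "GGCTAA", region = 1000)
  expect_equal(h2$start, 501L)
  expect_equal(h2$strand, "-")

  # hits outside the trailing window are not reported
  far <- paste0("GGCTAA", substr(bg, 7, 1200))
  expect_equal(nrow(scan_promoter(far, "GGCTAA", region = 1000)), 0L)
  expect_equal(nrow(scan_promoter(far, "GGCTAA", region = 1200)), 1L)

  # IUPAC degeneracy
  expect_equal(scan_promoter("AAGGCTAAACC", "GGCTAWA", region = 11)$start,
               3L)

  expect_equal(nrow(scan_promoter("ACG", "GGCTAA")), 0L)
  expect_error(scan_promoter("ACGT", ""), "non-empty")

  # strand consistency: scanning the reverse complement swaps strands and
  # mirrors coordinates
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(up2)))
  h3 <- scan_promoter(rc, "GGCTAA", region = nchar(rc))
  h2b <- scan_promoter(up2, "GGCTAA", region = nchar(up2))
  expect_equal(nrow(h3), nrow(h2b))
  expect_equal(sort(nchar(up2) - (h2b$start + 6 - 1) + 1),
               sort(h3$start))
  expect_setequal(h3$strand, setdiff(c("+", "-"), h2b$strand))
})

test_that("multi-region scans attach gene ids", {
  regions <- c(g1 = "AAAAGGCTAAACCCC", g2 = "TTTTTTTTTTTT")
  hits <- scan_promoters(regions, "GGCTAAA", region = 15)
  expect_equal(hits$id, "g1")
  expect_equal(hits$start, 5L)
  expect_error(scan_promoters(unname(regions), "GGCTAAA"), "named")
})
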