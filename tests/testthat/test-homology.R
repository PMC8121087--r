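simple4 <- scoring_scheme("simple", match = 1, mismatch = -1,
                          gap_opening = 10, gap_extension = 4)

test_that("global alignment scores hand-checkable cases", {
  expect_equal(nw_align("ACDE", "ACDE", simple4)$score, 4)
  out <- nw_align("ACD", "AD", simple4)
  expect_equal(out$score, -12)          # 1 + 1 - (10 + 4)
  expect_equal(out$aligned_a, "ACD")
  expect_equal(out$aligned_b, "A-D")
  expect_error(nw_align("", "A", simple4), "non-empty")
  expect_error(nw_align("AC1", "AC", simple4), "illegal residue")
  # X scores 0 against everything under simple scoring
  expect_equal(nw_align("AXA", "AAA", simple4)$score, 2)
})

test_that("dynamic program equals the exhaustive alignment enumerator", {
  set.seed(20)
  alphabet <- c("A", "C", "G", "T")
  for (rep in 1:60) {
    la <- sample(1:6, 1); lb <- sample(1:6, 1)
    a <- paste(sample(alphabet, la, replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, lb, replace = TRUE), collapse = "")
    expect_equal(nw_align(a, b, simple4)$score,
                 enum_align_score(a, b, simple4),
                 info = paste(a, b))
  }
  # also under a cheaper gap scheme where gaps actually win
  cheap <- scoring_scheme("simple", match = 2, mismatch = -3,
                          gap_opening = 1, gap_extension = 1)
  for (rep in 1:40) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(nw_align(a, b, cheap)$score, enum_align_score(a, b, cheap),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric and maximal on self", {
  set.seed(21)
  seqs <- vapply(1:5, function(i) {
    paste(sample(protacclim:::AA20, 12, replace = TRUE), collapse = "")
  }, character(1))
  for (i in 1:4) {
    expect_equal(nw_align(seqs[i], seqs[i + 1])$score,
                 nw_align(seqs[i + 1], seqs[i])$score)
  }
  db <- fasta_db(paste0("S", 1:5), seqs)
  sc <- align_all(db, db, simple4)
  expect_equal(unname(diag(sc)), nchar(seqs))
  for (i in 1:5) expect_equal(which.max(sc[i, ]), i, ignore_attr = TRUE)
  # 1x1 table equals nw_align
  sc1 <- align_all(db[1, ], db[2, ], simple4)
  expect_equal(sc1[1, 1], nw_align(seqs[1], seqs[2], simple4)$score)
  expect_error(align_all(db[0, ], db), "non-empty")
})

test_that("alignment agrees with an independent reference engine", {
  set.seed(22)
  for (rep in 1:10) {
    a <- paste(sample(protacclim:::AA20, sample(8:25, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(protacclim:::AA20, sample(8:25, 1), replace = TRUE),
               collapse = "")
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4,
      type = "global"))
    expect_equal(nw_align(a, b, scoring_scheme("blosum62"))$score, ref)
  }
})

test_that("synthetic proteome pairs map back to their true families", {
  pp <- generate_proteome_pair(3, 2, 0.05, seed = 1)
  sc <- align_all(pp$query, pp$reference)
  fam_map <- setNames(pp$truth$family, pp$truth$reference_id)
  asg <- assign_paralogs(sc, fam_map)
  expect_gte(mean(asg$family == pp$truth$family), 5 / 6)
  expect_true(all(asg$accepted))
})

test_that("paralog assignment applies threshold, ties and evidence classes", {
  sc <- rbind(q1 = c(r1 = 9.9, r2 = 3),
              q2 = c(r1 = 15, r2 = 15),
              q3 = c(r1 = 2, r2 = 40))
  fam <- c(r1 = "uS14", r2 = "uS14")
  ev <- data.frame(query_id = c("q1", "q2"),
                   peptide = c("PEPK", "PEPR"),
                   is_unique = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expect_warning(asg <- assign_paralogs(sc, fam, ev), "absent")
  expect_false(asg$accepted[asg$query_id == "q1"])   # 9.9 <= 10 rejected
  # equal-score candidates from one family both listed, family assigned
  expect_equal(asg$candidates[asg$query_id == "q2"], "r1;r2")
  expect_equal(asg$family[asg$query_id == "q2"], "uS14")
  expect_equal(asg$evidence, c("certain", "potential", "potential"))
  expect_equal(attr(asg, "n_certain"), 0)  # q1 certain but not accepted
  expect_equal(attr(asg, "n_potential"), 2)
  # raising the threshold never increases the accepted count
  n_acc <- vapply(c(0, 10, 20, 50), function(th) {
    sum(suppressWarnings(assign_paralogs(sc, fam, ev,
                                         threshold = th))$accepted)
  }, numeric(1))
  expect_true(all(diff(n_acc) <= 0))
  expect_error(assign_paralogs(sc, fam[1]), "family_map missing")
})

test_that("planted unique peptides yield the planted certain count", {
  pp <- generate_proteome_pair(4, 2, 0.02, seed = 9)
  sc <- align_all(pp$query, pp$reference)
  fam_map <- setNames(pp$truth$family, pp$truth$reference_id)
  qids <- pp$truth$query_id
  ev <- data.frame(query_id = qids,
                   peptide = paste0("PEP", seq_along(qids)),
                   is_unique = seq_along(qids) <= 4, stringsAsFactors = FALSE)
  asg <- assign_paralogs(sc, fam_map, ev)
  expect_equal(attr(asg, "n_certain"), sum(asg$accepted[1:4]))
})

test_that("translation-related selection uses keywords and GO whitelist", {
  ev <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4"),
    description = c("60S ribosomal protein L7",
                    "Ribosome biogenesis factor",
                    "chitinase",
                    "unknown protein"),
    go_terms = c("", "", "", "GO:0006412"),
    stringsAsFactors = FALSE)
  expect_equal(select_translation_related(ev), c("p1", "p2"))
  expect_equal(select_translation_related(ev, "GO:0006412"),
               c("p1", "p2", "p4"))
})

test_that("FASTA databases round-trip through standard files", {
  pp <- generate_proteome_pair(2, 2, 0.1, seed = 2)
  f <- tempfile(fileext = ".fasta")
  write_fasta_db(pp$reference, f)
  back <- read_fasta_db(f)
  expect_equal(back$seq, pp$reference$seq)
  expect_error(fasta_db(c("a", "a"), c("MK", "ML")), "unique")
  expect_error(fasta_db("a", ""), "zero-length")
})
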