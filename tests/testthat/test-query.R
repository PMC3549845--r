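test_that("the tailored matrix keeps symmetry and isobaric structure", {
  sm <- build_matrix()
  M <- sm$matrix
  expect_equal(M, t(M))
  # full interchangeability: identical rows for L/I and Q/K
  expect_equal(M["L", ], M["I", ])
  expect_equal(M["Q", ], M["K", ])
  expect_equal(M["L", "I"], M["L", "L"])
  expect_equal(M["Q", "K"], M["K", "K"])
  # X scores zero against everything
  expect_true(all(M["X", ] == 0))
  expect_true(all(M[, "X"] == 0))
})

test_that("averaged entries match the standard BLOSUM62 read independently", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  M <- build_matrix()$matrix
  expect_equal(M["L", "I"], (B["L", "L"] + B["I", "I"]) / 2)
  expect_equal(M["Q", "K"], (B["Q", "Q"] + B["K", "K"]) / 2)
  # cleavage anchor: average of the K and R diagonals, against K and R only
  expect_equal(M["^", "K"], (B["K", "K"] + B["R", "R"]) / 2)
  expect_equal(M["^", "R"], (B["K", "K"] + B["R", "R"]) / 2)
  expect_equal(M["^", "A"], 0)
  # untouched entries stay at their BLOSUM62 values
  expect_equal(M["W", "W"], B["W", "W"])
  expect_equal(M["A", "D"], B["A", "D"])
})

test_that("local_align agrees with the Biostrings aligner", {
  sm <- build_matrix()
  B <- sm$matrix[1:20, 1:20]
  storage.mode(B) <- "double"
  aa <- rownames(B)
  set.seed(41)
  for (i in 1:120) {
    q <- paste(sample(aa, sample(3:10, 1), TRUE), collapse = "")
    s <- paste(sample(aa, sample(3:10, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = B,
      gapOpening = sm$gap_open, gapExtension = sm$gap_extend,
      scoreOnly = TRUE)
    expect_equal(local_align(q, s, sm)$score, max(ref, 0), info = paste(q, s))
  }
})

test_that("an exactly contained tag scores the sum of diagonal entries", {
  sm <- build_matrix()
  tag <- "WDNAY"
  pep <- "GGWDNAYEK"
  al <- local_align(tag, pep, sm)
  expect_equal(al$score,
               sum(diag(sm$matrix[strsplit(tag, "")[[1]],
                                  strsplit(tag, "")[[1]]])))
  expect_equal(al$subject_span, c(3L, 7L))
})

test_that("Ss is invariant under L/I and Q/K swaps in the tag", {
  sm <- build_matrix()
  set.seed(43)
  aa <- rownames(sm$matrix)[1:20]
  for (i in 1:40) {
    tag <- paste(sample(aa, 6, TRUE), collapse = "")
    pep <- paste(sample(aa, 12, TRUE), collapse = "")
    swapped <- chartr("LIQK", "ILKQ", tag)
    expect_equal(local_align(tag, pep, sm)$score,
                 local_align(swapped, pep, sm)$score)
  }
})

test_that("query_tags prefilters by mass, merges per peptide, caps hits", {
  sm <- build_matrix()
  prot <- data.frame(
    accession = c("P1", "P2"), description = "",
    sequence = c("MAAAGWDNAYEKTTTR", "MWDNAYWDNAYWDNAYKR")
  )
  idx <- build_peptide_index(prot, missed_cleavages = 0L, min_len = 5L,
                             max_len = 20L)
  # tryptic peptides: MAAAGWDNAYEK (P1) and MWDNAYWDNAYWDNAYK (P2)
  tags <- data.frame(tag = "WDNAY", prefix_gap = 500, suffix_gap = 300,
                     score = 5)
  M_target <- peptide_mass("MAAAGWDNAYEK")
  hits <- query_tags(tags, idx, sm, M_target, max_hits = 10L,
                     mass_window = 2.5)
  expect_true(all(abs(hits$mass - M_target) <= 2.5))
  expect_equal(hits$peptide[1], "MAAAGWDNAYEK")
  # no duplicate peptides after merging
  expect_false(any(duplicated(paste(hits$peptide, hits$parent_accession))))
  # open search sees every peptide; cap respected
  hits_open <- query_tags(tags, idx, sm, M_target, max_hits = 2L,
                          mass_window = Inf)
  expect_lte(nrow(hits_open), 2L)
  # empty tag list -> empty result
  expect_equal(nrow(query_tags(tags[0, ], idx, sm, M_target)), 0L)
})

test_that("an N-terminal tag gains the cleavage-anchor bonus", {
  sm <- build_matrix()
  idx <- data.frame(sequence = "WDNAYEK", parent_accession = "P1",
                    start = 0L, end = 7L, missed_cleavages = 0L,
                    mass = peptide_mass("WDNAYEK"), is_decoy = FALSE)
  tags <- data.frame(tag = "WDNAY", prefix_gap = 0, suffix_gap = 100,
                     score = 5)
  anchored <- query_tags(tags, idx, sm, peptide_mass("WDNAYEK"),
                         mass_window = Inf)
  tags$prefix_gap <- 250  # same tag placed mid-peptide: no anchor
  plain <- query_tags(tags, idx, sm, peptide_mass("WDNAYEK"),
                      mass_window = Inf)
  expect_equal(anchored$Ss - plain$Ss, build_matrix()$matrix["^", "K"])
})
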