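# hand-built linear graph: source - v1 - v2 - ... - sink spelling `residues`
linear_graph <- function(residues, scores = rep(1, nchar(residues) + 2L)) {
  res <- strsplit(residues, "")[[1]]
  pm <- c(0, unname(cumsum(RESIDUE_MASS[res])))
  n <- length(pm)
  vertices <- data.frame(
    id = seq_len(n), prefix_mass = unname(pm),
    interp = c("source", rep("b", n - 2L), "sink"),
    origin_peak = c(NA, seq_len(n - 2L), NA),
    score = scores[seq_len(n)]
  )
  vertices$score[c(1, n)] <- 0
  edges <- data.frame(from = seq_len(n - 1L), to = 2:n, residue = res)
  structure(
    list(vertices = vertices, origin_sets = NULL, edges = edges,
         source_id = 1L, sink_id = n,
         neutral_mass = pm[n] + MASS_CONST[["water"]],
         residue_mass_total = unname(pm[n]), tolerance = 0.5),
    class = "SpectrumGraph"
  )
}

test_that("top_k_paths on a linear chain yields exactly one path", {
  g <- linear_graph("PEPTIDEK")
  p <- top_k_paths(g, 20)
  expect_length(p, 1L)
  expect_equal(p[[1]]$residues, "PEPTIDEK")
  expect_equal(p[[1]]$score, 7)  # 7 internal vertices at score 1
})

test_that("top_k_paths matches exhaustive enumeration on random DAGs", {
  set.seed(101)
  for (trial in 1:150) {
    g <- random_dag_graph()
    k <- sample(1:6, 1)
    mine <- top_k_paths(g, k)
    oracle <- brute_force_paths(g, k)
    expect_equal(length(mine), length(oracle))
    expect_equal(lapply(mine, `[[`, "score"),
                 lapply(oracle, `[[`, "score"))
    expect_equal(lapply(mine, `[[`, "residues"),
                 lapply(oracle, `[[`, "residues"))
  }
})

test_that("k = 1 returns the optimal antisymmetric path", {
  set.seed(55)
  for (trial in 1:30) {
    g <- random_dag_graph()
    best <- top_k_paths(g, 1)
    all_paths <- brute_force_paths(g, .Machine$integer.max)
    if (length(all_paths) == 0L) {
      expect_length(best, 0L)
    } else {
      expect_equal(best[[1]]$score, all_paths[[1]]$score)
    }
  }
})

test_that("graphs without a source-sink path yield an empty list", {
  g <- linear_graph("AG")
  g$edges <- g$edges[-1L, , drop = FALSE]  # cut the chain
  expect_length(top_k_paths(g, 5), 0L)
})

test_that("align_candidates reproduces simple alignments", {
  mk <- function(s) list(residues = s, score = 1,
                         vertices = seq_len(nchar(s) + 1L),
                         prefix_masses = c(0, cumsum(
                           RESIDUE_MASS[strsplit(s, "")[[1]]])))
  # identical sequences align without gaps
  aln <- align_candidates(list(mk("PEPTIDE"), mk("PEPTIDE")))
  expect_equal(dim(aln), c(2L, 7L))
  expect_false(any(aln == "-"))

  # deletion of 2 residues: exactly 2 gap columns in the second row
  aln2 <- align_candidates(list(mk("PEPTIDE"), mk("PEPDE")))
  expect_equal(ncol(aln2), 7L)
  expect_equal(sum(aln2[2, ] == "-"), 2L)
  expect_equal(paste(aln2[1, ], collapse = ""), "PEPTIDE")

  # a single path is returned as a 1-row alignment
  aln3 <- align_candidates(list(mk("AGAK")))
  expect_equal(dim(aln3), c(1L, 4L))
})

test_that("extract_tags returns consensus runs with correct gaps", {
  g <- linear_graph("PEPTIDEK")
  paths <- top_k_paths(g, 5)
  aln <- align_candidates(paths)
  # single unanimous row, length 8, max_len 10: one full-length tag
  tags <- extract_tags(aln, g, min_len = 3L, max_len = 10L)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$tag, "PEPTIDEK")
  expect_equal(tags$prefix_gap, 0)
  expect_equal(tags$suffix_gap, MASS_CONST[["water"]])
  # mass closure against the neutral precursor mass
  expect_equal(tags$prefix_gap + residue_sum(tags$tag) + tags$suffix_gap,
               g$neutral_mass)
})

test_that("a broken consensus column splits tags and clipping is by score", {
  mk <- function(s, score) list(residues = s, score = score,
                                vertices = seq_len(nchar(s) + 1L),
                                prefix_masses = c(0, cumsum(
                                  RESIDUE_MASS[strsplit(s, "")[[1]]])))
  g <- linear_graph("AGAGWGAGA")
  # disagreeing middle column (W vs F are same length): two flanking tags
  paths <- list(mk("AGAGWGAGA", 2), mk("AGAGFGAGA", 1))
  aln <- align_candidates(paths)
  tags <- extract_tags(aln, g, min_len = 3L, max_len = 10L,
                       min_support_fraction = 0.9)
  # both rows propose the flanking runs; the GAGA proposals differ in
  # prefix mass (W vs F interpretations), so both survive deduplication
  expect_setequal(unique(tags$tag), c("AGAG", "GAGA"))
  expect_false("AGAGWGAGA" %in% tags$tag)

  # unanimous run longer than max_len clips to the best-scoring window.
  # vertex scores rise along the chain (terminals at 0); column j scores
  # (s_j + s_{j+1}) / 2, so the best 4-column window starts at column 5
  vsc <- c(0, seq(0.5, 4, by = 0.5), 0)  # 10 vertices, terminals at 0
  g2 <- linear_graph("AGAGWGAGA", scores = vsc)
  col_sc <- (vsc[1:9] + vsc[2:10]) / 2
  best <- which.max(vapply(1:6, function(s) mean(col_sc[s:(s + 3)]),
                           numeric(1)))
  expect_equal(best, 5L)  # hand-computed window start
  p2 <- top_k_paths(g2, 3)
  aln2 <- align_candidates(p2)
  t2 <- extract_tags(aln2, g2, min_len = 3L, max_len = 4L)
  expect_equal(nchar(t2$tag), 4L)
  expect_equal(t2$tag, substr("AGAGWGAGA", 5, 8))  # "WGAG"
  expect_equal(t2$prefix_gap, sum(RESIDUE_MASS[c("A", "G", "A", "G")]),
               ignore_attr = TRUE)
})

test_that("tags are substrings of their paths with closed mass budgets", {
  fit <- shared_fit()
  set.seed(23)
  for (i in 1:25) {
    pep <- random_peptide(sample(9:13, 1))
    sim <- ladder_spectrum(pep)
    proc <- preprocess_spectrum(sim$spectrum)
    g <- build_graph(proc, 0.5)
    g <- score_graph(g, proc, fit$model, fit$noise)
    paths <- top_k_paths(g, 20)
    if (length(paths) == 0L) next
    aln <- align_candidates(paths)
    tags <- extract_tags(aln, g)
    for (j in seq_len(nrow(tags))) {
      expect_true(any(vapply(paths, function(p)
        grepl(tags$tag[j], p$residues, fixed = TRUE), logical(1))),
        info = tags$tag[j])
      closure <- tags$prefix_gap[j] + residue_sum(tags$tag[j]) +
        tags$suffix_gap[j]
      expect_lt(abs(closure - spectrum_neutral_mass(sim$spectrum)), 1)
    }
  }
})

test_that("the top tag is an exact substring of the truth in >= 95% of 200", {
  fit <- train_default_model(n_train = 200L, seed = 101L)
  bench <- simulate_benchmark(n_spectra = 200,
                              params = sim_params_noise_free(300), seed = 19)
  n_ok <- 0L
  for (sim in bench$annotated) {
    tags <- infer_tags(sim$spectrum, fit$model, fit$noise)
    if (nrow(tags) > 0L &&
        grepl(tags$tag[1], canonical_residues(sim$peptide), fixed = TRUE)) {
      n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / 200, 0.95)
})
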