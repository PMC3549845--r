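# a hand-built trained model whose conditionals are all a known constant,
# plus a uniform noise model: p_real and p_random become simple powers
constant_model <- function(p = 0.25, tolerance = 0.5) {
  m <- peptag:::new_cpt_model()
  m$tables <- lapply(m$counts, function(a) array(p, dim = dim(a)))
  m$tolerance <- tolerance
  m$trained <- TRUE
  noise <- matrix(0.25, nrow = 5, ncol = 4)
  class(noise) <- c("NoiseModel", class(noise))
  list(model = m, noise = noise)
}

test_that("train_model smooths empty cells to uniform and learns dominance", {
  set.seed(2)
  ann <- lapply(1:30, function(i) {
    sim <- ladder_spectrum(random_peptide(9))
    list(spectrum = sim$spectrum, peptide = sim$peptide)
  })
  fit <- train_model(ann)
  # every conditional distribution sums to 1
  for (ion in peptag:::ION_TYPES) {
    tab <- fit$model$tables[[ion]]
    sums <- apply(tab, seq_along(dim(tab))[-1], sum)
    expect_true(all(abs(sums - 1) < 1e-9), info = ion)
    expect_true(all(tab > 0), info = ion)
  }
  # noise-free world: y always strong (level 3), b always medium (level 2)
  expect_equal(unname(which.max(fit$model$marginals["y", ])), 4L)
  expect_equal(unname(which.max(fit$model$marginals["b", ])), 3L)
  # a context never observed stays at the uniform prior (pure pseudo-counts)
  # NT class H (2) with CT class H: vanishingly rare in 30 spectra of 9
  # residues; find an all-smoothing cell by looking for exact uniformity
  tab_b <- fit$model$tables[["b"]]
  expect_true(any(abs(tab_b - 0.25) < 1e-12))
  expect_error(train_model(list()), "empty")
})

test_that("p_real is a product of conditionals and p_random of noise terms", {
  fit <- constant_model(p = 0.25)
  sim <- ladder_spectrum("PEPTIDEK")
  proc <- preprocess_spectrum(sim$spectrum)
  m <- sum(RESIDUE_MASS[c("P", "E", "P")])
  expect_equal(p_real(m, proc, fit$model), 0.25^9)
  expect_equal(p_random(m, proc, fit$noise, 0.5), 0.25^9)
  # likelihood ratio 1 -> score exactly 0
  expect_equal(score_vertex(m, proc, fit$model, fit$noise), 0)
  # untrained model errors
  um <- peptag:::new_cpt_model()
  expect_error(p_real(m, proc, um), "not trained")
})

test_that("score_vertex is log(p_real) - log(p_random)", {
  fit <- shared_fit()
  set.seed(3)
  sim <- ladder_spectrum(random_peptide(10))
  proc <- preprocess_spectrum(sim$spectrum)
  for (m in runif(10, 150, proc$residue_mass_total - 150)) {
    o <- score_vertex(m, proc, fit$model, fit$noise)
    expect_equal(o, log(p_real(m, proc, fit$model)) -
                   log(p_random(m, proc, fit$noise, fit$model$tolerance)))
    expect_true(is.finite(o))
  }
})

test_that("p_real ignores peak order and intensity scale within levels", {
  fit <- shared_fit()
  set.seed(8)
  sim <- simulate_spectrum(random_peptide(11), sim_params())
  sp <- sim$spectrum
  proc <- preprocess_spectrum(sp)
  m <- proc$residue_mass_total / 2
  ref <- p_real(m, proc, fit$model)
  # shuffle peaks: spectrum() restores canonical order
  o <- sample(nrow(sp$peaks))
  sp_shuf <- spectrum(sp$peaks$mz[o], sp$peaks$intensity[o],
                      sp$precursor_mz, sp$precursor_charge, sp$id)
  expect_equal(p_real(m, preprocess_spectrum(sp_shuf), fit$model), ref)
  # rescaling all raw intensities preserves baseline-normalised levels
  sp_scaled <- spectrum(sp$peaks$mz, sp$peaks$intensity * 37,
                        sp$precursor_mz, sp$precursor_charge, sp$id)
  expect_equal(p_real(m, preprocess_spectrum(sp_scaled), fit$model), ref)
})

test_that("model JSON serialisation round-trips exactly", {
  fit <- shared_fit()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, f)
  back <- read_model_json(f)
  expect_equal(back$model$tables, fit$model$tables)
  expect_equal(unclass(back$noise), unclass(fit$noise), ignore_attr = TRUE)
  expect_equal(back$model$tolerance, fit$model$tolerance)
  # identical scores through the round-tripped model
  set.seed(4)
  sim <- ladder_spectrum(random_peptide(9))
  proc <- preprocess_spectrum(sim$spectrum)
  m <- proc$residue_mass_total / 3
  expect_equal(score_vertex(m, proc, back$model, back$noise),
               score_vertex(m, proc, fit$model, fit$noise))
})

test_that("trained scores separate true cleavages from random masses", {
  fit <- shared_fit()
  set.seed(9)
  strue <- c(); srand <- c()
  for (i in 1:30) {
    sim <- simulate_spectrum(random_peptide(10), sim_params())
    proc <- preprocess_spectrum(sim$spectrum)
    res <- strsplit(sim$peptide, "")[[1]]
    pref <- cumsum(RESIDUE_MASS[res])
    pref <- pref[-length(pref)]
    strue <- c(strue, vapply(pref, function(m)
      score_vertex(m, proc, fit$model, fit$noise), numeric(1)))
    rnd <- runif(length(pref), 120, proc$residue_mass_total - 120)
    srand <- c(srand, vapply(rnd, function(m)
      score_vertex(m, proc, fit$model, fit$noise), numeric(1)))
  }
  expect_gt(mean(strue), mean(srand))
})
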