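test_that("theoretical spectra carry the nine ion types at set intensities", {
  th <- theoretical_spectrum("PEPTIDEK", charge = 2L)
  n <- nchar("PEPTIDEK") - 1L
  expect_equal(nrow(th), 9L * n)
  expect_true(all(th$intensity[th$ion_type %in% c("b", "y")] == 100))
  expect_true(all(th$intensity[th$ion_type %in% c("b2", "y2")] == 50))
  expect_true(all(th$intensity[th$ion_type %in%
                                 c("a", "bH2O", "bNH3", "yH2O", "yNH3")] == 20))
  # singly charged precursor: no doubly charged fragments
  th1 <- theoretical_spectrum("PEPTIDEK", charge = 1L)
  expect_equal(nrow(th1), 7L * n)
  expect_false(any(th1$ion_type %in% c("b2", "y2")))
  expect_error(theoretical_spectrum("G", 2L), "at least 2")
})

test_that("fragment m/z arithmetic matches the residue mass table", {
  th <- theoretical_spectrum("GG", charge = 1L)
  b1 <- th$mz[th$ion_type == "b" & th$ordinal == 1L]
  expect_equal(b1, 57.02146374 + 1.007276466, tolerance = 1e-6)
  y1 <- th$mz[th$ion_type == "y" & th$ordinal == 1L]
  expect_equal(y1, 57.02146374 + 18.010564684 + 1.007276466, tolerance = 1e-6)
})

# processed spectrum whose kept peaks are exactly `mz` with normalised
# intensity `norm`
proc_from_peaks <- function(mz, norm, prec_mz, charge = 2L) {
  sp <- spectrum(mz, norm, prec_mz, charge)
  M <- prec_mz * charge - charge * MASS_CONST[["proton"]]
  structure(
    list(spectrum = sp, norm_intensity = sp$peaks$intensity,
         level = rep(3L, nrow(sp$peaks)), region = rep(0L, nrow(sp$peaks)),
         kept = rep(TRUE, nrow(sp$peaks)), n_regions = 5L,
         neutral_mass = M,
         residue_mass_total = M - MASS_CONST[["water"]]),
    class = "ProcessedSpectrum"
  )
}

test_that("match_ions self-match fills I and counts primary series", {
  pep <- "LVEALYK"
  th <- theoretical_spectrum(pep, 2L)
  proc <- proc_from_peaks(th$mz, rep(10, nrow(th)), precursor_mz(pep, 2L))
  res <- match_ions(proc, th, tolerance = 0.5)
  n <- nchar(pep) - 1L
  expect_true(all(res$I > 0))
  expect_equal(length(res$I), nrow(th))
  # b+ and b2+ of one cleavage count as a single assigned b-ion
  expect_equal(res$Nb, n)
  expect_equal(res$Ny, n)
})

test_that("empty experimental spectra match nothing", {
  th <- theoretical_spectrum("PEPTIDEK", 2L)
  proc <- proc_from_peaks(5000, 1, precursor_mz("PEPTIDEK", 2L))
  res <- match_ions(proc, th, tolerance = 0.5)
  expect_true(all(res$I == 0))
  expect_equal(res$Nb + res$Ny, 0L)
})

test_that("greedy matching assigns each peak to its closest partner once", {
  th <- data.frame(mz = c(200.0, 200.6), intensity = c(100, 100),
                   ion_type = c("b", "y"), ordinal = c(1L, 1L))
  proc <- proc_from_peaks(200.25, 7, 500)
  res <- match_ions(proc, th, tolerance = 0.5)
  expect_equal(res$I, c(7, 0))  # closer theoretical peak wins
  expect_equal(res$Nb, 1L)
  expect_equal(res$Ny, 0L)
})

test_that("correlation_score evaluates the factorial dot-product in logs", {
  mk <- function(I, P, Nb, Ny) structure(
    list(I = I, P = P, Nb = Nb, Ny = Ny), class = "MatchResult")
  # no match -> 0 with flag
  s0 <- correlation_score(mk(c(0, 0), c(100, 100), 0L, 0L))
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "no_match"))
  # Nb! * Ny! * dot = 2 * 1 * 10 = 20
  s <- correlation_score(mk(c(0.1), c(100), 2L, 1L))
  expect_equal(as.numeric(s), log(20))
  # doubling intensities adds exactly log(2)
  s2 <- correlation_score(mk(c(0.2), c(100), 2L, 1L))
  expect_equal(as.numeric(s2) - as.numeric(s), log(2))
  expect_error(correlation_score(mk(c(-1), c(100), 0L, 0L)), "negative")
})

test_that("the log form equals the literal product up to Nb, Ny = 10", {
  set.seed(12)
  for (i in 1:50) {
    Nb <- sample(0:10, 1); Ny <- sample(0:10, 1)
    I <- runif(5, 0, 5); P <- sample(c(20, 50, 100), 5, TRUE)
    r <- structure(list(I = I, P = P, Nb = Nb, Ny = Ny),
                   class = "MatchResult")
    expect_equal(exp(as.numeric(correlation_score(r))),
                 factorial(Nb) * factorial(Ny) * sum(I * P))
  }
})

test_that("Sc ranks the true peptide above same-mass decoys (noise-free)", {
  set.seed(31)
  n_ok <- 0L; n_trials <- 40L
  for (i in seq_len(n_trials)) {
    pep <- random_peptide(10)
    sim <- ladder_spectrum(pep)
    proc <- preprocess_spectrum(sim$spectrum)
    sc_true <- as.numeric(correlation_score(match_ions(
      proc, theoretical_spectrum(pep, 2L), 0.5)))
    # same-composition decoy: shuffle interior residues (same mass)
    res <- strsplit(pep, "")[[1]]
    n <- length(res)
    dec <- paste(c(res[sample(n - 1L)], res[n]), collapse = "")
    if (dec == pep) next
    sc_dec <- as.numeric(correlation_score(match_ions(
      proc, theoretical_spectrum(dec, 2L), 0.5)))
    if (sc_true > sc_dec) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_trials, 0.95)
})
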