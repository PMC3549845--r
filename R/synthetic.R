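## Synthetic proteins and annotated spectra with the statistical structure
## the method assumes: b/y fragment ladders with ion-type-dependent
## discrete intensity levels, missing fragments, mass jitter and uniform
## noise peaks. Everything is driven by one parameter object and a seed.

#' Simulation parameters
#'
#' Defaults describe a realistic tryptic CID world: primary b+/y+ ions are
#' detected almost always and are strong; doubly charged ions are detected
#' half the time at medium level; a+ and neutral-loss ions are sporadic and
#' weak. Emission intensities are placed at the centres of the default
#' discretisation bins (thresholds 1/3/10 on baseline-normalised
#' intensity), with noise peaks straddling the baseline, so the
#' discrete-level family the generator draws from is the one the Bayesian
#' model estimates.
#'
#' @param n_proteins Number of proteins in the synthetic database.
#' @param protein_length_mean,protein_length_sd Normal protein length
#'   distribution (truncated below at 60 residues).
#' @param charge Precursor charge of simulated spectra.
#' @param detect Named detection probability per ion type.
#' @param level_probs Named list: per ion type, probability of discrete
#'   levels 1..3 given detection (level 0 arises from non-detection).
#' @param level_intensity 3x2 matrix of `runif` bounds per level.
#' @param noise_mean Poisson mean of the uniform noise peak count.
#' @param noise_intensity `runif` bounds for noise peak intensities.
#' @param mass_jitter_sd Gaussian m/z jitter standard deviation (Da).
#' @return List of class `SimulationParams`.
#' @export
sim_params <- function(n_proteins = 500L,
                       protein_length_mean = 300,
                       protein_length_sd = 50,
                       charge = 2L,
                       detect = c(b = 0.85, y = 0.95, a = 0.3,
                                  bH2O = 0.3, bNH3 = 0.3, b2 = 0.5,
                                  yH2O = 0.3, yNH3 = 0.3, y2 = 0.5),
                       level_probs = list(
                         b = c(0.15, 0.35, 0.50),
                         y = c(0.05, 0.20, 0.75),
                         a = c(0.70, 0.25, 0.05),
                         bH2O = c(0.70, 0.25, 0.05),
                         bNH3 = c(0.70, 0.25, 0.05),
                         b2 = c(0.20, 0.60, 0.20),
                         yH2O = c(0.70, 0.25, 0.05),
                         yNH3 = c(0.70, 0.25, 0.05),
                         y2 = c(0.20, 0.60, 0.20)),
                       level_intensity = rbind(c(1.8, 3.2),
                                               c(11, 19),
                                               c(36, 90)),
                       noise_mean = 30,
                       noise_intensity = c(0.5, 1.5),
                       mass_jitter_sd = 0.01) {
  stopifnot(all(detect >= 0 & detect <= 1),
            identical(sort(names(detect)), sort(ION_TYPES)))
  structure(as.list(environment()), class = "SimulationParams")
}

#' Noise-free simulation parameters
#'
#' Degenerate world for end-to-end recovery tests: every ion detected,
#' no m/z jitter, no noise peaks, deterministic bin-centre intensities.
#' The y series is strong and the b series medium, keeping the b/y
#' intensity asymmetry of tryptic CID spectra that lets the fragmentation
#' model orient the ladder (a perfectly symmetric spectrum is two-fold
#' ambiguous: the mirrored ladder reads the reversed peptide).
#'
#' @inheritParams sim_params
#' @return `SimulationParams`.
#' @export
sim_params_noise_free <- function(n_proteins = 500L) {
  sim_params(
    n_proteins = n_proteins,
    detect = c(b = 1, y = 1, a = 1, bH2O = 1, bNH3 = 1, b2 = 1,
               yH2O = 1, yNH3 = 1, y2 = 1),
    level_probs = list(
      b = c(0, 1, 0), y = c(0, 0, 1),
      a = c(1, 0, 0), bH2O = c(1, 0, 0), bNH3 = c(1, 0, 0),
      yH2O = c(1, 0, 0), yNH3 = c(1, 0, 0),
      b2 = c(0, 1, 0), y2 = c(0, 1, 0)),
    level_intensity = rbind(c(2, 2), c(10, 10), c(40, 40)),
    noise_mean = 0,
    mass_jitter_sd = 0
  )
}

#' Generate a random protein database
#'
#' Residue frequencies are uniform over the 20 standard residues except
#' that K and R are boosted to a combined 11%, giving tryptic peptides a
#' realistic mean length near 9 residues.
#'
#' @param params A `SimulationParams`.
#' @return data.frame as from [read_fasta()] (accessions `SYN0001`, ...).
#'   Generation consumes the R random number stream; seed it with
#'   [set.seed()] for reproducibility.
#' @export
generate_fasta <- function(params = sim_params()) {
  n <- params$n_proteins
  if (n == 0L) {
    return(data.frame(accession = character(), description = character(),
                      sequence = character()))
  }
  freqs <- stats::setNames(rep((1 - 0.11) / 18, 20), AA20)
  freqs["K"] <- 0.06; freqs["R"] <- 0.05
  lens <- pmax(60L, round(stats::rnorm(n, params$protein_length_mean,
                                       params$protein_length_sd)))
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE, prob = freqs), collapse = "")
  }, character(1))
  data.frame(
    accession = sprintf("SYN%04d", seq_len(n)),
    description = "synthetic protein",
    sequence = seqs
  )
}

#' Simulate an annotated tandem spectrum of a peptide
#'
#' Each theoretical fragment (nine ion types per cleavage) is detected with
#' its ion type's probability; detected fragments get an intensity drawn
#' from the discrete-level family (level from `level_probs`, value uniform
#' within that level's intensity band) and an m/z jittered by Gaussian
#' noise. Uniform noise peaks (Poisson count) are added over
#' `[100, precursor m/z * charge]`.
#'
#' @param peptide Residue string (length >= 2).
#' @param params A `SimulationParams`.
#' @param id Spectrum identifier.
#' @return List with `spectrum` (a [spectrum()]) and `annotation`
#'   (data.frame `mz`, `ion_type`, `ordinal`, `level`; one row per emitted
#'   fragment peak). Consumes the R random number stream.
#' @export
simulate_spectrum <- function(peptide, params = sim_params(), id = peptide) {
  theo <- theoretical_spectrum(peptide, params$charge)
  det_p <- params$detect[theo$ion_type]
  detected <- stats::runif(nrow(theo)) < det_p
  th <- theo[detected, , drop = FALSE]
  lev <- vapply(th$ion_type, function(ion) {
    sample.int(3L, 1L, prob = params$level_probs[[ion]])
  }, integer(1))
  inten <- stats::runif(nrow(th),
                        params$level_intensity[lev, 1],
                        params$level_intensity[lev, 2])
  mz <- th$mz + stats::rnorm(nrow(th), 0, params$mass_jitter_sd)
  prec_mz <- precursor_mz(peptide, params$charge)
  n_noise <- if (params$noise_mean > 0) stats::rpois(1L, params$noise_mean) else 0L
  if (n_noise > 0L) {
    nmz <- stats::runif(n_noise, 100, prec_mz * params$charge)
    ninten <- stats::runif(n_noise, params$noise_intensity[1],
                           params$noise_intensity[2])
  } else {
    nmz <- numeric(); ninten <- numeric()
  }
  sp <- spectrum(c(mz, nmz), c(inten, ninten), prec_mz, params$charge, id)
  list(
    spectrum = sp,
    annotation = data.frame(mz = mz, ion_type = th$ion_type,
                            ordinal = th$ordinal, level = lev),
    peptide = peptide
  )
}

#' Expected marginal level distribution of an ion type under the generator
#'
#' `P(level = 0) = 1 - detect`, `P(level = l) = detect * level_probs[l]`
#' for l in 1..3. Used as the reference when checking that training
#' recovers the generator's marginals.
#'
#' @param params A `SimulationParams`.
#' @param ion Ion type name.
#' @return Numeric vector of length 4 (levels 0..3) summing to 1.
#' @export
generator_marginal <- function(params, ion) {
  d <- params$detect[[ion]]
  c(1 - d, d * params$level_probs[[ion]])
}

#' Simulate a whole benchmark: database, peptides and annotated spectra
#'
#' Draws unique tryptic peptides (no missed cleavages, length 8-16 by
#' default) from a generated database and simulates one spectrum per
#' peptide.
#'
#' @param n_spectra Number of spectra.
#' @param params A `SimulationParams`.
#' @param seed Integer seed fixing every draw.
#' @param min_len,max_len Length bounds of sampled peptides.
#' @return List with `proteins`, `peptides` (character), `annotated` (list
#'   of [simulate_spectrum()] results), `truth` (data.frame `spectrum_id`,
#'   `peptide`).
#' @export
simulate_benchmark <- function(n_spectra = 100L, params = sim_params(),
                               seed = 1L, min_len = 8L, max_len = 16L) {
  set.seed(seed)
  proteins <- generate_fasta(params)
  idx <- build_peptide_index(proteins, missed_cleavages = 0L,
                             min_len = min_len, max_len = max_len)
  idx <- idx[!duplicated(idx$sequence), , drop = FALSE]
  if (nrow(idx) < n_spectra) {
    stop("database too small: only ", nrow(idx), " unique peptides")
  }
  pick <- sample.int(nrow(idx), n_spectra)
  peptides <- idx$sequence[pick]
  annotated <- lapply(seq_along(peptides), function(i) {
    simulate_spectrum(peptides[i], params, id = sprintf("sim%04d", i))
  })
  list(
    proteins = proteins,
    peptides = peptides,
    annotated = annotated,
    truth = data.frame(spectrum_id = sprintf("sim%04d", seq_along(peptides)),
                       peptide = peptides)
  )
}
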