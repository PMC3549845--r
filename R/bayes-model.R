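## Trainable Bayesian fragmentation network scoring spectrum-graph vertices
## by the likelihood ratio of "real cleavage" vs "random peak matches".
##
## Network topology (a declared design choice): the primary ions b+ and y+
## are parent nodes; a+, b2+, y2+ and the water/ammonia neutral-loss ions
## each have their primary ion as single parent. Every conditional table is
## additionally conditioned on the peak region R and on coarse chemical
## classes of the residues flanking the cleavage (NT, CT).

ION_TYPES <- c("b", "y", "a", "bH2O", "bNH3", "b2", "yH2O", "yNH3", "y2")
ION_PARENT <- c(b = NA, y = NA, a = "b", bH2O = "b", bNH3 = "b", b2 = "b",
                yH2O = "y", yNH3 = "y", y2 = "y")
N_LEVELS <- 4L
N_CLASSES <- 5L

#' Chemical class of a flanking residue
#'
#' Coarse classes used to condition the fragmentation model: 1 = K/R
#' (basic, mobile-proton sequestering), 2 = H, 3 = P (strong cleavage
#' enhancement N-terminal to proline), 4 = G, 5 = other. Unknown context
#' (e.g. when scoring de novo graph vertices) uses class 5.
#'
#' @param residue One-letter residue code(s).
#' @return Integer class in `1:5`.
#' @export
residue_class <- function(residue) {
  out <- rep(5L, length(residue))
  out[residue %in% c("K", "R")] <- 1L
  out[residue == "H"] <- 2L
  out[residue == "P"] <- 3L
  out[residue == "G"] <- 4L
  out
}

## m/z positions of all modelled ion types for a cleavage at prefix residue
## mass m, given the residue-mass total M_res. Doubly charged ions are only
## meaningful when the precursor charge is >= 2; they are still computed and
## simply never observed otherwise.
ion_mz_positions <- function(prefix_mass, M_res) {
  prefix_mass <- unname(prefix_mass)
  p <- MASS_CONST[["proton"]]; w <- MASS_CONST[["water"]]
  b <- prefix_mass + p
  y <- (M_res - prefix_mass) + w + p
  c(b = b, y = y,
    a = b - MASS_CONST[["co"]],
    bH2O = b - w, bNH3 = b - MASS_CONST[["ammonia"]],
    b2 = (prefix_mass + 2 * p) / 2,
    yH2O = y - w, yNH3 = y - MASS_CONST[["ammonia"]],
    y2 = (M_res - prefix_mass + w + 2 * p) / 2)
}

## Observed discrete level at each of a set of m/z positions: the maximum
## level of any kept peak within tolerance, 0 when none. The tolerance is a
## neutral-mass tolerance; doubly charged positions are matched at half of
## it in m/z space.
ION_CHARGE <- c(b = 1, y = 1, a = 1, bH2O = 1, bNH3 = 1, b2 = 2,
                yH2O = 1, yNH3 = 1, y2 = 2)

observed_levels <- function(positions, proc, tolerance) {
  keep <- which(proc$kept)
  mz <- proc$spectrum$peaks$mz[keep]
  lev <- proc$level[keep]
  tol <- tolerance / ION_CHARGE[names(positions)]
  out <- integer(length(positions))
  for (i in seq_along(positions)) {
    hit <- which(abs(mz - positions[i]) <= tol[i])
    if (length(hit) > 0L) out[i] <- max(lev[hit])
  }
  names(out) <- names(positions)
  out
}

new_cpt_model <- function() {
  tables <- list()
  for (ion in ION_TYPES) {
    if (is.na(ION_PARENT[[ion]])) {
      tables[[ion]] <- array(0, dim = c(N_LEVELS, N_CLASSES, N_CLASSES,
                                        N_CLASSES))
    } else {
      tables[[ion]] <- array(0, dim = c(N_LEVELS, N_LEVELS, N_CLASSES,
                                        N_CLASSES, N_CLASSES))
    }
  }
  structure(
    list(version = "1.0", counts = tables, tables = NULL, marginals = NULL,
         tolerance = NA_real_, trained = FALSE),
    class = "CPTModel"
  )
}

## Normalise count arrays (plus smoothing pseudo-counts) into conditional
## probability tables over the level dimension (dim 1).
normalize_cpts <- function(counts, smoothing) {
  lapply(counts, function(a) {
    a <- a + smoothing
    sums <- apply(a, seq_along(dim(a))[-1], sum)
    sweep(a, seq_along(dim(a))[-1], sums, "/")
  })
}

#' Train the Bayesian fragmentation model and the noise model
#'
#' For every annotated spectrum and every cleavage site of its peptide, the
#' observed discrete intensity levels of all nine modelled ion types are
#' recorded under their context (region R of the b-ion position, chemical
#' classes NT/CT of the flanking residues, and the observed level of the
#' parent ion for dependent ion types). Conditional probability tables are
#' smoothed relative frequencies (Laplace pseudo-count `smoothing` per
#' cell). The noise model estimates, per region, the probability of
#' observing each discrete level at a uniformly random m/z position; it is
#' computed analytically from the density of all kept peaks (each covering
#' a `2 * tolerance` window) -- under the random-match null the candidate
#' mass is wrong, so genuine fragment peaks are hit as coincidentally as
#' noise peaks.
#'
#' @param annotated List of `list(spectrum = <Spectrum>, peptide = <string>)`
#'   pairs (or a list with named elements `spectra` and `peptides`).
#' @param config Configuration list, see [default_config()]; uses the
#'   preprocessing keys and `fragment_tolerance`.
#' @param smoothing Positive pseudo-count.
#' @return List with elements `model` (a `CPTModel`) and `noise` (a
#'   `NoiseModel`: matrix `n_regions x 4` of level probabilities, rows sum
#'   to 1).
#' @export
train_model <- function(annotated, config = default_config(), smoothing = 1) {
  if (length(annotated) == 0L) stop("empty training set")
  stopifnot(smoothing > 0)
  tol <- config$fragment_tolerance
  model <- new_cpt_model()
  model$tolerance <- tol
  marg <- matrix(0, nrow = length(ION_TYPES), ncol = N_LEVELS,
                 dimnames = list(ION_TYPES, NULL))
  n_regions <- as.integer(config$n_regions)
  noise_density <- matrix(0, nrow = n_regions, ncol = N_LEVELS - 1L)
  n_spec <- 0L

  for (ann in annotated) {
    sp <- ann$spectrum; pep <- ann$peptide
    proc <- preprocess_spectrum(sp, config)
    M_res <- proc$residue_mass_total
    res <- strsplit(pep, "")[[1]]
    npos <- length(res) - 1L
    if (npos < 1L) next
    n_spec <- n_spec + 1L
    prefix <- cumsum(RESIDUE_MASS[res])[seq_len(npos)]
    upper <- proc$neutral_mass + MASS_CONST[["proton"]]
    for (j in seq_len(npos)) {
      pos <- ion_mz_positions(prefix[j], M_res)
      levs <- observed_levels(pos, proc, tol)
      R <- region_of_mz(pos[["b"]], upper, n_regions) + 1L
      NT <- residue_class(res[j]); CT <- residue_class(res[j + 1L])
      for (ion in ION_TYPES) {
        l <- levs[[ion]] + 1L
        marg[ion, l] <- marg[ion, l] + 1
        par <- ION_PARENT[[ion]]
        if (is.na(par)) {
          model$counts[[ion]][l, R, NT, CT] <-
            model$counts[[ion]][l, R, NT, CT] + 1
        } else {
          pl <- levs[[par]] + 1L
          model$counts[[ion]][l, pl, R, NT, CT] <-
            model$counts[[ion]][l, pl, R, NT, CT] + 1
        }
      }
    }
    # null model: probability that a uniformly random mass position falls
    # within tolerance of some kept peak of each level. Every kept peak
    # counts -- under the random-match hypothesis the candidate mass is
    # wrong, so hitting a genuine fragment peak is just as coincidental as
    # hitting a noise peak.
    keep <- which(proc$kept)
    mzk <- proc$spectrum$peaks$mz[keep]
    levk <- proc$level[keep]
    regk <- region_of_mz(mzk, upper, n_regions) + 1L
    width <- upper / n_regions
    for (i in seq_along(mzk)) {
      l <- levk[i]
      if (l >= 1L) {
        noise_density[regk[i], l] <-
          noise_density[regk[i], l] + (2 * tol) / width
      }
    }
  }
  if (n_spec == 0L) stop("no usable annotated spectra (peptides too short?)")

  model$tables <- normalize_cpts(model$counts, smoothing)
  model$marginals <- sweep(marg, 1, pmax(rowSums(marg), 1), "/")
  model$trained <- TRUE

  # per-region probability that a random position shows level l (noise);
  # level 0 takes the remaining mass, floored to keep all entries positive
  noise_p <- noise_density / n_spec
  floor_p <- 1e-3
  noise_p <- pmin(pmax(noise_p, floor_p), 0.45)
  p0 <- pmax(1 - rowSums(noise_p), floor_p)
  noise <- cbind(p0, noise_p)
  noise <- noise / rowSums(noise)
  colnames(noise) <- paste0("level", 0:3)
  class(noise) <- c("NoiseModel", class(noise))
  list(model = model, noise = noise)
}

#' @export
print.CPTModel <- function(x, ...) {
  cat(sprintf("CPTModel (v%s): %d ion types, %s\n", x$version,
              length(ION_TYPES),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Probability of the observed intensities under the real-fragment model
#'
#' Product over the nine modelled ion types of the conditional probability
#' of the observed discrete level at the m/z implied by the candidate
#' cleavage mass, given the parent ion's level, the peak region R and the
#' flanking-residue classes NT/CT. Positions without a kept peak within
#' tolerance contribute the "no signal" level.
#'
#' @param vertex_mass Prefix residue mass (Da) of the candidate cleavage.
#' @param proc A `ProcessedSpectrum`.
#' @param model Trained `CPTModel`.
#' @param nt,ct Flanking-residue classes in `1:5` (default 5 = unknown).
#' @return Probability in (0, 1].
#' @export
p_real <- function(vertex_mass, proc, model, nt = 5L, ct = 5L) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  pos <- ion_mz_positions(vertex_mass, proc$residue_mass_total)
  levs <- observed_levels(pos, proc, model$tolerance)
  upper <- proc$neutral_mass + MASS_CONST[["proton"]]
  R <- region_of_mz(pos[["b"]], upper, proc$n_regions) + 1L
  p <- 1
  for (ion in ION_TYPES) {
    l <- levs[[ion]] + 1L
    par <- ION_PARENT[[ion]]
    p <- p * if (is.na(par)) {
      model$tables[[ion]][l, R, nt, ct]
    } else {
      model$tables[[ion]][l, levs[[par]] + 1L, R, nt, ct]
    }
  }
  p
}

#' Probability of the observed intensities under the random-match model
#'
#' Product over the same nine ion-type m/z positions of the per-region
#' noise probability of the observed level.
#'
#' @inheritParams p_real
#' @param noise A `NoiseModel` (matrix regions x 4 levels).
#' @return Probability in (0, 1].
#' @export
p_random <- function(vertex_mass, proc, noise, tolerance) {
  pos <- ion_mz_positions(vertex_mass, proc$residue_mass_total)
  levs <- observed_levels(pos, proc, tolerance)
  upper <- proc$neutral_mass + MASS_CONST[["proton"]]
  regs <- region_of_mz(pos, upper, proc$n_regions) + 1L
  prod(noise[cbind(regs, levs + 1L)])
}

#' Likelihood-ratio score of a candidate cleavage mass
#'
#' `log(p_real / p_random)` (natural log); positive values indicate
#' fragment-like evidence at that mass.
#'
#' @inheritParams p_real
#' @param noise A `NoiseModel`.
#' @return Finite real score.
#' @export
score_vertex <- function(vertex_mass, proc, model, noise, nt = 5L, ct = 5L) {
  log(p_real(vertex_mass, proc, model, nt, ct)) -
    log(p_random(vertex_mass, proc, noise, model$tolerance))
}

#' Score every vertex of a spectrum graph
#'
#' Terminal vertices (source/sink) keep score 0; every peak-derived vertex
#' gets the likelihood-ratio score at its prefix mass.
#'
#' @param graph A `SpectrumGraph`.
#' @param proc The `ProcessedSpectrum` the graph was built from.
#' @param model Trained `CPTModel`.
#' @param noise `NoiseModel`.
#' @return The graph with `vertices$score` filled in.
#' @export
score_graph <- function(graph, proc, model, noise) {
  v <- graph$vertices
  mid <- which(!(v$interp %in% c("source", "sink")))
  v$score[mid] <- vapply(v$prefix_mass[mid], function(m) {
    score_vertex(m, proc, model, noise)
  }, numeric(1))
  graph$vertices <- v
  graph
}

#' Serialise a trained model (and noise model) to JSON
#'
#' Versioned plain-text representation: array dimensions and values are
#' stored explicitly so the tables round-trip exactly.
#'
#' @param fit List with `model` and `noise` as returned by [train_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  ser_array <- function(a) list(dim = dim(a), values = as.vector(a))
  obj <- list(
    format = "peptag-cpt-model",
    version = fit$model$version,
    tolerance = fit$model$tolerance,
    ion_types = ION_TYPES,
    parents = as.list(ION_PARENT),
    tables = lapply(fit$model$tables, ser_array),
    marginals = ser_array(fit$model$marginals),
    noise = ser_array(unclass(fit$noise))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialised by [write_model_json()]
#'
#' @param path Path to the JSON file.
#' @return List with `model` and `noise`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "peptag-cpt-model")) {
    stop("not a peptag model file: ", path)
  }
  de_array <- function(x) array(x$values, dim = x$dim)
  model <- new_cpt_model()
  model$tolerance <- obj$tolerance
  model$tables <- lapply(obj$tables, de_array)
  marg <- de_array(obj$marginals)
  dimnames(marg) <- list(ION_TYPES, NULL)
  model$marginals <- marg
  model$trained <- TRUE
  noise <- de_array(obj$noise)
  colnames(noise) <- paste0("level", 0:3)
  class(noise) <- c("NoiseModel", class(noise))
  list(model = model, noise = noise)
}
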