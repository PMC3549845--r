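# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive: brute force, direct enumeration,
# or a third-party implementation -- never the package's own code path.

# Exhaustively enumerate every source->sink path of a spectrum graph,
# drop paths violating antisymmetry (two vertices sharing an origin peak),
# and return the top k by (score desc, residue string asc). The reference
# for top_k_paths().
brute_force_paths <- function(graph, k) {
  v <- graph$vertices
  ed <- graph$edges
  osets <- graph$origin_sets
  if (is.null(osets)) {
    osets <- lapply(v$origin_peak, function(p) if (is.na(p)) integer() else p)
  }
  src <- match(graph$source_id, v$id)
  snk <- match(graph$sink_id, v$id)
  ef <- match(ed$from, v$id); et <- match(ed$to, v$id)
  results <- list()
  recurse <- function(path, peaks) {
    tip <- path[length(path)]
    if (tip == snk) {
      results[[length(results) + 1L]] <<- path
      return(invisible())
    }
    for (e in which(ef == tip)) {
      j <- et[e]
      pj <- osets[[j]]
      if (length(pj) > 0L && any(pj %in% peaks)) next
      recurse(c(path, j), c(peaks, pj))
    }
  }
  if (nrow(ed) > 0L) recurse(src, osets[[src]])
  if (length(results) == 0L) return(list())
  ekey <- paste(ef, et)
  paths <- lapply(results, function(p) {
    steps <- paste(p[-length(p)], p[-1L])
    list(vertices = v$id[p],
         residues = paste(ed$residue[match(steps, ekey)], collapse = ""),
         score = sum(v$score[p]))
  })
  sc <- vapply(paths, `[[`, numeric(1), "score")
  rs <- vapply(paths, `[[`, character(1), "residues")
  paths <- paths[order(-sc, rs)]
  paths[seq_len(min(k, length(paths)))]
}

# Random small DAG dressed up as a SpectrumGraph: vertices ordered by
# prefix mass, forward edges with random residue labels, random scores
# (both signs), and origin peaks shared between some vertex pairs so the
# antisymmetry constraint is exercised.
random_dag_graph <- function(n_vertices = sample(4:10, 1)) {
  n <- n_vertices
  pm <- sort(runif(n - 2L, 100, 900))
  vertices <- data.frame(
    id = seq_len(n),
    prefix_mass = c(0, pm, 1000),
    interp = c("source", sample(c("b", "y"), n - 2L, TRUE), "sink"),
    origin_peak = c(NA, sample.int(max(2L, (n - 2L) %/% 1L), n - 2L,
                                   replace = TRUE), NA),
    score = c(0, round(rnorm(n - 2L, 1, 2), 3), 0)
  )
  from <- integer(); to <- integer()
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < 0.45) { from <- c(from, i); to <- c(to, j) }
    }
  }
  edges <- data.frame(from = from, to = to,
                      residue = sample(c("A", "G", "S", "L", "K"),
                                       length(from), TRUE))
  structure(
    list(vertices = vertices, origin_sets = NULL, edges = edges,
         source_id = 1L, sink_id = n, neutral_mass = 1018.011,
         residue_mass_total = 1000, tolerance = 0.5),
    class = "SpectrumGraph"
  )
}

# Noise-free annotated spectrum of a peptide (b/y ladder world).
ladder_spectrum <- function(peptide, n_proteins = 20L) {
  simulate_spectrum(peptide, sim_params_noise_free(n_proteins), id = peptide)
}

# Random tryptic-looking peptide: interior residues from the 20 letters,
# C-terminal K or R.
random_peptide <- function(len = 10L) {
  paste(c(sample(names(peptag::RESIDUE_MASS), len - 1L, TRUE),
          sample(c("K", "R"), 1L)), collapse = "")
}

# One small trained model, shared across tests (training is seeded and
# deterministic; ~60 spectra keep it fast).
.fit_cache <- new.env(parent = emptyenv())
shared_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    .fit_cache$fit <- train_default_model(n_train = 60L, seed = 42L)
  }
  .fit_cache$fit
}

# Map I->L (and Q->K at the default 0.5 Da tolerance) the way graph edge
# labels collapse isobaric residues.
canonical_residues <- function(s) chartr("IQ", "LK", s)
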