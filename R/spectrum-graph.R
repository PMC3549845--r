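## Spectrum graph: vertices are prefix-mass interpretations of peaks (b and
## y), plus source (empty peptide) and sink (intact peptide); edges connect
## vertex pairs whose mass difference matches one residue mass.

## Single-residue edge label table: I/L are exactly isobaric and collapse to
## one label ("L"); Q/K collapse to "K" unless the fragment tolerance
## resolves their 0.036 Da difference.
edge_label_table <- function(tolerance) {
  m <- RESIDUE_MASS[setdiff(names(RESIDUE_MASS), "I")]  # I/L -> L
  if (tolerance >= 0.04) m <- m[setdiff(names(m), "Q")] # Q/K -> K
  m
}

#' Build the spectrum graph of a preprocessed spectrum
#'
#' Every kept peak contributes a vertex under the b-ion interpretation
#' (prefix mass `mz - proton`) and one under the y-ion interpretation
#' (prefix mass `M_res - (mz - proton - water)` where `M_res` is the
#' residue-mass total). A source vertex (prefix mass 0, empty peptide) and a
#' sink (prefix mass `M_res`, intact peptide) are added. Vertices closer
#' than the fragment tolerance are merged keeping the origin peak of
#' highest normalised intensity. Edges connect vertex pairs whose prefix
#' mass difference matches a single residue mass within tolerance
#' (optionally also residue minus water/ammonia degradation offsets).
#'
#' Each non-terminal vertex records its origin peak; a path using two
#' distinct vertices that interpret the same peak violates the antisymmetry
#' constraint enforced in [top_k_paths()].
#'
#' @param proc A `ProcessedSpectrum`.
#' @param tolerance Fragment mass tolerance in Dalton (> 0).
#' @param degradation_offsets Also add edges for residue mass minus water or
#'   ammonia (off by default).
#' @return Object of class `SpectrumGraph`: list with `vertices` (data.frame
#'   `id`, `prefix_mass`, `interp`, `origin_peak`, `score`), `edges`
#'   (data.frame `from`, `to`, `residue`), `source_id`, `sink_id`,
#'   `neutral_mass`, `residue_mass_total`, `tolerance`.
#' @export
build_graph <- function(proc, tolerance = 0.5, degradation_offsets = FALSE) {
  stopifnot(inherits(proc, "ProcessedSpectrum"))
  if (tolerance <= 0) stop("tolerance must be positive")
  M_res <- proc$residue_mass_total
  keep <- which(proc$kept)
  mz <- proc$spectrum$peaks$mz[keep]
  inten <- proc$norm_intensity[keep]
  p <- MASS_CONST[["proton"]]; w <- MASS_CONST[["water"]]

  pm_b <- mz - p
  pm_y <- M_res - (mz - p - w)
  cand <- data.frame(
    prefix_mass = c(pm_b, pm_y),
    interp = rep(c("b", "y"), each = length(keep)),
    origin_peak = c(keep, keep),
    intensity = c(inten, inten)
  )
  cand <- cand[cand$prefix_mass > tolerance &
                 cand$prefix_mass < M_res - tolerance, , drop = FALSE]
  cand <- cand[order(cand$prefix_mass, -cand$intensity), , drop = FALSE]

  # merge runs of vertices closer than the tolerance: the most intense
  # origin peak of each run fixes the representative mass, but the conflict
  # set retains every merged-in peak so the antisymmetry constraint can see
  # both interpretations of a peak (true vertex and its b/y mirror share
  # their origin peaks and can then never co-occur on one path)
  verts <- list(); origin_sets <- list(); k <- 0L
  i <- 1L
  while (i <= nrow(cand)) {
    j <- i
    while (j < nrow(cand) &&
           cand$prefix_mass[j + 1L] - cand$prefix_mass[j] < tolerance) {
      j <- j + 1L
    }
    run <- cand[i:j, , drop = FALSE]
    best <- which.max(run$intensity)
    k <- k + 1L
    verts[[k]] <- run[best, , drop = FALSE]
    origin_sets[[k]] <- sort(unique(run$origin_peak))
    i <- j + 1L
  }
  vdf <- if (k > 0L) do.call(rbind, verts) else cand
  vertices <- data.frame(
    id = seq_len(nrow(vdf) + 2L),
    prefix_mass = c(0, vdf$prefix_mass, M_res),
    interp = c("source", vdf$interp, "sink"),
    origin_peak = c(NA_integer_, vdf$origin_peak, NA_integer_),
    score = 0
  )
  origin_sets <- c(list(integer()), origin_sets, list(integer()))
  o <- order(vertices$prefix_mass)
  vertices <- vertices[o, , drop = FALSE]
  origin_sets <- origin_sets[o]
  vertices$id <- seq_len(nrow(vertices))
  rownames(vertices) <- NULL

  labels <- edge_label_table(tolerance)
  offsets <- labels
  if (degradation_offsets) {
    offsets <- c(offsets,
                 stats::setNames(labels - MASS_CONST[["water"]],
                                 paste0(names(labels), "-H2O")),
                 stats::setNames(labels - MASS_CONST[["ammonia"]],
                                 paste0(names(labels), "-NH3")))
  }

  pm <- vertices$prefix_mass
  n <- length(pm)
  from <- integer(); to <- integer(); residue <- character()
  lo <- min(offsets) - tolerance; hi <- max(offsets) + tolerance
  for (i in seq_len(n)) {
    js <- which(pm > pm[i] + lo & pm <= pm[i] + hi)
    for (j in js) {
      d <- pm[j] - pm[i]
      hit <- which(abs(offsets - d) <= tolerance)
      if (length(hit) > 0L) {
        # nearest offset wins when several match within tolerance
        best <- hit[which.min(abs(offsets[hit] - d))]
        from <- c(from, i); to <- c(to, j)
        residue <- c(residue, sub("-.*$", "", names(offsets)[best]))
      }
    }
  }
  structure(
    list(
      vertices = vertices,
      origin_sets = origin_sets,
      edges = data.frame(from = from, to = to, residue = residue),
      source_id = vertices$id[vertices$interp == "source"],
      sink_id = vertices$id[vertices$interp == "sink"],
      neutral_mass = proc$neutral_mass,
      residue_mass_total = M_res,
      tolerance = tolerance
    ),
    class = "SpectrumGraph"
  )
}

#' @export
print.SpectrumGraph <- function(x, ...) {
  cat(sprintf("SpectrumGraph: %d vertices, %d edges, tolerance %.3g Da\n",
              nrow(x$vertices), nrow(x$edges), x$tolerance))
  invisible(x)
}

#' Check that a spectrum graph is acyclic under the prefix-mass order
#'
#' Every edge must strictly increase prefix mass; with vertices sorted by
#' prefix mass this implies a DAG.
#'
#' @param graph A `SpectrumGraph`.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_graph <- function(graph) {
  pm <- graph$vertices$prefix_mass[match(c(graph$edges$from, graph$edges$to),
                                         graph$vertices$id)]
  n <- nrow(graph$edges)
  if (n > 0L && any(pm[seq_len(n)] >= pm[n + seq_len(n)])) {
    stop("graph has a non-increasing edge: not a DAG under prefix mass")
  }
  invisible(TRUE)
}

#' Export a small spectrum graph in DOT format (debugging aid)
#'
#' @param graph A `SpectrumGraph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
graph_to_dot <- function(graph, path) {
  v <- graph$vertices
  lines <- c("digraph spectrum {",
             sprintf('  v%d [label="%.2f/%s"];', v$id, v$prefix_mass, v$interp),
             sprintf('  v%d -> v%d [label="%s"];',
                     graph$edges$from, graph$edges$to, graph$edges$residue),
             "}")
  writeLines(lines, path)
  invisible(path)
}
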