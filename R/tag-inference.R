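## Sequence tag inference: enumerate top-k antisymmetric source->sink paths
## of the scored spectrum graph, align them progressively, and extract
## consensus sequence tags with flanking mass gaps.

#' Enumerate the top-k antisymmetric source-to-sink paths
#'
#' Exact lazy enumeration by best-first search over the DAG with an
#' admissible bound (exact best unconstrained suffix score from a reverse
#' topological sweep). The antisymmetry constraint — no two distinct
#' vertices interpreting the same peak on one path — is enforced during
#' expansion. Ties in total score are broken by lexicographic residue
#' string for determinism.
#'
#' @param graph A scored `SpectrumGraph`.
#' @param k Number of paths (>= 1).
#' @param max_pops Safety cap on search expansions.
#' @return List of paths, each `list(vertices, residues, score)`, in
#'   descending score; empty list when no source-to-sink path exists.
#' @export
top_k_paths <- function(graph, k = 20L, max_pops = 50000L) {
  stopifnot(k >= 1L)
  v <- graph$vertices
  n <- nrow(v)
  score <- v$score
  osets <- graph$origin_sets
  if (is.null(osets)) {  # graphs built by hand: one origin peak per vertex
    osets <- lapply(v$origin_peak, function(p) if (is.na(p)) integer() else p)
  }
  src <- match(graph$source_id, v$id)
  snk <- match(graph$sink_id, v$id)
  ed <- graph$edges
  if (nrow(ed) == 0L) return(list())
  ef <- match(ed$from, v$id); et <- match(ed$to, v$id)
  adj <- split(seq_len(nrow(ed)), ef)

  # best suffix score h[i]: score[i] + max over children of h[child]
  ord <- order(v$prefix_mass, decreasing = TRUE)
  h <- rep(-Inf, n); h[snk] <- score[snk]
  for (i in ord) {
    if (i == snk) next
    ei <- adj[[as.character(i)]]
    if (is.null(ei)) next
    best <- suppressWarnings(max(h[et[ei]]))
    if (is.finite(best)) h[i] <- score[i] + best
  }
  if (!is.finite(h[src])) return(list())

  # frontier entries: list(vs, peaks, g (sum of scores incl last), f bound)
  frontier <- list(list(vs = src, peaks = integer(), g = score[src],
                        f = h[src]))
  done <- list()
  pops <- 0L
  repeat {
    if (length(frontier) == 0L || pops >= max_pops) break
    fs <- vapply(frontier, `[[`, numeric(1), "f")
    if (length(done) >= k) {
      kth <- sort(vapply(done, `[[`, numeric(1), "score"),
                  decreasing = TRUE)[k]
      if (max(fs) < kth - 1e-12) break
    }
    best <- which.max(fs)
    cur <- frontier[[best]]
    frontier[[best]] <- NULL
    pops <- pops + 1L
    tip <- cur$vs[length(cur$vs)]
    if (tip == snk) {
      done[[length(done) + 1L]] <- list(vertices = v$id[cur$vs],
                                        score = cur$g, vs = cur$vs)
      next
    }
    ei <- adj[[as.character(tip)]]
    if (is.null(ei)) next
    for (e in ei) {
      j <- et[e]
      if (!is.finite(h[j])) next
      pj <- osets[[j]]
      if (length(pj) > 0L && any(pj %in% cur$peaks)) next  # antisymmetry
      frontier[[length(frontier) + 1L]] <- list(
        vs = c(cur$vs, j),
        peaks = c(cur$peaks, pj),
        g = cur$g + score[j],
        f = cur$g + h[j]
      )
    }
  }
  if (length(done) == 0L) return(list())

  # residues along each path from the edge labels
  elab <- ed$residue
  ekey <- paste(ef, et)
  paths <- lapply(done, function(d) {
    steps <- paste(d$vs[-length(d$vs)], d$vs[-1L])
    resid <- elab[match(steps, ekey)]
    list(vertices = d$vertices, residues = paste(resid, collapse = ""),
         score = d$score,
         prefix_masses = v$prefix_mass[d$vs])
  })
  sc <- vapply(paths, `[[`, numeric(1), "score")
  rs <- vapply(paths, `[[`, character(1), "residues")
  paths <- paths[order(-sc, rs)]
  paths[seq_len(min(k, length(paths)))]
}

## ---------------------------------------------------------------------------
## Progressive multiple alignment of candidate residue strings
## (match +1, mismatch -1, gap -2; guide order = descending path score).

## Global pairwise alignment of a sequence against a profile (list of
## aligned rows as character matrices). Returns the expanded alignment.
align_seq_to_profile <- function(aln, seq_chars, match = 1, mismatch = -1,
                                 gap = -2) {
  ncol_a <- ncol(aln); n <- length(seq_chars)
  # column consensus (majority non-gap residue) used for scoring
  cons <- apply(aln, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("-")
    names(sort(table(col), decreasing = TRUE))[1]
  })
  S <- matrix(0, n + 1L, ncol_a + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:ncol_a)
  B <- matrix(0L, n + 1L, ncol_a + 1L)  # 1 diag, 2 up (gap in profile), 3 left
  B[, 1L] <- 2L; B[1L, ] <- 3L; B[1L, 1L] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(ncol_a)) {
      m <- S[i, j] + if (cons[j] == "-") gap else
        if (seq_chars[i] == cons[j]) match else mismatch
      up <- S[i, j + 1L] + gap
      lf <- S[i + 1L, j] + gap
      best <- max(m, up, lf)
      S[i + 1L, j + 1L] <- best
      B[i + 1L, j + 1L] <- if (best == m) 1L else if (best == up) 2L else 3L
    }
  }
  # traceback
  i <- n; j <- ncol_a
  new_cols <- list()
  while (i > 0L || j > 0L) {
    d <- B[i + 1L, j + 1L]
    if (d == 1L) {
      new_cols[[length(new_cols) + 1L]] <- c(aln[, j], seq_chars[i])
      i <- i - 1L; j <- j - 1L
    } else if (d == 2L) {
      new_cols[[length(new_cols) + 1L]] <- c(rep("-", nrow(aln)), seq_chars[i])
      i <- i - 1L
    } else {
      new_cols[[length(new_cols) + 1L]] <- c(aln[, j], "-")
      j <- j - 1L
    }
  }
  do.call(cbind, rev(new_cols))
}

#' Progressive multiple alignment of candidate paths
#'
#' Rows are aligned in guide order (descending path score, i.e. the input
#' order from [top_k_paths()]); each new sequence is aligned globally to the
#' growing profile with match +1, mismatch -1, gap -2, scoring against the
#' column majority residue.
#'
#' @param paths List of candidate paths from [top_k_paths()] (>= 1).
#' @return Character matrix (rows = paths, columns = alignment columns) with
#'   `"-"` as gap symbol; attribute `paths` keeps the input.
#' @export
align_candidates <- function(paths) {
  stopifnot(length(paths) >= 1L)
  seqs <- lapply(paths, function(p) strsplit(p$residues, "")[[1]])
  aln <- matrix(seqs[[1]], nrow = 1L)
  for (i in seq_along(seqs)[-1L]) {
    aln <- align_seq_to_profile(aln, seqs[[i]])
  }
  rownames(aln) <- NULL
  attr(aln, "paths") <- paths
  aln
}

## residue index per row/column of an alignment (NA at gaps)
alignment_residue_index <- function(aln) {
  t(apply(aln, 1, function(row) {
    idx <- cumsum(row != "-")
    idx[row == "-"] <- NA_integer_
    idx
  }))
}

#' Extract consensus sequence tags from an alignment
#'
#' Every alignment row (candidate path) proposes tags: a column supports a
#' row when the rows carrying the same residue in that column hold at least
#' `min_support_fraction` of the total path weight. Rows vote with weight
#' `exp((score - best_score) / temperature)`: path scores are sums of
#' log-likelihood-ratio vertex scores, so this is a tempered posterior over
#' the candidate interpretations -- a swarm of low-scoring variants cannot
#' outvote a clearly better family, while genuine near-ties dilute support
#' and mark the region as ambiguous. Maximal runs of supported columns become tags,
#' so every tag is by construction a substring of one candidate path, with
#' flanking mass gaps taken from that path's vertex masses. Runs longer
#' than `max_len` are clipped to the `max_len` consecutive columns of
#' highest mean vertex score; runs shorter than `min_len` are discarded;
#' duplicate (tag, prefix gap) proposals from different rows are merged
#' keeping the best score. Gaps satisfy `prefix_gap + sum(residue masses)
#' + suffix_gap = precursor neutral mass` (the suffix gap absorbs the
#' water of the intact peptide).
#'
#' @param aln Alignment matrix from [align_candidates()].
#' @param graph The scored `SpectrumGraph` (for vertex scores and masses).
#' @param min_len,max_len Tag length bounds.
#' @param min_support_fraction Minimum weighted fraction of rows supporting
#'   a column.
#' @param temperature Softmax temperature of the path-score weighting.
#' @return data.frame with columns `tag`, `prefix_gap`, `suffix_gap`,
#'   `score`, `support` (unweighted count of agreeing rows), sorted by
#'   score descending. Zero rows when nothing qualifies.
#' @export
extract_tags <- function(aln, graph, min_len = 3L, max_len = 7L,
                         min_support_fraction = 0.5, temperature = 10) {
  stopifnot(min_len >= 1L, min_len <= max_len, temperature > 0)
  paths <- attr(aln, "paths")
  nr <- nrow(aln); nc <- ncol(aln)
  ridx <- alignment_residue_index(aln)
  M <- graph$neutral_mass
  scores <- vapply(paths, `[[`, numeric(1), "score")
  w <- exp((scores - max(scores)) / temperature)
  w_total <- sum(w)
  out <- list()
  for (r in seq_len(nr)) {
    cons <- aln[r, ]
    agree <- aln == matrix(cons, nr, nc, byrow = TRUE)
    support <- colSums(agree)
    w_support <- colSums(agree * w)
    ok <- cons != "-" & w_support / w_total >= min_support_fraction
    if (!any(ok)) next
    p <- paths[[r]]
    vs <- match(p$vertices, graph$vertices$id)
    col_score <- rep(NA_real_, nc)
    for (j in which(ok)) {
      ri <- ridx[r, j]
      col_score[j] <- (graph$vertices$score[vs[ri]] +
                         graph$vertices$score[vs[ri + 1L]]) / 2
    }
    runs <- rle(as.vector(ok))
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (rn in which(runs$values)) {
      a <- starts[rn]; b <- ends[rn]
      if (b - a + 1L < min_len) next
      if (b - a + 1L > max_len) {
        # best max_len-window by mean column score
        ws <- a:(b - max_len + 1L)
        means <- vapply(ws, function(s)
          mean(col_score[s:(s + max_len - 1L)]), numeric(1))
        a <- ws[which.max(means)]
        b <- a + max_len - 1L
      }
      i0 <- ridx[r, a]; i1 <- ridx[r, b]
      out[[length(out) + 1L]] <- data.frame(
        tag = paste(cons[a:b], collapse = ""),
        prefix_gap = p$prefix_masses[i0],
        suffix_gap = M - p$prefix_masses[i1 + 1L],
        score = mean(col_score[a:b]),
        support = min(support[a:b])
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tag = character(), prefix_gap = numeric(),
                      suffix_gap = numeric(), score = numeric(),
                      support = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$score, res$tag), , drop = FALSE]
  res <- res[!duplicated(paste(res$tag, round(res$prefix_gap, 2))), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Infer sequence tags for one spectrum
#'
#' Convenience wrapper: preprocess, build and score the graph, enumerate
#' top-k paths, align, and extract tags.
#'
#' @param spec A [spectrum()].
#' @param model,noise Trained model pair from [train_model()].
#' @param config Configuration list ([default_config()]).
#' @return data.frame of tags as from [extract_tags()] (zero rows when the
#'   spectrum yields none).
#' @export
infer_tags <- function(spec, model, noise, config = default_config()) {
  proc <- preprocess_spectrum(spec, config)
  if (sum(proc$kept) == 0L) return(extract_tags_empty())
  graph <- build_graph(proc, config$fragment_tolerance,
                       config$degradation_offsets)
  graph <- score_graph(graph, proc, model, noise)
  paths <- top_k_paths(graph, config$top_k)
  if (length(paths) == 0L) return(extract_tags_empty())
  aln <- align_candidates(paths)
  extract_tags(aln, graph, config$tag_min_len, config$tag_max_len,
               config$tag_min_support, config$tag_support_temperature)
}

extract_tags_empty <- function() {
  data.frame(tag = character(), prefix_gap = numeric(),
             suffix_gap = numeric(), score = numeric(), support = integer())
}
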