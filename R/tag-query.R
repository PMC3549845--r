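## Error-tolerant sequence-tag query against the digested database:
## Smith-Waterman local alignment with affine gaps over a BLOSUM62 matrix
## tailored to mass spectrometry.

MATRIX_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
  "P", "S", "T", "W", "Y", "V", "X", "^"
)

#' Build the MS-tailored substitution matrix
#'
#' Starts from the standard BLOSUM62 matrix (as shipped with Biostrings)
#' and applies three modifications for scoring de novo sequence tags:
#'
#' * the isobaric pairs L/I (identical mass) and Q/K (0.036 Da apart) are
#'   made fully interchangeable — their mutual and diagonal scores are the
#'   average of the two original diagonal entries, and their rows/columns
#'   against every other residue are averaged likewise;
#' * the undefined residue `X` scores 0 against everything, so incomplete
#'   or erroneous tag positions neither reward nor punish;
#' * a cleavage-anchor symbol `^` (a tryptic cleavage site preceding the
#'   peptide) scores the average of the original K and R diagonal entries
#'   against K, R (and Q, K's isobaric twin, so Q/K interchangeability
#'   stays exact) and itself, and 0 otherwise.
#'
#' Because Q and K are fully interchangeable, reserving the K code for the
#' C-terminal lysine of tryptic peptides is implicit: an internal K scores
#' identically whether written K or Q.
#'
#' @param gap_open,gap_extend Affine gap penalties (positive costs; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return Object of class `SubstitutionMatrix`: list with `matrix` (22 x 22
#'   symmetric numeric), `gap_open`, `gap_extend`.
#' @export
build_matrix <- function(gap_open = 11, gap_extend = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  aa <- setdiff(MATRIX_ALPHABET, c("X", "^"))
  M <- matrix(0, 22L, 22L, dimnames = list(MATRIX_ALPHABET, MATRIX_ALPHABET))
  M[aa, aa] <- B[aa, aa]
  for (pair in list(c("L", "I"), c("Q", "K"))) {
    a <- pair[1]; b <- pair[2]
    diag_avg <- (M[a, a] + M[b, b]) / 2
    others <- setdiff(aa, pair)
    row_avg <- (M[a, others] + M[b, others]) / 2
    M[a, others] <- row_avg; M[b, others] <- row_avg
    M[others, a] <- row_avg; M[others, b] <- row_avg
    M[a, a] <- diag_avg; M[b, b] <- diag_avg
    M[a, b] <- diag_avg; M[b, a] <- diag_avg
  }
  M["X", ] <- 0; M[, "X"] <- 0
  # Q included alongside K so that Q/K interchangeability stays exact
  anchor <- (B["K", "K"] + B["R", "R"]) / 2
  M["^", ] <- 0; M[, "^"] <- 0
  M["^", c("K", "Q", "R", "^")] <- anchor
  M[c("K", "Q", "R"), "^"] <- anchor
  structure(list(matrix = M, gap_open = gap_open, gap_extend = gap_extend),
            class = "SubstitutionMatrix")
}

#' Smith-Waterman local alignment score with affine gaps
#'
#' Standard Gotoh recursion; the empty alignment scores 0, so the result is
#' always non-negative. Only the optimal score and its end coordinates are
#' returned (tags are short; the aligned span is recovered from the score
#' matrix).
#'
#' @param query,subject Character scalars over the matrix alphabet.
#' @param submat A `SubstitutionMatrix` from [build_matrix()].
#' @return List with `score`, `query_span`, `subject_span` (1-based
#'   inclusive `c(start, end)`; `c(0, 0)` for an empty alignment).
#' @export
local_align <- function(query, subject, submat) {
  M <- submat$matrix
  go <- submat$gap_open; ge <- submat$gap_extend
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  nq <- length(q); ns <- length(s)
  qi <- match(q, rownames(M)); si <- match(s, colnames(M))
  if (anyNA(qi) || anyNA(si)) stop("sequence contains letters outside the matrix alphabet")
  H <- matrix(0, nq + 1L, ns + 1L)
  E <- matrix(-Inf, nq + 1L, ns + 1L)  # gap in query (horizontal)
  F <- matrix(-Inf, nq + 1L, ns + 1L)  # gap in subject (vertical)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(nq)) {
    for (j in seq_len(ns)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - go - ge, E[i + 1L, j] - ge)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - go - ge, F[i, j + 1L] - ge)
      d <- H[i, j] + M[qi[i], si[j]]
      h <- max(0, d, E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) {
    return(list(score = 0, query_span = c(0L, 0L), subject_span = c(0L, 0L)))
  }
  # walk back to the start of the optimal local path for the spans
  i <- bi; j <- bj
  while (i > 1L && j > 1L && H[i, j] > 0 &&
         H[i + 1L, j + 1L] == H[i, j] + M[qi[i], si[j]]) {
    i <- i - 1L; j <- j - 1L
  }
  list(score = best, query_span = c(i, bi), subject_span = c(j, bj))
}

#' Query sequence tags against a peptide index
#'
#' For every tag, candidate peptides are pre-filtered by the precursor mass
#' the tag implies (`prefix_gap + tag residues + suffix_gap`) within
#' `mass_window` Da (peptides of unknown mass, i.e. containing `X`, always
#' pass; set `mass_window = Inf` for an open search). Each candidate is
#' aligned locally to the tag; hits from multiple tags of one spectrum are
#' merged per peptide keeping the maximum similarity score Ss, ranked by
#' Ss descending (ties by peptide string) and capped at `max_hits`.
#'
#' When a tag's prefix gap is below the fragment tolerance (the tag starts
#' at the peptide N-terminus) the cleavage-anchor symbol `^` is prepended to
#' both tag and peptide so that a correct N-terminal placement is rewarded.
#'
#' @param tags data.frame from [extract_tags()] (columns `tag`,
#'   `prefix_gap`, `suffix_gap`, `score`).
#' @param index Peptide index from [build_peptide_index()].
#' @param submat `SubstitutionMatrix` from [build_matrix()].
#' @param spectrum_neutral_mass Neutral precursor mass (Da) of the spectrum
#'   the tags came from.
#' @param max_hits Cap on hits per spectrum (>= 1).
#' @param mass_window Precursor mass prefilter half-width (Da).
#' @param fragment_tolerance Tolerance used for the N-terminal anchor test.
#' @return data.frame with columns `peptide`, `parent_accession`,
#'   `is_decoy`, `mass`, `Ss`, `tag`, `tag_score` (best tag for that
#'   peptide). Zero rows for an empty tag list.
#' @export
query_tags <- function(tags, index, submat, spectrum_neutral_mass,
                       max_hits = 50L, mass_window = 2.5,
                       fragment_tolerance = 0.5) {
  stopifnot(max_hits >= 1L)
  empty <- data.frame(peptide = character(), parent_accession = character(),
                      is_decoy = logical(), mass = numeric(), Ss = numeric(),
                      tag = character(), tag_score = numeric())
  if (is.null(tags) || nrow(tags) == 0L || nrow(index) == 0L) return(empty)
  in_window <- is.na(index$mass) |
    abs(index$mass - spectrum_neutral_mass) <= mass_window
  cand <- index[in_window, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand_idx <- integer(); ss <- numeric(); tag_of <- integer()
  for (t in seq_len(nrow(tags))) {
    tag <- tags$tag[t]
    anchored <- tags$prefix_gap[t] <= fragment_tolerance
    qseq <- if (anchored) paste0("^", tag) else tag
    for (i in seq_len(nrow(cand))) {
      sseq <- if (anchored) paste0("^", cand$sequence[i]) else cand$sequence[i]
      sc <- local_align(qseq, sseq, submat)$score
      if (sc <= 0) next
      cand_idx <- c(cand_idx, i); ss <- c(ss, sc); tag_of <- c(tag_of, t)
    }
  }
  if (length(cand_idx) == 0L) return(empty)
  h <- data.frame(
    peptide = cand$sequence[cand_idx],
    parent_accession = cand$parent_accession[cand_idx],
    is_decoy = cand$is_decoy[cand_idx],
    mass = cand$mass[cand_idx],
    Ss = ss,
    tag = tags$tag[tag_of],
    tag_score = tags$score[tag_of]
  )
  # merge per peptide, keep max Ss (and the tag achieving it)
  h <- h[order(-h$Ss, h$peptide), , drop = FALSE]
  h <- h[!duplicated(paste(h$peptide, h$parent_accession)), , drop = FALSE]
  h <- h[seq_len(min(nrow(h), max_hits)), , drop = FALSE]
  rownames(h) <- NULL
  h
}
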