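## Final scoring: combine the similarity score Ss and the correlation score
## Sc into one score S per candidate, delta score D, per-spectrum ranking,
## target-decoy FDR and the sequence-inference accuracy metric.

#' Combine normalised Ss and Sc into the final score S
#'
#' Both inputs must be normalised to `[0, 1]` per spectrum (min-max over
#' that spectrum's candidate set; see [rank_and_report()]). The default
#' `weighted_sum` mode computes `S = W * Ss + (1 - W) * Sc`. The
#' `literal_product` mode computes `S = W * Ss * (1 - W) * Sc`; in that
#' form `W (1 - W)` is a common factor of every candidate so the weight
#' cannot change relative ranking — which is why the weighted sum is the
#' default (see the methods vignette).
#'
#' @param Ss_norm,Sc_norm Normalised scores in `[0, 1]`.
#' @param W De novo weight in `[0, 1]`.
#' @param mode `"weighted_sum"` (default) or `"literal_product"`.
#' @return Final score S (vectorised over the inputs).
#' @export
final_score <- function(Ss_norm, Sc_norm, W = 0.5, mode = "weighted_sum") {
  if (W < 0 || W > 1) stop("W must be in [0, 1]")
  switch(mode,
    weighted_sum = W * Ss_norm + (1 - W) * Sc_norm,
    literal_product = W * Ss_norm * (1 - W) * Sc_norm,
    stop("unknown mode: ", mode)
  )
}

#' Delta score D of a spectrum's candidate list
#'
#' `D = (S_max - S_2nd) / S_max`, the relative margin of the best candidate
#' over the runner-up. With a single candidate, `S_2nd` is treated as 0 and
#' `D = 1`. When `S_max <= 0` the delta is undefined and `NA` is returned.
#'
#' @param scores Numeric vector of final scores (any order).
#' @return D in `[0, 1]`, or `NA` when undefined.
#' @export
delta_score <- function(scores) {
  if (length(scores) == 0L) return(NA_real_)
  s <- sort(scores, decreasing = TRUE)
  if (s[1] <= 0) return(NA_real_)
  s2 <- if (length(s) >= 2L) s[2] else 0
  (s[1] - s2) / s[1]
}

## min-max normalisation over a candidate set; a degenerate set (all equal)
## maps to 1 so a lone candidate keeps full weight
minmax_norm <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(1, length(x)))
  (x - r[1]) / diff(r)
}

#' Score, rank and report the candidates of one spectrum
#'
#' Normalises Ss and Sc_log by min-max over the candidate set, combines
#' them with [final_score()], computes the delta score over distinct
#' peptides, and ranks by S descending with ties broken by Sc_log then by
#' lexicographic peptide string.
#'
#' @param hits data.frame with columns `peptide`, `parent_accession`,
#'   `is_decoy`, `Ss`, `Sc_log`, `tag` (as assembled by [identify_spectra()]).
#' @param spectrum_id Identifier copied into every row.
#' @param W,mode Passed to [final_score()].
#' @return data.frame with the input columns plus `spectrum_id`, `S`, `D`
#'   (same value on every row), `rank`. Zero rows in, zero rows out.
#' @export
rank_and_report <- function(hits, spectrum_id, W = 0.5,
                            mode = "weighted_sum") {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(psm_empty())
  }
  hits$Ss_norm <- minmax_norm(hits$Ss)
  hits$Sc_norm <- minmax_norm(hits$Sc_log)
  hits$S <- final_score(hits$Ss_norm, hits$Sc_norm, W, mode)
  # delta over distinct peptides (shared peptides across proteins collapse)
  per_pep <- tapply(hits$S, hits$peptide, max)
  D <- delta_score(as.numeric(per_pep))
  o <- order(-hits$S, -hits$Sc_log, hits$peptide)
  hits <- hits[o, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  hits$D <- D
  hits$spectrum_id <- spectrum_id
  rownames(hits) <- NULL
  hits[, c("spectrum_id", "peptide", "parent_accession", "is_decoy",
           "tag", "Ss", "Sc_log", "S", "D", "rank")]
}

psm_empty <- function() {
  data.frame(spectrum_id = character(), peptide = character(),
             parent_accession = character(), is_decoy = logical(),
             tag = character(), Ss = numeric(), Sc_log = numeric(),
             S = numeric(), D = numeric(), rank = integer())
}

#' Target-decoy FDR at a score threshold
#'
#' `FDR(threshold) = #decoy / #target` among rank-1 PSMs with `S >=
#' threshold`, assuming the database was searched with an equal-size
#' reversed-decoy complement. Undefined (NA) when no targets pass.
#'
#' @param psms data.frame of rank-1 PSMs with columns `S`, `is_decoy`.
#' @param threshold Score threshold.
#' @return FDR estimate in `[0, Inf)`, or `NA`.
#' @export
estimate_fdr <- function(psms, threshold) {
  above <- psms$S >= threshold
  n_decoy <- sum(above & psms$is_decoy)
  n_target <- sum(above & !psms$is_decoy)
  if (n_target == 0L) return(NA_real_)
  n_decoy / n_target
}

#' q-values for rank-1 PSMs by target-decoy counting
#'
#' The raw FDR at each PSM's score is transformed by a cumulative minimum
#' from the lowest score upward, making the result monotone non-increasing
#' in the score.
#'
#' @param psms data.frame of rank-1 PSMs with columns `S`, `is_decoy`.
#' @return Numeric vector of q-values aligned with the input rows.
#' @export
compute_qvalues <- function(psms) {
  n <- nrow(psms)
  if (n == 0L) return(numeric(0))
  o <- order(psms$S, decreasing = TRUE)
  dec <- cumsum(psms$is_decoy[o])
  tar <- cumsum(!psms$is_decoy[o])
  fdr <- ifelse(tar == 0L, Inf, dec / tar)
  q <- rev(cummin(rev(fdr)))
  out <- numeric(n)
  out[o] <- q
  out
}

#' Sequence-inference accuracy of a de novo call
#'
#' The fraction of identified residues that are correct: an inferred
#' residue counts as correct when the true peptide has, at the position
#' implied by the residue's prefix mass (within `tolerance`), a matching
#' residue letter. L/I are always equivalent; Q/K are equivalent unless the
#' tolerance resolves their 0.036 Da mass difference.
#'
#' @param inferred Inferred residue string.
#' @param prefix_masses Numeric vector, length `nchar(inferred)`: prefix
#'   residue mass (Da) before each inferred residue. Defaults to the masses
#'   implied by the inferred letters themselves (pure de novo reading).
#' @param truth True peptide string.
#' @param tolerance Fragment mass tolerance (Da).
#' @return Accuracy in `[0, 1]`.
#' @export
sequence_accuracy <- function(inferred, truth,
                              prefix_masses = NULL, tolerance = 0.5) {
  stopifnot(nzchar(inferred), nzchar(truth))
  inf_res <- strsplit(inferred, "")[[1]]
  if (is.null(prefix_masses)) {
    prefix_masses <- c(0, cumsum(RESIDUE_MASS[inf_res]))[seq_along(inf_res)]
  }
  stopifnot(length(prefix_masses) == length(inf_res))
  tru_res <- strsplit(truth, "")[[1]]
  tru_prefix <- c(0, cumsum(RESIDUE_MASS[tru_res]))[seq_along(tru_res)]
  equivalent <- function(a, b) {
    canon <- function(x) {
      x[x == "I"] <- "L"
      if (tolerance >= 0.04) x[x == "Q"] <- "K"
      x
    }
    canon(a) == canon(b)
  }
  correct <- 0L
  for (i in seq_along(inf_res)) {
    j <- which(abs(tru_prefix - prefix_masses[i]) <= tolerance)
    if (length(j) > 0L) {
      j <- j[which.min(abs(tru_prefix[j] - prefix_masses[i]))]
      if (equivalent(inf_res[i], tru_res[j])) correct <- correct + 1L
    }
  }
  correct / length(inf_res)
}

#' Write a PSM table as tab-separated text
#'
#' Columns: `spectrum_id`, `peptide`, `parent_accession`, `is_decoy`,
#' `tag`, `Ss`, `Sc_log`, `S`, `D`, `rank` (and `q_value` when present).
#' One header line; `NA` written as `NA`.
#'
#' @param psms PSM data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PSM table written by [write_psm_table()]
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_psm_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}
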