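## Theoretical fragmentation (nine ion types with empirical intensities) and
## dot-product correlation scoring against the experimental spectrum.

## empirical relative intensities of the nine modelled ion types
ION_INTENSITY <- c(b = 100, y = 100, a = 20, bH2O = 20, bNH3 = 20,
                   yH2O = 20, yNH3 = 20, b2 = 50, y2 = 50)

#' Theoretical spectrum of a peptide
#'
#' Enumerates, for every cleavage position, the nine modelled ion types
#' with their empirical intensities: b+ and y+ at 100, b2+ and y2+ at 50,
#' and a+, b+-H2O, b+-NH3, y+-H2O, y+-NH3 at 20. Doubly charged fragments
#' are only emitted when `charge >= 2`.
#'
#' @param peptide Residue string of length >= 2.
#' @param charge Precursor charge (>= 1).
#' @return data.frame with columns `mz`, `intensity`, `ion_type`, `ordinal`
#'   (cleavage position, 1-based from the N-terminus).
#' @export
#' @examples
#' nrow(theoretical_spectrum("PEPTIDEK", 2))  # 9 * 7
theoretical_spectrum <- function(peptide, charge = 2L) {
  if (nchar(peptide) < 2L) stop("peptide must have at least 2 residues")
  stopifnot(charge >= 1L)
  res <- strsplit(peptide, "")[[1]]
  M_res <- residue_sum(peptide)
  n <- length(res) - 1L
  prefix <- cumsum(RESIDUE_MASS[res])[seq_len(n)]
  types <- names(ION_INTENSITY)
  if (charge < 2L) types <- setdiff(types, c("b2", "y2"))
  out <- do.call(rbind, lapply(seq_len(n), function(j) {
    pos <- ion_mz_positions(prefix[j], M_res)
    data.frame(mz = unname(pos[types]), intensity = unname(ION_INTENSITY[types]),
               ion_type = types, ordinal = j)
  }))
  rownames(out) <- NULL
  out
}

#' Match an experimental spectrum to a theoretical spectrum
#'
#' Greedy closest-pair-first assignment: all (theoretical, experimental)
#' pairs within `tolerance` are ranked by absolute mass error and assigned
#' in that order, each peak (on either side) used at most once. The aligned
#' experimental intensity vector `I` carries the continuous normalised
#' intensity of the matched kept peak and 0 where no fragment ion is
#' observed. `Nb` and `Ny` count assigned primary-series ions: the number
#' of distinct cleavage positions with a matched b-series (b+, b2+) or
#' y-series (y+, y2+) ion respectively; neutral losses and a+ are matched
#' but not counted.
#'
#' @param proc A `ProcessedSpectrum` (only kept peaks participate).
#' @param theo Theoretical spectrum from [theoretical_spectrum()].
#' @param tolerance Fragment mass tolerance in Dalton (> 0).
#' @return Object of class `MatchResult`: list with `I` (numeric, length
#'   `nrow(theo)`), `P` (theoretical intensities), `Nb`, `Ny`, `matches`
#'   (data.frame `theo_idx`, `peak_idx`, `error`).
#' @export
match_ions <- function(proc, theo, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  keep <- which(proc$kept)
  mz <- proc$spectrum$peaks$mz[keep]
  inten <- proc$norm_intensity[keep]
  nt <- nrow(theo)
  I <- numeric(nt)
  ti <- integer(); pi <- integer(); err <- numeric()
  if (length(mz) > 0L && nt > 0L) {
    pairs <- list(); np <- 0L
    for (i in seq_len(nt)) {
      hit <- which(abs(mz - theo$mz[i]) <= tolerance)
      for (h in hit) {
        np <- np + 1L
        pairs[[np]] <- c(i, h, abs(mz[h] - theo$mz[i]))
      }
    }
    if (np > 0L) {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(pm[, 3]), , drop = FALSE]
      used_t <- logical(nt); used_p <- logical(length(mz))
      for (r in seq_len(nrow(pm))) {
        i <- pm[r, 1]; h <- pm[r, 2]
        if (used_t[i] || used_p[h]) next
        used_t[i] <- TRUE; used_p[h] <- TRUE
        I[i] <- inten[h]
        ti <- c(ti, i); pi <- c(pi, keep[h]); err <- c(err, pm[r, 3])
      }
    }
  }
  matched_types <- theo$ion_type[ti]
  matched_ord <- theo$ordinal[ti]
  structure(
    list(I = I, P = theo$intensity,
         Nb = length(unique(matched_ord[matched_types %in% c("b", "b2")])),
         Ny = length(unique(matched_ord[matched_types %in% c("y", "y2")])),
         matches = data.frame(theo_idx = ti, peak_idx = pi, error = err)),
    class = "MatchResult"
  )
}

#' Correlation score Sc of a match (log space)
#'
#' The underlying score is `Nb! * Ny! * sum(I_i * P_i)` (a hypergeometric-
#' flavoured count-weighted dot product). It is evaluated in log space via
#' log-gamma so long peptides cannot overflow while the ranking is
#' preserved (log is strictly monotone): `Sc_log = lgamma(Nb+1) +
#' lgamma(Ny+1) + log(dot)`. A zero dot product returns 0 with attribute
#' `no_match = TRUE`.
#'
#' @param result A `MatchResult` from [match_ions()].
#' @return `Sc_log` (numeric scalar, attribute `no_match` flags empty
#'   matches).
#' @export
correlation_score <- function(result) {
  if (any(result$I < 0)) stop("negative experimental intensities")
  dot <- sum(result$I * result$P)
  if (dot == 0) {
    return(structure(0, no_match = TRUE))
  }
  structure(lgamma(result$Nb + 1) + lgamma(result$Ny + 1) + log(dot),
            no_match = FALSE)
}
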