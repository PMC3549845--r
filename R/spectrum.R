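#' Construct a tandem mass spectrum
#'
#' Peaks are sorted ascending by m/z; peaks with identical m/z are merged by
#' summing their intensities so that the peak list is strictly ascending.
#'
#' @param mz Numeric vector of peak m/z values (Th), all > 0.
#' @param intensity Numeric vector of raw intensities, all >= 0.
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Positive integer precursor charge.
#' @param id Spectrum identifier (opaque string).
#' @return Object of class `Spectrum`: a list with `peaks` (data.frame with
#'   columns `mz`, `intensity`), `precursor_mz`, `precursor_charge`, `id`.
#' @export
#' @examples
#' sp <- spectrum(c(300, 100, 200), c(1, 2, 3), 500.25, 2, "scan=1")
#' sp$peaks$mz
spectrum <- function(mz, intensity, precursor_mz, precursor_charge, id = "") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0L) {
    stopifnot(all(mz > 0), all(intensity >= 0))
  }
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0)
  precursor_charge <- as.integer(precursor_charge)
  stopifnot(precursor_charge >= 1L)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(
    list(
      peaks = data.frame(mz = mz, intensity = intensity),
      precursor_mz = precursor_mz,
      precursor_charge = precursor_charge,
      id = as.character(id)
    ),
    class = "Spectrum"
  )
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf(
    "Spectrum '%s': %d peaks, precursor %.4f Th (%d+), neutral mass %.4f Da\n",
    x$id, nrow(x$peaks), x$precursor_mz, x$precursor_charge,
    spectrum_neutral_mass(x)
  ))
  invisible(x)
}

#' Neutral precursor mass of a spectrum
#'
#' @param spec A `Spectrum`.
#' @return Neutral (uncharged) precursor mass in Dalton.
#' @export
spectrum_neutral_mass <- function(spec) {
  neutral_mass(spec$precursor_mz, spec$precursor_charge)
}
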