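## Spectrum preprocessing: baseline normalisation, four-level intensity
## discretisation, sliding-window denoising, and five m/z regions.

#' Normalise peak intensities against a baseline
#'
#' The baseline is the median of the nonzero raw intensities (robust to a
#' few dominant peaks); every intensity is divided by it.
#'
#' @param spec A [spectrum()].
#' @param baseline_method Currently `"median"` only.
#' @return Numeric vector of normalised intensities (same length as the
#'   peak list).
#' @export
normalize_intensities <- function(spec, baseline_method = "median") {
  ints <- spec$peaks$intensity
  nz <- ints[ints > 0]
  if (length(nz) == 0L) stop("no signal: all intensities are zero")
  baseline <- switch(baseline_method,
    median = stats::median(nz),
    stop("unknown baseline_method: ", baseline_method)
  )
  ints / baseline
}

#' Discretise normalised intensities into four levels
#'
#' Level = number of thresholds strictly below the value, giving the four
#' classes no signal (0), low (1), medium (2) and strong (3).
#'
#' @param x Numeric vector of normalised intensities.
#' @param thresholds Three strictly ascending thresholds.
#' @return Integer vector of levels in `0:3`.
#' @export
#' @examples
#' discretize_levels(c(0.5, 2, 3.5, 50))  # 0 1 2 3
discretize_levels <- function(x, thresholds = c(1, 3, 10)) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 3 strictly ascending values")
  }
  findInterval(x, thresholds, left.open = TRUE)
}

#' Sliding-window peak filter
#'
#' A peak survives if it ranks within the `top_n` most intense peaks of at
#' least one window of width `window_width` containing it. One window is
#' centred on every peak (`[mz - width/2, mz + width/2]`), so the filter is
#' independent of any grid phase.
#'
#' @param spec A [spectrum()].
#' @param norm_intensity Normalised intensities (ranking key).
#' @param window_width Window width in Thomson (> 0).
#' @param top_n Peaks retained per window (>= 1).
#' @return Logical vector: `TRUE` for kept peaks.
#' @export
window_filter <- function(spec, norm_intensity = normalize_intensities(spec),
                          window_width = 100, top_n = 6L) {
  stopifnot(window_width > 0, top_n >= 1L)
  mz <- spec$peaks$mz
  n <- length(mz)
  if (n == 0L) return(logical(0))
  kept <- logical(n)
  half <- window_width / 2
  for (centre in mz) {
    in_win <- which(mz >= centre - half & mz <= centre + half)
    if (length(in_win) == 0L) next
    if (length(in_win) <= top_n) {
      kept[in_win] <- TRUE
    } else {
      top <- in_win[order(norm_intensity[in_win], decreasing = TRUE)[seq_len(top_n)]]
      kept[top] <- TRUE
    }
  }
  kept
}

#' Assign peaks to m/z regions
#'
#' The range from 0 to the singly-protonated precursor mass is split into
#' `n_regions` equal-width bins; each peak maps to the bin containing its
#' m/z (last bin closed above). Peaks beyond the upper bound (plus
#' tolerance) fall into the last region with a warning.
#'
#' @param spec A [spectrum()].
#' @param n_regions Number of regions (default 5).
#' @param tolerance Slack (Th) above the upper bound before warning.
#' @return Integer vector of 0-based region indices in `0:(n_regions-1)`.
#' @export
assign_regions <- function(spec, n_regions = 5L, tolerance = 2) {
  stopifnot(n_regions >= 1L)
  upper <- spectrum_neutral_mass(spec) + MASS_CONST[["proton"]]
  region_of_mz(spec$peaks$mz, upper, n_regions, tolerance, warn = TRUE)
}

## Region index for arbitrary m/z values given the upper bound of the range.
region_of_mz <- function(mz, upper, n_regions = 5L, tolerance = 2,
                         warn = FALSE) {
  width <- upper / n_regions
  r <- floor(mz / width)
  over <- mz > upper + tolerance
  if (warn && any(over)) {
    warning(sum(over), " peak(s) beyond the precursor mass assigned to the ",
            "last region")
  }
  as.integer(pmin(pmax(r, 0), n_regions - 1L))
}

#' Preprocess a spectrum for tag inference and ion matching
#'
#' Runs normalisation, discretisation, sliding-window filtering and region
#' assignment. A peak is kept when it survives the window filter and its
#' discrete level is at least 1 (level-0 "no signal" peaks are dropped
#' before graph construction).
#'
#' @param spec A [spectrum()].
#' @param config Configuration list; see [default_config()]. Keys used:
#'   `baseline_method`, `discretize_thresholds`, `window_width`,
#'   `window_top_n`, `n_regions`.
#' @return Object of class `ProcessedSpectrum`: list with `spectrum`,
#'   `norm_intensity`, `level`, `region`, `kept`, `neutral_mass` (precursor)
#'   and `residue_mass_total` (neutral mass minus water).
#' @export
preprocess_spectrum <- function(spec, config = default_config()) {
  norm <- normalize_intensities(spec, config$baseline_method)
  lev <- discretize_levels(norm, config$discretize_thresholds)
  kept_win <- window_filter(spec, norm, config$window_width, config$window_top_n)
  region <- assign_regions(spec, config$n_regions)
  M <- spectrum_neutral_mass(spec)
  structure(
    list(
      spectrum = spec,
      norm_intensity = norm,
      level = lev,
      region = region,
      kept = kept_win & lev >= 1L,
      n_regions = as.integer(config$n_regions),
      neutral_mass = M,
      residue_mass_total = M - MASS_CONST[["water"]]
    ),
    class = "ProcessedSpectrum"
  )
}

#' @export
print.ProcessedSpectrum <- function(x, ...) {
  cat(sprintf("ProcessedSpectrum '%s': %d/%d peaks kept, %d regions\n",
              x$spectrum$id, sum(x$kept), length(x$kept), x$n_regions))
  invisible(x)
}
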