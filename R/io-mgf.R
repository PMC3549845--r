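## Mascot Generic Format reader/writer. MGF is a loose line-oriented text
## format (BEGIN IONS / END IONS blocks with KEY=VALUE headers and
## whitespace-separated peak lines); no pre-installed R package parses it,
## so a small dedicated parser lives here.

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` (first numeric token)
#' and `CHARGE` (e.g. `2+`) are required/recognised headers; `TITLE` becomes
#' the spectrum identifier (falling back to `block<i>`). Peaks are sorted
#' ascending by m/z.
#'
#' @param path Path to an MGF file.
#' @param default_charge Charge assumed when a block carries no CHARGE line.
#' @return List of [spectrum()] objects (empty list for an empty file).
#' @export
read_mgf <- function(path, default_charge = 2L) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  out <- list()
  i <- 1L; n <- length(lines); block <- 0L
  while (i <= n) {
    if (lines[i] != "BEGIN IONS") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#")) {
        # tolerate global headers (KEY=VALUE) outside blocks
        if (!grepl("=", lines[i], fixed = TRUE)) {
          stop("malformed MGF: unexpected line outside block ", block + 1L,
               ": '", lines[i], "'")
        }
      }
      i <- i + 1L
      next
    }
    block <- block + 1L
    i <- i + 1L
    title <- sprintf("block%d", block)
    pepmass <- NA_real_; charge <- NA_integer_
    mz <- numeric(); inten <- numeric()
    closed <- FALSE
    while (i <= n) {
      ln <- lines[i]
      if (ln == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (ln == "BEGIN IONS") stop("malformed MGF: unterminated block ", block)
      if (nzchar(ln)) {
        if (grepl("^[A-Za-z]", ln)) {
          kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
          key <- toupper(kv[1])
          val <- if (length(kv) > 1L) paste(kv[-1], collapse = "=") else ""
          if (key == "TITLE") title <- val
          if (key == "PEPMASS") {
            pepmass <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]][1]))
          }
          if (key == "CHARGE") {
            charge <- suppressWarnings(as.integer(gsub("[^0-9]", "", val)))
          }
        } else {
          toks <- strsplit(ln, "[\\s]+", perl = TRUE)[[1]]
          v <- suppressWarnings(as.numeric(toks))
          if (length(v) < 2L || anyNA(v[1:2])) {
            stop("malformed MGF: bad peak line in block ", block, ": '", ln, "'")
          }
          mz <- c(mz, v[1]); inten <- c(inten, v[2])
        }
      }
      i <- i + 1L
    }
    if (!closed) stop("malformed MGF: block ", block, " has no END IONS")
    if (is.na(pepmass)) stop("malformed MGF: block ", block, " has no PEPMASS")
    if (is.na(charge)) charge <- as.integer(default_charge)
    out[[block]] <- spectrum(mz, inten, pepmass, charge, id = title)
  }
  out
}

#' Write spectra to a Mascot Generic Format (MGF) file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$precursor_charge),
      sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}
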