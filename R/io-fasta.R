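## FASTA input (via Biostrings) and in-silico tryptic digestion.

#' Read a protein FASTA file
#'
#' Sequences are uppercased; any letter outside the 20 standard residues is
#' replaced by `X` with a warning. The accession is the first whitespace-
#' separated token of the header, the remainder becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e))
  )
  headers <- names(aa)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(aa)))
  n_bad <- 0L
  seqs <- vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    bad <- !(chars %in% ALLOWED_AA)
    if (any(bad)) {
      n_bad <<- n_bad + sum(bad)
      chars[bad] <- "X"
      s <- paste(chars, collapse = "")
    }
    s
  }, character(1), USE.NAMES = FALSE)
  if (n_bad > 0L) {
    warning(n_bad, " non-standard residue letter(s) replaced by X")
  }
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA '", path, "'")
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(accession = accession, description = description,
             sequence = seqs)
}

#' Write proteins to FASTA
#'
#' @param proteins data.frame with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    desc <- if ("description" %in% names(proteins) &&
                nzchar(proteins$description[i])) {
      paste0(" ", proteins$description[i])
    } else ""
    writeLines(paste0(">", proteins$accession[i], desc), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves C-terminal to K or R except when the next residue is P, keeping
#' peptides with up to `missed_cleavages` retained internal sites and length
#' within `[min_len, max_len]`. Coordinates are 0-based half-open, so
#' `substr(protein, start + 1, end)` recovers the peptide.
#'
#' @param sequence Protein sequence (string).
#' @param accession Parent accession carried into the output.
#' @param missed_cleavages Maximum internal missed cleavage sites (>= 0).
#' @param min_len,max_len Peptide length bounds.
#' @return data.frame with columns `sequence`, `parent_accession`, `start`,
#'   `end`, `missed_cleavages`. May have zero rows.
#' @export
#' @examples
#' digest("AKRPG", "P1", missed_cleavages = 0)$sequence  # "AK", "RPG"
digest <- function(sequence, accession = "", missed_cleavages = 2L,
                   min_len = 6L, max_len = 30L) {
  stopifnot(missed_cleavages >= 0L, min_len >= 1L, max_len >= min_len)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # cleavage site after position i (1-based): K/R at i, not P at i+1;
  # a C-terminal K/R is not an internal site
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n]
  sites <- sites[chars[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)          # 0-based cut positions
  nb <- length(bounds)
  out <- list(); k <- 0L
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + missed_cleavages)) {
      start <- bounds[i]; end <- bounds[j]
      len <- end - start
      if (len < min_len || len > max_len) next
      k <- k + 1L
      out[[k]] <- data.frame(
        sequence = paste(chars[(start + 1L):end], collapse = ""),
        parent_accession = accession,
        start = start, end = end,
        missed_cleavages = j - i - 1L
      )
    }
  }
  if (k == 0L) {
    return(data.frame(sequence = character(), parent_accession = character(),
                      start = integer(), end = integer(),
                      missed_cleavages = integer()))
  }
  do.call(rbind, out)
}

#' Digest a whole protein table into a peptide index
#'
#' Runs [digest()] over every protein, deduplicates identical (sequence,
#' accession, start) rows and annotates each peptide with its neutral mass.
#' Peptides containing `X` (unknown residue) get `NA` mass and are excluded
#' from mass-window prefilters but still searchable.
#'
#' @param proteins data.frame as from [read_fasta()].
#' @inheritParams digest
#' @return data.frame sorted by neutral `mass` with an extra `is_decoy`
#'   column (all `FALSE`; see [add_decoys()]).
#' @export
build_peptide_index <- function(proteins, missed_cleavages = 2L,
                                min_len = 6L, max_len = 30L) {
  parts <- lapply(seq_len(nrow(proteins)), function(i) {
    digest(proteins$sequence[i], proteins$accession[i],
           missed_cleavages, min_len, max_len)
  })
  idx <- do.call(rbind, parts)
  if (is.null(idx) || nrow(idx) == 0L) {
    idx <- digest("", "")  # zero-row frame with the right columns
  }
  idx$mass <- vapply(idx$sequence, function(s) {
    if (grepl("X", s, fixed = TRUE)) NA_real_ else peptide_mass(s)
  }, numeric(1), USE.NAMES = FALSE)
  idx$is_decoy <- startsWith(idx$parent_accession, "DECOY_")
  idx <- idx[order(idx$mass, idx$sequence), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

#' Append reversed-sequence decoy proteins
#'
#' Standard target-decoy construction: every protein is duplicated with its
#' sequence reversed and accession prefixed `DECOY_`, preserving length and
#' composition.
#'
#' @param proteins data.frame as from [read_fasta()].
#' @return data.frame with targets followed by decoys.
#' @export
add_decoys <- function(proteins) {
  rev_seq <- vapply(proteins$sequence, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  decoys <- data.frame(
    accession = paste0("DECOY_", proteins$accession),
    description = "reversed decoy",
    sequence = rev_seq
  )
  if (!"description" %in% names(proteins)) proteins$description <- ""
  rbind(proteins[, c("accession", "description", "sequence")], decoys)
}
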