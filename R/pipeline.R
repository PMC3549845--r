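## End-to-end orchestration of the five stages: preprocess -> spectrum
## graph -> vertex scoring -> tag inference -> tag query -> ion matching ->
## final scoring -> report.

#' Default run configuration
#'
#' One declarative list holding every tunable of the pipeline. Unknown keys
#' are rejected by [merge_config()].
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    baseline_method = "median",
    discretize_thresholds = c(1, 3, 10),
    window_width = 100,
    window_top_n = 6L,
    n_regions = 5L,
    fragment_tolerance = 0.5,
    degradation_offsets = FALSE,
    top_k = 20L,
    tag_min_len = 3L,
    tag_max_len = 7L,
    tag_min_support = 0.5,
    tag_support_temperature = 10,
    max_hits = 50L,
    mass_window = 2.5,
    gap_open = 11,
    gap_extend = 1,
    W_denovo = 0.5,
    score_mode = "weighted_sum",
    missed_cleavages = 2L,
    digest_min_len = 6L,
    digest_max_len = 30L,
    seed = 1L
  )
}

#' Merge user overrides into the default configuration
#'
#' @param overrides Named list of configuration values.
#' @param base Configuration to merge into.
#' @return Full configuration list.
#' @export
merge_config <- function(overrides = list(), base = default_config()) {
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(base, overrides)
}

#' Train the default model from a seed-fixed synthetic training set
#'
#' Stand-in for a model trained on annotated real data: simulates
#' `n_train` annotated spectra under the default generator world and trains
#' the Bayesian fragmentation model on them.
#'
#' @param n_train Number of simulated training spectra.
#' @param seed Integer seed.
#' @param config Configuration list.
#' @return List with `model` and `noise` as from [train_model()].
#' @export
train_default_model <- function(n_train = 200L, seed = 101L,
                                config = default_config()) {
  bench <- simulate_benchmark(n_spectra = n_train,
                              params = sim_params(n_proteins = 200L),
                              seed = seed)
  train_model(bench$annotated, config)
}

#' Identify peptides from spectra against a protein database
#'
#' Runs the full pipeline per spectrum: preprocessing, spectrum-graph
#' construction and Bayesian vertex scoring, top-k antisymmetric path
#' enumeration, progressive alignment and tag extraction, error-tolerant
#' tag query (similarity score Ss), theoretical-ion matching (correlation
#' score Sc), and combined final scoring with delta score. Spectra that
#' yield no tags (or no hits) produce one row flagged `no_tags` /
#' `no_hits` in the `status` column.
#'
#' @param spectra List of [spectrum()] objects.
#' @param proteins Protein data.frame (as from [read_fasta()]); pass the
#'   output of [add_decoys()] for target-decoy FDR control.
#' @param fit Trained model pair (`list(model, noise)`), e.g. from
#'   [train_model()] or [train_default_model()].
#' @param config Configuration list ([default_config()]).
#' @param index Optional pre-built peptide index (skips digestion).
#' @param verbose Print per-stage counts.
#' @return PSM data.frame (columns of [rank_and_report()] plus `status`).
#' @export
identify_spectra <- function(spectra, proteins, fit,
                             config = default_config(), index = NULL,
                             verbose = FALSE) {
  if (is.null(fit$model) || !isTRUE(fit$model$trained)) {
    stop("no trained model available: train one with train_model() or ",
         "train_default_model()")
  }
  if (is.null(index)) {
    index <- build_peptide_index(proteins, config$missed_cleavages,
                                 config$digest_min_len, config$digest_max_len)
  }
  submat <- build_matrix(config$gap_open, config$gap_extend)
  out <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    row_flag <- function(status) {
      data.frame(spectrum_id = sp$id, peptide = NA_character_,
                 parent_accession = NA_character_, is_decoy = NA,
                 tag = NA_character_, Ss = NA_real_, Sc_log = NA_real_,
                 S = NA_real_, D = NA_real_, rank = NA_integer_,
                 status = status)
    }
    tags <- infer_tags(sp, fit$model, fit$noise, config)
    if (nrow(tags) == 0L) { out[[si]] <- row_flag("no_tags"); next }
    M <- spectrum_neutral_mass(sp)
    hits <- query_tags(tags, index, submat, M,
                       max_hits = config$max_hits,
                       mass_window = config$mass_window,
                       fragment_tolerance = config$fragment_tolerance)
    if (nrow(hits) == 0L) { out[[si]] <- row_flag("no_hits"); next }
    proc <- preprocess_spectrum(sp, config)
    hits$Sc_log <- vapply(hits$peptide, function(pep) {
      theo <- theoretical_spectrum(pep, sp$precursor_charge)
      as.numeric(correlation_score(
        match_ions(proc, theo, config$fragment_tolerance)))
    }, numeric(1), USE.NAMES = FALSE)
    psms <- rank_and_report(hits, sp$id, config$W_denovo, config$score_mode)
    psms$status <- "ok"
    out[[si]] <- psms
    if (verbose) {
      message(sprintf("%s: %d peaks kept, %d tags, %d hits, %d PSMs",
                      sp$id, sum(proc$kept), nrow(tags), nrow(hits),
                      nrow(psms)))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- cbind(psm_empty(), data.frame(status = character()))
  }
  rownames(res) <- NULL
  res
}
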