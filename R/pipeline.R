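# End-to-end screening pipeline: QC -> wave correction -> HMM calling ->
# merge -> (optional two-caller union) -> filter -> disorder matching.
# Deterministic given inputs; no hidden state — the pipeline result equals
# the composition of the stage functions applied by hand.

#' Run the CNV screening pipeline
#'
#' For each sample: quality control, wave correction against the reference
#' model, HMM segmentation of the corrected signal, gap merging, optional
#' union with externally produced calls, threshold filtering, and matching
#' against the disorder database. Samples failing QC are reported with
#' status `"qc_failed"` and produce no calls.
#'
#' @param model A `wave_reference` (or path to an archive from
#'   [write_reference()]).
#' @param samples List of `signal_sample`s aligned to the model's marker
#'   map.
#' @param db Disorder database data.frame (or path to its TSV).
#' @param pfb Optional per-marker PFB vector (used when the HMM's BAF term
#'   is enabled).
#' @param external_calls Optional named list (by sample id) of CNV call
#'   data.frames from an external caller, unioned in before filtering.
#' @param qc_min_call_rate,qc_max_lrr_sd QC thresholds (defaults 0.98, 0.2).
#' @param max_gap Merge gap in bp (default 200000).
#' @param min_snps,min_length,min_conf Call filters (defaults 10, 50000,
#'   50; strict).
#' @param min_fraction Detection threshold on the detected fraction
#'   (default 1e-9: any positive overlap).
#' @param hmm An `hmm_params`.
#' @param knn_k Neighbours for cluster assignment (default 5).
#' @param out_dir Optional directory; when given, writes `report.tsv`,
#'   `qc.tsv`, per-sample rawcnv files and `manifest.json`.
#' @return List with `results` (screen report data.frame; one row per
#'   sample x disorder, or a single `qc_failed` row for failing samples),
#'   `qc` (QC table), `calls` (named list of filtered call data.frames) and
#'   `manifest` (thresholds, versions, model seed).
#' @export
run_screen_pipeline <- function(model, samples, db, pfb = NULL,
                                external_calls = NULL,
                                qc_min_call_rate = 0.98, qc_max_lrr_sd = 0.2,
                                max_gap = 200000, min_snps = 10,
                                min_length = 50000, min_conf = 50,
                                min_fraction = 1e-9, hmm = hmm_params(),
                                knn_k = 5L, out_dir = NULL) {
  if (is.character(model)) model <- read_reference(model)
  if (is.character(db)) db <- read_disorder_db(db)
  markers <- model$markers
  qc_rows <- list(); res_rows <- list(); calls_out <- list()
  for (s in samples) {
    qc <- sample_qc(s, markers, min_call_rate = qc_min_call_rate,
                    max_lrr_sd = qc_max_lrr_sd)
    qc_rows[[length(qc_rows) + 1L]] <- qc
    if (!qc$passed) {
      row <- data.frame(sample_id = s$sample_id, disorder = NA_character_,
                        detected_fraction = NA_real_, n_matched_calls = 0L,
                        status = "qc_failed", stringsAsFactors = FALSE)
      row$matched_calls <- I(list(cnv_calls_frame()))
      res_rows[[length(res_rows) + 1L]] <- row
      next
    }
    corrected <- correct_sample(s, model, knn_k = knn_k)
    calls <- call_cnvs(corrected, markers, params = hmm, pfb = pfb)
    calls <- merge_adjacent_calls(calls, max_gap = max_gap)
    ext <- external_calls[[s$sample_id]]
    if (!is.null(ext)) calls <- combine_callsets(calls, ext)
    calls <- filter_calls(calls, min_snps = min_snps, min_length = min_length,
                          min_conf = min_conf)
    calls_out[[s$sample_id]] <- calls
    res_rows[[length(res_rows) + 1L]] <-
      match_disorders(calls, db, sample_id = s$sample_id,
                      min_fraction = min_fraction)
  }
  results <- do.call(rbind, res_rows)
  qc_tab <- do.call(rbind, qc_rows)
  manifest <- list(wavecnv_version = as.character(utils::packageVersion("wavecnv")),
                   model_seed = model$seed, model_k = model$k,
                   n_samples = length(samples),
                   thresholds = list(qc_min_call_rate = qc_min_call_rate,
                                     qc_max_lrr_sd = qc_max_lrr_sd,
                                     max_gap = max_gap, min_snps = min_snps,
                                     min_length = min_length,
                                     min_conf = min_conf,
                                     min_fraction = min_fraction),
                   hmm = unclass(hmm), knn_k = knn_k)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(results[, setdiff(names(results), "matched_calls")],
                file.path(out_dir, "report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(qc_tab, file.path(out_dir, "qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (sid in names(calls_out)) {
      if (nrow(calls_out[[sid]])) {
        write_cnv_calls(calls_out[[sid]],
                        file.path(out_dir, paste0(sid, ".rawcnv")), markers)
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, qc = qc_tab, calls = calls_out, manifest = manifest)
}

#' Run the pipeline from a YAML configuration file
#'
#' Configuration keys: `model` (reference archive path), `signals` (directory
#' of signal tables or explicit file list), `db` (disorder TSV), optional
#' `pfb`, optional `external_calls` (directory of `<sample>.rawcnv` files),
#' optional `out` (output directory), and a `thresholds` mapping overriding
#' any of the [run_screen_pipeline()] threshold arguments, plus optional
#' `hmm` overrides for [hmm_params()].
#'
#' @param path YAML file.
#' @return The [run_screen_pipeline()] result.
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("model", "signals", "db")
  if (!all(need %in% names(cfg))) {
    stop_format("pipeline config: missing key(s) %s",
                paste(setdiff(need, names(cfg)), collapse = ", "))
  }
  model <- read_reference(cfg$model)
  files <- if (length(cfg$signals) == 1L && dir.exists(cfg$signals[[1L]])) {
    list.files(cfg$signals[[1L]], pattern = "\\.txt$", full.names = TRUE)
  } else unlist(cfg$signals)
  samples <- lapply(files, function(f) read_signal_table(f)$sample)
  pfb <- if (!is.null(cfg$pfb)) unname(read_pfb_table(cfg$pfb)) else NULL
  ext <- NULL
  if (!is.null(cfg$external_calls)) {
    fl <- list.files(cfg$external_calls, pattern = "\\.rawcnv$", full.names = TRUE)
    ext <- lapply(fl, read_cnv_calls)
    names(ext) <- sub("\\.rawcnv$", "", basename(fl))
  }
  args <- c(list(model = model, samples = samples, db = cfg$db, pfb = pfb,
                 external_calls = ext, out_dir = cfg$out),
            cfg$thresholds)
  if (!is.null(cfg$hmm)) args$hmm <- do.call(hmm_params, cfg$hmm)
  do.call(run_screen_pipeline, args)
}
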