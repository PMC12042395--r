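# End-to-end orchestration: simulate/ingest -> filter -> scrub -> extract
# -> ground truth -> aggregate -> evaluate -> cost, with every intermediate
# persisted and a manifest recording seed, config fingerprint, and
# per-stage record counts.

#' Pipeline run configuration
#'
#' Bundles the stage configurations for a reproducible end-to-end run on a
#' synthetic cohort. Aggregation defaults follow the cohort style: registry
#' style (`"BGR"`) uses majority voting for both questions; clinic style
#' (`"CP_VSS"`/`"CP_CFCS"`) uses any-yes for ambulatory (to overcome serial
#' duplicated-history notes) and majority for verbal. The cohort style is
#' an explicit field, never inferred.
#'
#' @param cohort A [cohort_config()].
#' @param criteria A [selection_criteria()].
#' @param scrub A [scrub_config()].
#' @param mode Prompting mode, `"MCP"` or `"BCP"`.
#' @param backend An [extractor_backend()]; default a zero-error
#'   [mock_backend()] in the given mode.
#' @param cohort_style `"BGR"`, `"CP_VSS"`, or `"CP_CFCS"` (ground-truth
#'   instrument selection).
#' @param aggregation Named rules per question; default per cohort style.
#' @param min_informativeness_n Display threshold for the note-type
#'   informativeness table (default 50).
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            criteria = selection_criteria(),
                            scrub = scrub_config(),
                            mode = c("MCP", "BCP"),
                            backend = NULL,
                            cohort_style = c("BGR", "CP_VSS", "CP_CFCS"),
                            aggregation = NULL,
                            min_informativeness_n = 50,
                            seed = 1L) {
  mode <- arg_match(mode)
  cohort_style <- arg_match(cohort_style)
  backend <- backend %||% mock_backend(mode = mode, seed = seed)
  aggregation <- aggregation %||% if (cohort_style == "BGR")
    list(verbal = "majority", ambulatory = "majority") else
    list(verbal = "majority", ambulatory = "any_yes")
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(criteria, "selection_criteria"),
            inherits(scrub, "scrub_config"),
            inherits(backend, "extractor_backend"))
  structure(list(cohort = cohort, criteria = criteria, scrub = scrub,
                 mode = mode, backend = backend,
                 cohort_style = cohort_style, aggregation = aggregation,
                 min_informativeness_n = min_informativeness_n,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order on a generated cohort, persisting every
#' intermediate under `out_dir`: `notes.jsonl`, `patients.csv`,
#' `assessments.csv`, `truth.csv`, `kept.jsonl` + `exclusions.json`,
#' `scrubbed.jsonl`, `predictions.csv`, `individuals.csv`, `report.json`,
#' and `manifest.json`. A stage error halts the run naming the stage;
#' earlier intermediates remain on disk. Reports contain no timestamps, so
#' rerunning the same configuration yields byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage outputs (`cohort`,
#'   `truth`, `filtered`, `predictions`, `individuals`, `reports`,
#'   `informativeness`, `manifest`) plus `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "notepheno_pipeline_error", parent = e)
    })
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))
  write_notes(cohort$notes, file.path(out_dir, "notes.jsonl"))
  write_patients(cohort$patients, file.path(out_dir, "patients.csv"))
  write_assessments(cohort$assessments,
                    file.path(out_dir, "assessments.csv"))
  counts$notes_generated <- nrow(cohort$notes)

  truth <- stage("ground_truth",
                 resolve_cohort_truth(cohort$assessments,
                                      config$cohort_style))
  write_truth(truth, file.path(out_dir, "truth.csv"))
  counts$truth_labels <- nrow(truth)

  filtered <- stage("filter",
                    filter_notes(cohort$notes, cohort$patients, truth,
                                 config$criteria))
  write_notes(filtered$notes, file.path(out_dir, "kept.jsonl"))
  jsonlite::write_json(
    stats::setNames(as.list(filtered$tally$n_removed),
                    filtered$tally$rule),
    file.path(out_dir, "exclusions.json"), auto_unbox = TRUE)
  counts$notes_kept <- nrow(filtered$notes)

  scrubbed <- filtered$notes
  scrubbed$text <- stage("scrub",
                         scrub_leakage(scrubbed$text, config$scrub))
  write_notes(scrubbed, file.path(out_dir, "scrubbed.jsonl"))

  template <- prompt_template(mode = config$mode)
  ext <- stage("extract", extract_corpus(scrubbed, template,
                                         config$backend))
  write_predictions(ext$predictions,
                    file.path(out_dir, "predictions.csv"))
  counts$predictions <- nrow(ext$predictions)
  counts$extraction_failures <- nrow(ext$failures)

  individuals <- stage("aggregate",
                       aggregate_individuals(ext$predictions,
                                             config$aggregation))
  readr::write_csv(individuals, file.path(out_dir, "individuals.csv"),
                   progress = FALSE)
  counts$individuals <- nrow(individuals)

  reports <- stage("evaluate", evaluate(individuals, truth))
  if (inherits(reports, "eval_report")) {
    reports <- stats::setNames(list(reports), reports$question)
  }
  informativeness <- lapply(QUESTIONS, function(q) {
    note_type_informativeness(ext$predictions, truth, q,
                              min_n = config$min_informativeness_n,
                              by = "specialty")
  })
  names(informativeness) <- QUESTIONS

  cost <- stage("cost", {
    avg_chars <- measure_avg_input_chars(
      scrubbed, template, config$backend$context_char_limit)
    expected_cost(cost_params(
      n_notes = nrow(scrubbed), prompts_per_note = 1,
      avg_input_chars = avg_chars,
      input_cost_per_1k = 0.005, output_cost_per_1k = 0.015))
  })

  report <- list(
    cohort_style = config$cohort_style,
    mode = config$mode,
    aggregation = config$aggregation,
    evaluation = lapply(reports, function(r) list(
      question = r$question,
      avg_precision = r$avg_precision, avg_recall = r$avg_recall,
      weighted_f1 = r$weighted_f1, macro_f1 = r$macro_f1,
      n_individuals = r$n_individuals,
      n_zero_evidence = r$n_zero_evidence)),
    informativeness = informativeness,
    cost = list(total_cost = cost$total_cost,
                total_display = cost$total_display),
    counts = counts)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("notepheno")),
    seed = config$seed,
    cohort_seed = config$cohort$seed,
    cohort_style = config$cohort_style,
    mode = config$mode,
    backend_id = config$backend$backend_id,
    config_hash = fnv1a(paste(deparse(config[setdiff(names(config),
                                                     "backend")]),
                              collapse = "")),
    stage_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, truth = truth, filtered = filtered,
                 predictions = ext$predictions, failures = ext$failures,
                 individuals = individuals, reports = reports,
                 informativeness = informativeness, cost = cost,
                 manifest = manifest, out_dir = out_dir))
}
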