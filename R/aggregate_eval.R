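# Note-to-individual label aggregation, evaluation metrics, note-type
# informativeness analysis, and paired experiment comparison.

#' Aggregate one patient's note answers by majority vote
#'
#' `unknown` answers are excluded from the counts; the individual label is
#' "yes" iff the number of "yes" notes strictly exceeds the number of "no"
#' notes, and "no" otherwise -- so ties and all-unknown patients resolve to
#' "no". All-unknown patients are flagged as zero-evidence so reports can
#' quantify the effect of that convention.
#'
#' @param answers Character vector of note-level answers (yes/no/unknown).
#' @return A list: `label`, `n_yes`, `n_no`, `n_unknown`, `rule`,
#'   `zero_evidence`.
#' @export
aggregate_majority <- function(answers) {
  counts <- answer_counts(answers)
  c(list(label = if (counts$n_yes > counts$n_no) "yes" else "no"),
    counts, list(rule = "majority",
                 zero_evidence = counts$n_yes + counts$n_no == 0L))
}

#' Aggregate one patient's note answers by the any-yes rule
#'
#' The individual label is "yes" iff at least one note answered "yes".
#' Designed for corpora where serial notes with duplicated history sections
#' cause an influx of "no" answers for genuinely ambulatory patients: a
#' single current "yes" then decides.
#'
#' @inheritParams aggregate_majority
#' @return As [aggregate_majority()], with `rule = "any_yes"`.
#' @export
aggregate_any_yes <- function(answers) {
  counts <- answer_counts(answers)
  c(list(label = if (counts$n_yes >= 1L) "yes" else "no"),
    counts, list(rule = "any_yes",
                 zero_evidence = counts$n_yes + counts$n_no == 0L))
}

answer_counts <- function(answers) {
  if (length(answers) == 0L) {
    abort("Cannot aggregate an empty prediction set.",
          class = "notepheno_domain_error")
  }
  bad <- setdiff(unique(answers), ANSWERS)
  if (length(bad)) {
    abort(sprintf("Invalid answer '%s'.", bad[1]),
          class = "notepheno_domain_error")
  }
  list(n_yes = sum(answers == "yes"), n_no = sum(answers == "no"),
       n_unknown = sum(answers == "unknown"))
}

#' Aggregate note-level predictions to individual-level labels
#'
#' Applies a per-question aggregation rule over each patient's note
#' predictions.
#'
#' @param predictions Prediction tibble ([extract_corpus()] or
#'   [read_predictions()]).
#' @param rules Named list/character: rule per question, each `"majority"`
#'   or `"any_yes"` (e.g. `list(verbal = "majority", ambulatory =
#'   "any_yes")`).
#' @return Tibble with one row per (patient, question): patient_id,
#'   question, label, n_yes, n_no, n_unknown, rule, zero_evidence.
#' @export
aggregate_individuals <- function(predictions,
                                  rules = list(verbal = "majority",
                                               ambulatory = "majority")) {
  predictions <- tibble::as_tibble(predictions)
  out <- lapply(QUESTIONS, function(q) {
    rule <- rules[[q]]
    assert_choice(rule, c("majority", "any_yes"), paste0("rules$", q))
    f <- if (rule == "majority") aggregate_majority else aggregate_any_yes
    grp <- split(predictions[[q]], predictions$patient_id)
    rows <- lapply(names(grp), function(pid) {
      agg <- f(grp[[pid]])
      tibble::tibble(patient_id = pid, question = q, label = agg$label,
                     n_yes = agg$n_yes, n_no = agg$n_no,
                     n_unknown = agg$n_unknown, rule = agg$rule,
                     zero_evidence = agg$zero_evidence)
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

# Per-class precision/recall/F1 from a 2x2 confusion table, with the
# zero-denominator convention: a metric whose denominator is zero is 0 and
# flagged.
class_metrics <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       undefined = (tp + fp == 0) || (tp + fn == 0))
}

#' Evaluate individual-level predictions against ground truth
#'
#' Computes per-class (yes/no) precision, recall, and F1 with "yes" as the
#' positive class of its own table, then combines them as:
#' weighted F1 = `F1_yes * (n_yes / N) + F1_no * (n_no / N)` where the
#' weights are ground-truth class prevalences; macro F1 is the unweighted
#' mean. Average precision/recall are reported both as unweighted class
#' means (the default reading) and prevalence-weighted. Metrics with a zero
#' denominator are 0 and flagged.
#'
#' @param individual_preds Tibble from [aggregate_individuals()], or any
#'   tibble with patient_id, question, label.
#' @param truths Ground-truth tibble (patient_id, question, label).
#' @param question Optionally restrict to `"verbal"` or `"ambulatory"`;
#'   default evaluates each question present and returns a list keyed by
#'   question.
#' @return For one question: an `eval_report` list with `confusion`,
#'   `per_class`, `avg_precision`, `avg_recall`, `weighted_precision`,
#'   `weighted_recall`, `weighted_f1`, `macro_f1`, `n_individuals`,
#'   `n_zero_evidence`. For several: a named list of such reports.
#' @export
evaluate <- function(individual_preds, truths, question = NULL) {
  individual_preds <- tibble::as_tibble(individual_preds)
  truths <- tibble::as_tibble(truths)
  if (is.null(question)) {
    qs <- intersect(QUESTIONS, unique(individual_preds$question))
    out <- lapply(qs, function(q) evaluate(individual_preds, truths, q))
    names(out) <- qs
    return(if (length(out) == 1L) out[[1]] else out)
  }
  question <- arg_match(question, QUESTIONS)
  preds <- individual_preds[individual_preds$question == question, ]
  tr <- truths[truths$question == question, ]
  merged <- dplyr::inner_join(
    preds[c("patient_id", "label",
            intersect("zero_evidence", names(preds)))],
    tr[c("patient_id", "label")],
    by = "patient_id", suffix = c("_pred", "_true"))
  if (nrow(merged) < nrow(preds)) {
    missing <- setdiff(preds$patient_id, tr$patient_id)
    abort(sprintf(
      "Patient '%s' has a prediction but no ground-truth label for '%s'.",
      missing[1], question), class = "notepheno_domain_error")
  }
  n_zero <- if ("zero_evidence" %in% names(merged))
    sum(merged$zero_evidence) else 0L
  eval_labels(merged$label_pred, merged$label_true, question,
              n_zero_evidence = n_zero)
}

# Core metric computation from parallel label vectors.
eval_labels <- function(pred, truth, question = NA_character_,
                        n_zero_evidence = 0L) {
  stopifnot(length(pred) == length(truth))
  n <- length(pred)
  tp <- sum(pred == "yes" & truth == "yes")
  fp <- sum(pred == "yes" & truth == "no")
  fn <- sum(pred == "no" & truth == "yes")
  tn <- sum(pred == "no" & truth == "no")
  n_yes <- tp + fn
  n_no <- tn + fp
  yes <- class_metrics(tp, fp, fn)
  no <- class_metrics(tn, fn, fp)
  w_yes <- if (n > 0) n_yes / n else 0
  w_no <- if (n > 0) n_no / n else 0
  structure(list(
    question = question,
    confusion = list(tp = tp, fp = fp, fn = fn, tn = tn,
                     n_yes_annotations = n_yes, n_no_annotations = n_no),
    per_class = tibble::tibble(
      class = c("yes", "no"),
      precision = c(yes$precision, no$precision),
      recall = c(yes$recall, no$recall),
      f1 = c(yes$f1, no$f1),
      undefined = c(yes$undefined, no$undefined)),
    avg_precision = (yes$precision + no$precision) / 2,
    avg_recall = (yes$recall + no$recall) / 2,
    weighted_precision = yes$precision * w_yes + no$precision * w_no,
    weighted_recall = yes$recall * w_yes + no$recall * w_no,
    weighted_f1 = yes$f1 * w_yes + no$f1 * w_no,
    macro_f1 = (yes$f1 + no$f1) / 2,
    n_individuals = n,
    n_zero_evidence = n_zero_evidence),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s): n = %d individuals\n",
              x$question %||% "?", x$n_individuals))
  cat(sprintf("  weighted F1 %.3f | macro F1 %.3f | avg P %.3f | avg R %.3f\n",
              x$weighted_f1, x$macro_f1, x$avg_precision, x$avg_recall))
  if (x$n_zero_evidence > 0) {
    cat(sprintf("  %d individual(s) had only 'unknown' notes (counted as 'no')\n",
                x$n_zero_evidence))
  }
  invisible(x)
}

#' Informativeness of each note type
#'
#' For every note type: the proportion of note-level predictions that are
#' non-unknown, and -- over non-unknown predictions only -- the fraction
#' matching the corresponding individual's ground-truth label. Types with
#' fewer than `min_n` notes are omitted (display threshold); a type whose
#' predictions are all unknown reports `NA` correctness.
#'
#' @param note_preds Note-level prediction tibble.
#' @param truths Ground-truth tibble.
#' @param question `"verbal"` or `"ambulatory"`.
#' @param min_n Minimum note count for a type to be reported (default 50).
#' @param by Grouping column in `note_preds` (default `"note_type"`;
#'   synthetic corpora vary `"specialty"` instead).
#' @return Tibble: group, n_notes, prop_non_unknown,
#'   correctness_non_unknown.
#' @export
note_type_informativeness <- function(note_preds, truths, question,
                                      min_n = 50, by = "note_type") {
  question <- arg_match(question, QUESTIONS)
  note_preds <- tibble::as_tibble(note_preds)
  if (!by %in% names(note_preds)) {
    abort(sprintf("Column '%s' not present in predictions.", by),
          class = "notepheno_domain_error")
  }
  tr <- truths[truths$question == question, c("patient_id", "label")]
  df <- dplyr::inner_join(note_preds, tr, by = "patient_id")
  df$answer <- df[[question]]
  df$grp <- df[[by]]
  out <- dplyr::summarise(
    dplyr::group_by(df, grp),
    n_notes = dplyr::n(),
    prop_non_unknown = mean(answer != "unknown"),
    correctness_non_unknown = ifelse(sum(answer != "unknown") == 0,
                                     NA_real_,
                                     mean(answer[answer != "unknown"] ==
                                            label[answer != "unknown"])),
    .groups = "drop")
  names(out)[1] <- by
  out[out$n_notes >= min_n, , drop = FALSE]
}

#' Compare two experiments by Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test on per-unit score differences (the
#' pairing unit is the caller's choice; per-question weighted F1 across
#' bootstrap resamples of individuals is a natural one). Zero differences
#' are discarded (the standard zero-discard convention). With no nonzero
#' differences the comparison is degenerate and reported as no-evidence
#' (`p_value = NA`).
#'
#' @param scores_a,scores_b Equal-length numeric vectors of paired scores.
#' @return A list: `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n`, `n_nonzero`, `degenerate`.
#' @export
compare_experiments <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    abort("Paired samples must have equal length.",
          class = "notepheno_domain_error")
  }
  if (length(scores_a) < 5L) {
    abort("Need at least 5 pairs.", class = "notepheno_domain_error")
  }
  d <- scores_b - scores_a
  nz <- sum(d != 0)
  if (nz == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = length(d), n_nonzero = 0L, degenerate = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            paired = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(d), n_nonzero = nz, degenerate = FALSE)
}
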