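# Mapping of standardized-assessment responses to per-patient binary
# ground-truth labels, with conflict detection.
#
# The mappings implement the published response->label tables:
#   * CARS-2 "Is the person you are rating using words?"  yes/no -> verbal
#   * Telehealth screener "Does [name] use single words?"  yes/no -> verbal
#   * M-CHAT-R "Does your child walk?"                     yes/no -> ambulatory
#   * GMFCS (1-5, age-stratified)                          -> ambulatory
#   * Viking Speech Scale (1-4)                            -> verbal
#   * CFCS (1-5)                                           -> verbal

#' Map a GMFCS class to ambulatory ability
#'
#' The Gross Motor Function Classification System grades self-initiated
#' motor ability 1-5 with age-specific criteria. Walking without aid maps
#' as: ages 3 to 4 (the interval `[3, 4)`), class 1 is "yes" and classes
#' 2-5 "no"; ages 4 to 18 (`[4, 18]`), classes 1-2 are "yes" and classes
#' 3-5 "no". The boundary age 4.0 falls in the older stratum so the strata
#' tile the age axis without overlap.
#'
#' @param class Integer GMFCS class, 1-5 (vectorised).
#' @param age Age in decimal years, >= 3 (vectorised).
#' @param allow_adult Extend the 4-18 rule above age 18 (off by default;
#'   the published table stops at 18).
#' @return `"yes"`/`"no"` per element.
#' @export
map_gmfcs <- function(class, age, allow_adult = FALSE) {
  class <- as.integer(class)
  if (any(is.na(class)) || any(class < 1L | class > 5L)) {
    abort("GMFCS class must be an integer in 1..5.",
          class = "notepheno_domain_error")
  }
  if (any(age < 3)) {
    abort("GMFCS mapping is defined for ages >= 3.",
          class = "notepheno_domain_error")
  }
  if (!allow_adult && any(age > 18)) {
    abort("GMFCS mapping is defined for ages <= 18 (see `allow_adult`).",
          class = "notepheno_domain_error")
  }
  ifelse(age < 4, ifelse(class == 1L, "yes", "no"),
         ifelse(class <= 2L, "yes", "no"))
}

#' Map a Viking Speech Scale class to verbal ability
#'
#' The VSS grades motor impact on speech 1-4; classes 1-3 map to "yes"
#' (uses words), class 4 to "no".
#'
#' @param class Integer VSS class, 1-4 (vectorised).
#' @return `"yes"`/`"no"` per element.
#' @export
map_vss <- function(class) {
  class <- as.integer(class)
  if (any(is.na(class)) || any(class < 1L | class > 4L)) {
    abort("VSS class must be an integer in 1..4.",
          class = "notepheno_domain_error")
  }
  ifelse(class <= 3L, "yes", "no")
}

#' Map a CFCS class to verbal ability
#'
#' The Communication Function Classification System grades 1-5; classes 1-4
#' map to "yes", class 5 to "no".
#'
#' @param class Integer CFCS class, 1-5 (vectorised).
#' @return `"yes"`/`"no"` per element.
#' @export
map_cfcs <- function(class) {
  class <- as.integer(class)
  if (any(is.na(class)) || any(class < 1L | class > 5L)) {
    abort("CFCS class must be an integer in 1..5.",
          class = "notepheno_domain_error")
  }
  ifelse(class <= 4L, "yes", "no")
}

#' Map a binary-instrument response to a label
#'
#' CARS-2 ("Is the person you are rating using words?"), the telehealth
#' screener ("Does \[name\] use single words?") and M-CHAT-R ("Does your
#' child walk?") all map identically: the recorded yes/no is the label.
#'
#' @param instrument `"CARS2"`, `"TELEHEALTH"`, or `"MCHAT_R"`.
#' @param response `"yes"` or `"no"` (vectorised).
#' @return `"yes"`/`"no"` per element.
#' @export
map_binary_instrument <- function(instrument, response) {
  assert_choice(instrument, c("CARS2", "TELEHEALTH", "MCHAT_R"), "instrument")
  response <- tolower(response)
  if (any(!response %in% c("yes", "no"))) {
    abort(sprintf("%s response must be 'yes' or 'no'.", instrument),
          class = "notepheno_domain_error")
  }
  response
}

# Instruments applicable per (cohort style, question). BGR ground truth
# comes from the remote neurobehavioral battery; CP ground truth from
# clinic-curated scale classifications, with verbal evaluated against VSS
# and CFCS separately.
applicable_instruments <- function(cohort_style, question) {
  switch(cohort_style,
    BGR = if (question == "verbal") c("CARS2", "TELEHEALTH")
          else c("GMFCS", "MCHAT_R"),
    CP_VSS = if (question == "verbal") "VSS" else "GMFCS",
    CP_CFCS = if (question == "verbal") "CFCS" else "GMFCS",
    abort("cohort_style must be 'BGR', 'CP_VSS' or 'CP_CFCS'.",
          class = "notepheno_config_error"))
}

map_record <- function(instrument, response, age) {
  switch(instrument,
    GMFCS = map_gmfcs(as.integer(response), age),
    VSS = map_vss(as.integer(response)),
    CFCS = map_cfcs(as.integer(response)),
    map_binary_instrument(instrument, response))
}

#' Resolve one patient's ground-truth label for a question
#'
#' Maps every applicable assessment record through the published rules and
#' returns the consensus label with its sources. Conflicting mapped labels
#' raise an error naming the instruments -- conflicts are never silently
#' voted away, because none are expected in well-formed data and silent
#' resolution would mask upstream bugs.
#'
#' @param records Assessment tibble for one patient (see
#'   [read_assessments()]).
#' @param question `"verbal"` or `"ambulatory"`.
#' @param cohort_style `"BGR"` (verbal from CARS-2/telehealth, ambulatory
#'   from GMFCS/M-CHAT-R), `"CP_VSS"` or `"CP_CFCS"` (ambulatory from GMFCS
#'   only; verbal from the named scale only).
#' @return A list with `patient_id`, `question`, `label`, `sources`.
#' @export
resolve_ground_truth <- function(records, question,
                                 cohort_style = c("BGR", "CP_VSS",
                                                  "CP_CFCS")) {
  question <- arg_match(question, QUESTIONS)
  cohort_style <- arg_match(cohort_style)
  records <- tibble::as_tibble(records)
  inst <- applicable_instruments(cohort_style, question)
  rec <- records[records$instrument %in% inst, , drop = FALSE]
  if (nrow(rec) == 0L) {
    abort(sprintf(
      "No applicable assessment for question '%s' under cohort style '%s'.",
      question, cohort_style),
      class = "notepheno_missing_label_error")
  }
  labels <- vapply(seq_len(nrow(rec)), function(i) {
    map_record(rec$instrument[i], rec$response[i], rec$age_at_assessment[i])
  }, character(1))
  if (length(unique(labels)) > 1L) {
    abort(sprintf(
      "Conflicting mapped labels for patient '%s', question '%s': %s.",
      rec$patient_id[1], question,
      paste(sprintf("%s->%s", rec$instrument, labels), collapse = ", ")),
      class = "notepheno_conflict_error")
  }
  list(patient_id = rec$patient_id[1], question = question,
       label = labels[1], sources = sort(unique(rec$instrument)))
}

#' Resolve ground truth for a whole cohort
#'
#' Vectorised wrapper around the per-record mapping rules: every applicable
#' record is mapped, then labels are grouped per (patient, question).
#' Patients with zero applicable records for a question are omitted (they
#' are excluded upstream by the note-selection filter); conflicting labels
#' raise as in [resolve_ground_truth()].
#'
#' @inheritParams resolve_ground_truth
#' @param assessments Assessment tibble for the cohort.
#' @return A ground-truth tibble (patient_id, question, label, sources).
#' @export
resolve_cohort_truth <- function(assessments,
                                 cohort_style = c("BGR", "CP_VSS",
                                                  "CP_CFCS")) {
  cohort_style <- arg_match(cohort_style)
  assessments <- validate_assessments(assessments)
  out <- lapply(QUESTIONS, function(q) {
    inst <- applicable_instruments(cohort_style, q)
    rec <- assessments[assessments$instrument %in% inst, , drop = FALSE]
    if (nrow(rec) == 0L) return(NULL)
    rec$mapped <- NA_character_
    for (ins in unique(rec$instrument)) {
      sel <- rec$instrument == ins
      rec$mapped[sel] <- map_record_vec(ins, rec$response[sel],
                                        rec$age_at_assessment[sel])
    }
    grp <- dplyr::group_by(rec, patient_id)
    res <- dplyr::summarise(
      grp,
      n_labels = dplyr::n_distinct(mapped),
      label = mapped[1],
      sources = paste(sort(unique(instrument)), collapse = ";"),
      detail = paste(sprintf("%s->%s", instrument, mapped), collapse = ", "),
      .groups = "drop")
    conflict <- res$n_labels > 1L
    if (any(conflict)) {
      abort(sprintf(
        "Conflicting mapped labels for patient '%s', question '%s': %s.",
        res$patient_id[conflict][1], q, res$detail[conflict][1]),
        class = "notepheno_conflict_error")
    }
    tibble::tibble(patient_id = res$patient_id, question = q,
                   label = res$label, sources = res$sources)
  })
  dplyr::bind_rows(out)
}

map_record_vec <- function(instrument, response, age) {
  switch(instrument,
    GMFCS = map_gmfcs(as.integer(response), age),
    VSS = map_vss(as.integer(response)),
    CFCS = map_cfcs(as.integer(response)),
    map_binary_instrument(instrument, response))
}
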