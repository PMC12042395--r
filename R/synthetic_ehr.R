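# Synthetic EHR cohort generator: patients, notes, and assessment records
# with known latent abilities, so every downstream stage is testable without
# real data.

#' Cohort generator configuration
#'
#' Describes a synthetic clinic cohort: how many patients, the prevalence of
#' each latent ability, how many notes each patient accrues and how long
#' they are, the author-specialty mixture, and the rates at which notes
#' state an ability (`informative_rate`), state the opposite of the latent
#' truth (`contradiction_rate`), embed a scale-score mention that the
#' scrubber must remove (`leakage_rate`), or share identical history
#' sections across serial physical-therapy notes (`duplicate_history_rate`).
#'
#' `style = "BGR"` emulates a multi-site registry corpus (shorter notes, no
#' duplicated histories). `style = "CP"` emulates a cerebral-palsy clinic
#' corpus: notes of at least 520 words, frequent weekly physical-therapy
#' notes with identical aided-mobility history sections, and scale scores
#' (GMFCS/VSS/CFCS) recorded as clinic ground truth.
#'
#' Ages are sampled between 3 and 18 years, matching the population the
#' note-selection filter retains. Latent abilities are static per patient;
#' temporal drift is deliberately not modelled.
#'
#' @param n_patients Number of patients (default 125).
#' @param latent_prevalence Named probabilities `c(verbal=, ambulatory=)`
#'   that the latent ability is "yes".
#' @param notes_per_patient `list(min=, max=)` note count per patient.
#' @param note_length_words `list(min=, max=)` target word count per note.
#' @param specialty_mix Named non-negative weights over author specialties.
#' @param informative_rate Probability a note states its author specialty's
#'   primary ability (half that rate for the other ability). The first note
#'   of every patient is an intake evaluation documenting both abilities
#'   whenever this rate is positive.
#' @param contradiction_rate Probability an informative sentence states the
#'   opposite of the latent truth.
#' @param leakage_rate Probability a note embeds a scale mention in
#'   realistic casing (e.g. "GMFCS level III").
#' @param duplicate_history_rate Probability a patient's physical-therapy
#'   notes share one identical aided-mobility history section.
#' @param seed Integer seed; a fixed seed yields byte-identical cohorts.
#' @param style `"BGR"` or `"CP"` (see above).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 125,
                          latent_prevalence = c(verbal = 0.7,
                                                ambulatory = 0.6),
                          notes_per_patient = NULL,
                          note_length_words = NULL,
                          specialty_mix = DEFAULT_SPECIALTIES,
                          informative_rate = 0.6,
                          contradiction_rate = 0,
                          leakage_rate = NULL,
                          duplicate_history_rate = NULL,
                          seed = 1L,
                          style = c("BGR", "CP")) {
  style <- arg_match(style)
  notes_per_patient <- notes_per_patient %||% list(min = 5, max = 30)
  note_length_words <- note_length_words %||%
    if (style == "CP") list(min = 520, max = 900) else
      list(min = 150, max = 600)
  leakage_rate <- leakage_rate %||% if (style == "CP") 0.25 else 0.15
  duplicate_history_rate <- duplicate_history_rate %||%
    if (style == "CP") 0.5 else 0
  assert_count(n_patients, "n_patients", min = 1)
  for (nm in c("informative_rate", "contradiction_rate", "leakage_rate",
               "duplicate_history_rate")) {
    assert_probability(get(nm), nm)
  }
  assert_probability(latent_prevalence, "latent_prevalence")
  if (!all(QUESTIONS %in% names(latent_prevalence))) {
    abort("latent_prevalence needs named entries 'verbal' and 'ambulatory'.",
          class = "notepheno_config_error")
  }
  for (nm in c("notes_per_patient", "note_length_words")) {
    d <- get(nm)
    if (!is.list(d) || !all(c("min", "max") %in% names(d)) ||
        d$min < 1 || d$max < d$min) {
      abort(sprintf("`%s` must be list(min=, max=) with 1 <= min <= max.",
                    nm), class = "notepheno_config_error")
    }
  }
  if (!is.numeric(specialty_mix) || is.null(names(specialty_mix)) ||
      any(specialty_mix < 0) || sum(specialty_mix) <= 0) {
    abort("`specialty_mix` must be named nonnegative weights.",
          class = "notepheno_config_error")
  }
  assert_count(as.numeric(seed), "seed", min = 0)
  structure(list(
    n_patients = as.integer(n_patients),
    latent_prevalence = latent_prevalence,
    notes_per_patient = notes_per_patient,
    note_length_words = note_length_words,
    specialty_mix = specialty_mix / sum(specialty_mix),
    informative_rate = informative_rate,
    contradiction_rate = contradiction_rate,
    leakage_rate = leakage_rate,
    duplicate_history_rate = duplicate_history_rate,
    seed = as.integer(seed), style = style),
    class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws patients with latent verbal/ambulatory abilities, renders their
#' clinical notes from the template bank, and produces assessment records
#' whose mapped labels (see [resolve_cohort_truth()]) equal the latent
#' truth by construction. Each patient is generated from an independent
#' random substream derived from the cohort seed and the patient counter,
#' so adding a patient does not perturb the others.
#'
#' @param config A [cohort_config()].
#' @return A list with tibbles `patients`, `notes`, `assessments`, `truth`
#'   (the latent abilities plus consistent scale classes), and `note_tags`
#'   (machine-readable per-note stance tags, for tests and oracle
#'   extractors -- not visible to extraction backends).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  enrollment_base <- as.Date("2023-06-01")
  res <- lapply(seq_len(config$n_patients), function(i) {
    pseed <- (config$seed %% 100000L) * 20011L + i * 7919L
    with_seed(pseed %% 2147483647L, generate_patient(i, config,
                                                     enrollment_base))
  })
  list(
    patients = dplyr::bind_rows(lapply(res, `[[`, "patient")),
    notes = dplyr::bind_rows(lapply(res, `[[`, "notes")),
    assessments = dplyr::bind_rows(lapply(res, `[[`, "assessments")),
    truth = dplyr::bind_rows(lapply(res, `[[`, "truth")),
    note_tags = dplyr::bind_rows(lapply(res, `[[`, "tags"))
  )
}

generate_patient <- function(i, config, enrollment_base) {
  pid <- sprintf("P%04d", i)
  age_enroll <- stats::runif(1, 3.0, 17.9)
  enrollment <- enrollment_base + sample.int(60L, 1L) - 1L
  dob <- enrollment - ceiling(age_enroll * 365.25)

  latent <- draw_latent(pid, config)
  assessments <- generate_assessments(latent, age_enroll,
                                      style = config$style)

  n_notes <- sample1(seq(config$notes_per_patient$min,
                         config$notes_per_patient$max))
  dup_history <- stats::runif(1) < config$duplicate_history_rate
  dup_text <- if (dup_history) {
    paste("History:",
          sample(FILLER$history, 1L),
          sample(DUP_HISTORY_SENTENCES, 1L))
  } else NULL

  specs <- sample(names(config$specialty_mix), n_notes, replace = TRUE,
                  prob = config$specialty_mix)
  specs[1] <- "developmental pediatrics"  # intake evaluation

  # Encounter dates stay within the selection window and above age 3.
  lo <- -min(547L, floor((age_enroll - 3) * 365.25))
  offsets <- c(0L, sample(seq(lo, 547L), n_notes - 1L, replace = TRUE))

  notes <- vector("list", n_notes)
  tags <- vector("list", n_notes)
  for (j in seq_len(n_notes)) {
    nid <- sprintf("%s-N%03d", pid, j)
    rn <- render_note(
      note_id = nid, patient_id = pid,
      encounter_date = enrollment + offsets[j],
      latent = latent, specialty = specs[j], config = config,
      intake = (j == 1L),
      history_override = if (dup_history && specs[j] == "physical therapy")
        dup_text else NULL)
    notes[[j]] <- rn$note
    tags[[j]] <- rn$tags
  }
  list(
    patient = tibble::tibble(patient_id = pid, dob = dob,
                             enrollment_date = enrollment),
    notes = dplyr::bind_rows(notes),
    assessments = assessments,
    truth = tibble::tibble(
      patient_id = pid, verbal = latent$verbal,
      ambulatory = latent$ambulatory, gmfcs_class = latent$gmfcs_class,
      vss_class = latent$vss_class, cfcs_class = latent$cfcs_class,
      age_at_enrollment = age_enroll, dup_history = dup_history),
    tags = dplyr::bind_rows(tags)
  )
}

draw_latent <- function(pid, config) {
  verbal <- if (stats::runif(1) < config$latent_prevalence[["verbal"]])
    "yes" else "no"
  ambulatory <- if (stats::runif(1) < config$latent_prevalence[["ambulatory"]])
    "yes" else "no"
  list(patient_id = pid, verbal = verbal, ambulatory = ambulatory,
       gmfcs_class = NA_integer_, vss_class = NA_integer_,
       cfcs_class = NA_integer_)
}

#' Generate assessment records consistent with a latent truth
#'
#' Inverts the published assessment-to-label mappings: scale classes are
#' drawn from exactly the classes that map back to the latent binary
#' labels at the given age, so
#' `resolve_cohort_truth(generate_assessments(...))` recovers the latent
#' truth for every patient. BGR-style patients receive CARS-2, a
#' telehealth screener response, and a GMFCS class; CP-style patients
#' receive GMFCS, VSS, and CFCS classes. (M-CHAT-R is a 16-30-month
#' toddler screen and ages here are 3-18, so it is mapped but never
#' generated.)
#'
#' @param latent A latent-truth list or one-row tibble with `patient_id`,
#'   `verbal`, `ambulatory` (yes/no). Scale-class fields, if present and
#'   `NA`, are filled in by this call via the environment of the returned
#'   records.
#' @param age Age in years at assessment (>= 3, <= 18 for GMFCS).
#' @param style `"BGR"` or `"CP"`.
#' @return A tibble of assessment records; the attribute `"latent"` holds
#'   the latent list with drawn scale classes filled in.
#' @export
generate_assessments <- function(latent, age, style = c("BGR", "CP")) {
  style <- arg_match(style)
  latent <- as.list(latent)
  if (age < 3) {
    abort("Assessment ages below 3 are outside the mapped range.",
          class = "notepheno_domain_error")
  }
  gmfcs_pool <- if (age < 4) {
    if (latent$ambulatory == "yes") 1L else 2:5
  } else {
    if (latent$ambulatory == "yes") 1:2 else 3:5
  }
  latent$gmfcs_class <- sample1(gmfcs_pool)
  latent$vss_class <- if (latent$verbal == "yes") sample1(1:3) else 4L
  latent$cfcs_class <- if (latent$verbal == "yes") sample1(1:4) else 5L

  recs <- if (style == "BGR") {
    tibble::tibble(
      patient_id = latent$patient_id,
      instrument = c("CARS2", "TELEHEALTH", "GMFCS"),
      response = c(latent$verbal, latent$verbal,
                   as.character(latent$gmfcs_class)),
      age_at_assessment = age)
  } else {
    tibble::tibble(
      patient_id = latent$patient_id,
      instrument = c("GMFCS", "VSS", "CFCS"),
      response = as.character(c(latent$gmfcs_class, latent$vss_class,
                                latent$cfcs_class)),
      age_at_assessment = age)
  }
  attr(recs, "latent") <- latent
  recs
}

#' Render one synthetic clinical note
#'
#' Assembles note text from templated history, exam, and plan sections.
#' Whether the note states each ability is drawn from the informative rate
#' (full rate for the author specialty's primary question, half for the
#' other); an informative sentence agrees with the latent truth except at
#' the contradiction rate. Leakage sentences embed a scale mention for the
#' scrubber to remove. The rendered word count is at least the configured
#' minimum.
#'
#' @param note_id,patient_id,encounter_date Note identity fields.
#' @param latent Latent-truth list (with scale classes filled in).
#' @param specialty Author specialty (must be in the configured mix).
#' @param config A [cohort_config()].
#' @param intake If `TRUE`, the note documents both abilities whenever
#'   `informative_rate > 0` (an intake evaluation).
#' @param history_override Verbatim history section shared across a
#'   patient's serial physical-therapy notes, or `NULL`.
#' @return A list with `note` (one-row note tibble) and `tags` (one row per
#'   question: stance `"yes"`/`"no"`/`"none"`, plus a leakage flag).
#' @export
render_note <- function(note_id, patient_id, encounter_date, latent,
                        specialty, config, intake = FALSE,
                        history_override = NULL) {
  if (!specialty %in% names(config$specialty_mix)) {
    abort(sprintf("Specialty '%s' is not in the configured mix.", specialty),
          class = "notepheno_config_error")
  }
  primary <- SPECIALTY_PRIMARY_QUESTION[[specialty]] %||% "ambulatory"

  stance <- c(verbal = "none", ambulatory = "none")
  sentences <- character()
  for (q in QUESTIONS) {
    p <- if (intake && config$informative_rate > 0) 1 else
      config$informative_rate * if (q == primary) 1 else 0.5
    if (stats::runif(1) < p) {
      s <- if (stats::runif(1) < config$contradiction_rate)
        setdiff(c("yes", "no"), latent[[q]]) else latent[[q]]
      stance[[q]] <- s
      sentences <- c(sentences, sample(SENTENCE_BANK[[q]][[s]], 1L))
    }
  }

  leak <- stats::runif(1) < config$leakage_rate
  leak_sentence <- if (leak) leakage_sentence(latent) else NULL

  history <- history_override %||%
    paste("History:", paste(sample(FILLER$history, 2L), collapse = " "))
  exam <- paste("Exam:",
                paste(c(sample(FILLER$exam, 2L), sentences, leak_sentence),
                      collapse = " "))
  plan <- paste("Plan:", sample(FILLER$plan, 1L))

  target <- sample1(seq(config$note_length_words$min,
                        config$note_length_words$max))
  body <- paste(c(sprintf("PROGRESS NOTE (%s)", specialty),
                  history, exam, plan), collapse = "\n\n")
  n <- count_words(body)
  if (n < target) {
    pad <- rep(FILLER$padding, length.out = ceiling(
      (target - n) / min(vapply(FILLER$padding, count_words, numeric(1)))))
    k <- cumsum(count_words(pad))
    pad <- pad[seq_len(which(n + k >= target)[1])]
    body <- paste(c(body, "", "Additional documentation:",
                    paste(pad, collapse = " ")), collapse = "\n")
  }

  list(
    note = tibble::tibble(
      note_id = note_id, patient_id = patient_id, note_type = "progress",
      specialty = specialty, encounter_date = as.Date(encounter_date),
      text = body),
    tags = tibble::tibble(
      note_id = note_id, patient_id = patient_id,
      question = QUESTIONS,
      stance = unname(stance[QUESTIONS]),
      truth = unname(unlist(latent[QUESTIONS])),
      leakage = leak, specialty = specialty)
  )
}
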