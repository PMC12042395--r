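# Note inclusion criteria and assessment-score leakage scrubbing.

DEFAULT_SCRUB_PHRASES <- c("gmfcs", "gross motor function",
                           "gross motor function cs", "vss",
                           "viking speech", "cfcs")

#' Age in decimal years at a given date
#'
#' Exact day-count divided by 365.25; monotone in `on`.
#'
#' @param dob Date of birth (`Date`, vectorised).
#' @param on Date at which to evaluate the age (`Date`, vectorised).
#' @return Age in years.
#' @export
age_at <- function(dob, on) {
  dob <- as.Date(dob); on <- as.Date(on)
  if (any(on < dob)) {
    abort("`on` precedes `dob`.", class = "notepheno_domain_error")
  }
  as.numeric(on - dob) / 365.25
}

#' Note-selection criteria
#'
#' The inclusion rules applied to a raw note pull, in a fixed order:
#' note type, author specialty, ground-truth availability, patient age at
#' the encounter, a window around the ground-truth creation date, a minimum
#' word count, and finally a minimum per-patient count of *surviving* notes
#' (so "at least 5 remaining notes" is evaluated after all other rules).
#' All thresholds are inclusive (`>=`).
#'
#' @param allowed_note_types Character set, or `NULL` to allow all.
#'   Default `"progress"`.
#' @param allowed_specialties Character set, or `NULL` to allow all. The
#'   reference workflow used a 14-specialty clinician whitelist; it is a
#'   configuration value here.
#' @param min_age_years Minimum patient age at the encounter (default 3).
#' @param min_notes_per_patient Minimum surviving notes per patient
#'   (default 5).
#' @param min_words Minimum whitespace-delimited word count (default 0;
#'   500 for CP-style selection).
#' @param window_years Two-sided window (in years) around the patient's
#'   enrollment/ground-truth creation date, or `NULL` for no window
#'   (1.5 when restricting to notes near ground-truth creation).
#' @param require_ground_truth Drop notes of patients without any
#'   ground-truth label (default `TRUE`).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(allowed_note_types = "progress",
                               allowed_specialties = NULL,
                               min_age_years = 3,
                               min_notes_per_patient = 5,
                               min_words = 0,
                               window_years = NULL,
                               require_ground_truth = TRUE) {
  for (nm in c("min_age_years", "min_words")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(sprintf("`%s` must be a nonnegative number.", nm),
            class = "notepheno_config_error")
    }
  }
  assert_count(min_notes_per_patient, "min_notes_per_patient", min = 0)
  if (!is.null(window_years) &&
      (!is.numeric(window_years) || window_years < 0)) {
    abort("`window_years` must be NULL or a nonnegative number.",
          class = "notepheno_config_error")
  }
  structure(list(allowed_note_types = allowed_note_types,
                 allowed_specialties = allowed_specialties,
                 min_age_years = min_age_years,
                 min_notes_per_patient = min_notes_per_patient,
                 min_words = min_words,
                 window_years = window_years,
                 require_ground_truth = require_ground_truth),
            class = "selection_criteria")
}

#' Apply note-selection criteria
#'
#' Applies the rules of [selection_criteria()] in their fixed order and
#' returns the surviving notes together with a per-rule exclusion tally.
#' The tally entries sum to `nrow(notes) - nrow(kept)`. Filtering an
#' already-filtered corpus removes nothing (idempotence).
#'
#' @param notes Note tibble ([read_notes()]).
#' @param patients Patient tibble ([read_patients()]); supplies `dob` and
#'   `enrollment_date` (the window anchor).
#' @param truths Ground-truth tibble ([read_truth()]); used by the
#'   ground-truth-availability rule.
#' @param criteria A [selection_criteria()] object.
#' @return A list with `notes` (kept tibble) and `tally` (tibble of
#'   `rule`, `n_removed`).
#' @export
filter_notes <- function(notes, patients, truths, criteria) {
  stopifnot(inherits(criteria, "selection_criteria"))
  notes <- tibble::as_tibble(notes)
  unknown <- setdiff(unique(notes$patient_id), patients$patient_id)
  if (length(unknown)) {
    abort(sprintf("Note references unknown patient '%s'.", unknown[1]),
          class = "notepheno_schema_error")
  }
  tally <- list()
  keep_step <- function(df, keep, rule) {
    tally[[rule]] <<- sum(!keep)
    df[keep, , drop = FALSE]
  }

  df <- notes
  if (!is.null(criteria$allowed_note_types)) {
    df <- keep_step(df, df$note_type %in% criteria$allowed_note_types,
                    "note_type")
  } else tally[["note_type"]] <- 0L
  if (!is.null(criteria$allowed_specialties)) {
    df <- keep_step(df, df$specialty %in% criteria$allowed_specialties,
                    "specialty")
  } else tally[["specialty"]] <- 0L
  if (isTRUE(criteria$require_ground_truth)) {
    df <- keep_step(df, df$patient_id %in% unique(truths$patient_id),
                    "ground_truth")
  } else tally[["ground_truth"]] <- 0L

  pat <- patients[match(df$patient_id, patients$patient_id), ]
  ages <- as.numeric(df$encounter_date - pat$dob) / 365.25
  df <- keep_step(df, ages >= criteria$min_age_years, "age")

  if (!is.null(criteria$window_years)) {
    pat <- patients[match(df$patient_id, patients$patient_id), ]
    delta <- abs(as.numeric(df$encounter_date - pat$enrollment_date)) / 365.25
    df <- keep_step(df, delta <= criteria$window_years, "window")
  } else tally[["window"]] <- 0L

  df <- keep_step(df, count_words(df$text) >= criteria$min_words,
                  "min_words")

  counts <- table(df$patient_id)
  enough <- names(counts)[counts >= criteria$min_notes_per_patient]
  df <- keep_step(df, df$patient_id %in% enough, "min_notes_per_patient")

  list(notes = df,
       tally = tibble::tibble(rule = names(tally),
                              n_removed = as.integer(unlist(tally))))
}

#' Leakage-scrub configuration
#'
#' The phrases whose mentions (plus surrounding characters) are removed
#' from note text so that extraction cannot read the ground-truth scale
#' scores directly. Defaults are the six score-name phrases with a 15
#' character window on each side, matched case-insensitively.
#'
#' @param phrases Character vector of phrases to remove.
#' @param window_chars Characters removed before and after each match
#'   (default 15).
#' @param case_sensitive Match case-sensitively (default `FALSE`).
#' @return A `scrub_config` list.
#' @export
scrub_config <- function(phrases = DEFAULT_SCRUB_PHRASES,
                         window_chars = 15, case_sensitive = FALSE) {
  if (!is.character(phrases) || length(phrases) == 0L ||
      any(!nzchar(phrases))) {
    abort("`phrases` must be non-empty strings.",
          class = "notepheno_config_error")
  }
  assert_count(window_chars, "window_chars", min = 0)
  structure(list(phrases = phrases, window_chars = window_chars,
                 case_sensitive = case_sensitive),
            class = "scrub_config")
}

#' Remove ground-truth score mentions from note text
#'
#' For each configured phrase, every occurrence plus `window_chars`
#' characters on both sides is deleted. All match spans on the current text
#' are located first, expanded, clipped to the string bounds, merged where
#' they overlap, and deleted simultaneously; the pass repeats until no
#' phrase remains, so deletion that juxtaposes characters into a fresh
#' match (e.g. `"gmgmfcsfcs"`) still ends with a phrase-free string.
#'
#' @param text Character vector of note texts.
#' @param config A [scrub_config()].
#' @return Scrubbed character vector, same length as `text`.
#' @export
scrub_leakage <- function(text, config = scrub_config()) {
  stopifnot(inherits(config, "scrub_config"))
  vapply(text, scrub_one, character(1), config = config, USE.NAMES = FALSE)
}

scrub_one <- function(text, config) {
  if (is.na(text) || !nzchar(text)) return(text %||% "")
  repeat {
    spans <- locate_phrase_spans(text, config)
    if (nrow(spans) == 0L) return(text)
    spans$start <- pmax(spans$start - config$window_chars, 1L)
    spans$end <- pmin(spans$end + config$window_chars, nchar(text))
    spans <- merge_spans(spans)
    text <- delete_spans(text, spans)
  }
}

locate_phrase_spans <- function(text, config) {
  hay <- if (config$case_sensitive) text else tolower(text)
  out <- lapply(config$phrases, function(p) {
    needle <- if (config$case_sensitive) p else tolower(p)
    m <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer(), end = integer()) else out
}

merge_spans <- function(spans) {
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  starts <- spans$start[1]; ends <- spans$end[1]
  for (i in seq_len(nrow(spans))[-1]) {
    k <- length(starts)
    if (spans$start[i] <= ends[k] + 1L) {
      ends[k] <- max(ends[k], spans$end[i])
    } else {
      starts <- c(starts, spans$start[i]); ends <- c(ends, spans$end[i])
    }
  }
  data.frame(start = starts, end = ends)
}

delete_spans <- function(text, spans) {
  keep_start <- c(1L, spans$end + 1L)
  keep_end <- c(spans$start - 1L, nchar(text))
  pieces <- substring(text, keep_start, keep_end)
  paste(pieces[keep_end >= keep_start], collapse = "")
}
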