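# Canonical data model and readers/writers for notes, assessments,
# predictions, patients, and ground-truth labels.
#
# Conventions: dates are ISO-8601 strings on disk and `Date` objects in
# memory; note text is stored verbatim (scrubbing and case-folding happen in
# the preprocess stage, never at I/O time). JSONL is the primary note format
# because free text embeds newlines and quotes; CSV serves tabular records.

NOTE_FIELDS <- c("note_id", "patient_id", "note_type", "specialty",
                 "encounter_date", "text")

#' Read clinical notes from disk
#'
#' Reads a note corpus from JSONL (one object per line, the primary format)
#' or CSV. Each record must carry `note_id`, `patient_id`, `note_type`,
#' `specialty`, `encounter_date` (ISO-8601), and `text`. Row order is
#' preserved and text is returned verbatim.
#'
#' @param path File to read.
#' @param dialect `"jsonl"` or `"csv"`.
#' @return A tibble with one row per note; `encounter_date` is a `Date`.
#' @export
read_notes <- function(path, dialect = c("jsonl", "csv")) {
  dialect <- arg_match(dialect)
  df <- read_records(path, dialect, NOTE_FIELDS)
  df$encounter_date <- parse_iso_date(df$encounter_date, "encounter_date",
                                      df$note_id)
  validate_notes(df)
}

#' Write clinical notes to disk
#'
#' Inverse of [read_notes()]: `read_notes(write_notes(x, p), ...)` returns
#' `x` field-for-field, with note text preserved byte-for-byte (including
#' embedded newlines, commas, and quotes).
#'
#' @param notes A note tibble as returned by [read_notes()] or
#'   [generate_cohort()].
#' @inheritParams read_notes
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path, dialect = c("jsonl", "csv")) {
  dialect <- arg_match(dialect)
  notes <- validate_notes(notes)
  out <- notes[NOTE_FIELDS]
  out$encounter_date <- format(out$encounter_date, "%Y-%m-%d")
  write_records(out, path, dialect)
}

validate_notes <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$note_id)) {
    dup <- df$note_id[duplicated(df$note_id)][1]
    abort(sprintf("Duplicate note_id '%s' in corpus.", dup),
          class = "notepheno_schema_error")
  }
  df$text[is.na(df$text)] <- ""
  for (f in setdiff(NOTE_FIELDS, c("encounter_date", "text"))) {
    if (any(is.na(df[[f]]))) {
      abort(sprintf("Missing value in required field '%s'.", f),
            class = "notepheno_schema_error")
    }
  }
  df
}

#' Read or write patient demographics
#'
#' Patients carry `patient_id`, `dob`, and `enrollment_date` (the date
#' ground-truth annotations were created / registry enrollment). `dob` must
#' not postdate `enrollment_date`.
#'
#' @param path CSV file.
#' @return A tibble with `Date` columns.
#' @export
read_patients <- function(path) {
  df <- read_records(path, "csv", c("patient_id", "dob", "enrollment_date"))
  df$dob <- parse_iso_date(df$dob, "dob", df$patient_id)
  df$enrollment_date <- parse_iso_date(df$enrollment_date, "enrollment_date",
                                       df$patient_id)
  validate_patients(df)
}

#' @rdname read_patients
#' @param patients Patient tibble.
#' @export
write_patients <- function(patients, path) {
  patients <- validate_patients(patients)
  out <- patients[c("patient_id", "dob", "enrollment_date")]
  out$dob <- format(out$dob, "%Y-%m-%d")
  out$enrollment_date <- format(out$enrollment_date, "%Y-%m-%d")
  write_records(out, path, "csv")
}

validate_patients <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$patient_id)) {
    abort("Duplicate patient_id.", class = "notepheno_schema_error")
  }
  bad <- which(df$dob > df$enrollment_date)
  if (length(bad)) {
    abort(sprintf("Patient '%s': dob postdates enrollment_date.",
                  df$patient_id[bad[1]]),
          class = "notepheno_schema_error")
  }
  df
}

INSTRUMENT_RANGES <- list(
  CARS2 = c("yes", "no"), TELEHEALTH = c("yes", "no"),
  MCHAT_R = c("yes", "no"),
  GMFCS = as.character(1:5), VSS = as.character(1:4), CFCS = as.character(1:5)
)

#' Read or write assessment records
#'
#' Assessment records carry `patient_id`, `instrument` (one of CARS2,
#' TELEHEALTH, GMFCS, MCHAT_R, VSS, CFCS), `response` (yes/no for the binary
#' instruments; an integer class for the ordinal scales: GMFCS 1-5, VSS 1-4,
#' CFCS 1-5) and `age_at_assessment` in decimal years. Reading validates
#' every response against its instrument's range.
#'
#' @param path CSV file.
#' @return A tibble of assessment records; `response` is character.
#' @export
read_assessments <- function(path) {
  df <- read_records(path, "csv",
                     c("patient_id", "instrument", "response",
                       "age_at_assessment"))
  df$age_at_assessment <- as.numeric(df$age_at_assessment)
  validate_assessments(df)
}

#' @rdname read_assessments
#' @param assessments Assessment tibble.
#' @export
write_assessments <- function(assessments, path) {
  assessments <- validate_assessments(assessments)
  write_records(
    assessments[c("patient_id", "instrument", "response",
                  "age_at_assessment")],
    path, "csv")
}

validate_assessments <- function(df) {
  df <- tibble::as_tibble(df)
  df$response <- tolower(as.character(df$response))
  bad_inst <- setdiff(unique(df$instrument), INSTRUMENTS)
  if (length(bad_inst)) {
    abort(sprintf("Unknown instrument '%s'.", bad_inst[1]),
          class = "notepheno_schema_error")
  }
  for (i in seq_len(nrow(df))) {
    rng <- INSTRUMENT_RANGES[[df$instrument[i]]]
    if (!df$response[i] %in% rng) {
      abort(sprintf(
        "Row %d: response '%s' out of range for %s (allowed: %s).",
        i, df$response[i], df$instrument[i], paste(rng, collapse = ", ")),
        class = "notepheno_validation_error")
    }
  }
  if (any(is.na(df$age_at_assessment) | df$age_at_assessment < 0)) {
    abort("age_at_assessment must be >= 0.",
          class = "notepheno_validation_error")
  }
  df
}

PREDICTION_FIELDS <- c("note_id", "patient_id", "note_type", "verbal",
                       "ambulatory", "mode", "backend_id")

#' Read or write note-level predictions
#'
#' One row per note with the extractor's answers to both questions
#' (`verbal`, `ambulatory`, each in yes/no/unknown), the prompting `mode`
#' (MCP allows abstention, BCP does not) and the `backend_id` of the
#' extractor. Under BCP, `unknown` answers are rejected on read and write.
#'
#' @param path CSV file.
#' @return A prediction tibble.
#' @export
read_predictions <- function(path) {
  df <- read_records(path, "csv", PREDICTION_FIELDS)
  validate_predictions(df)
}

#' @rdname read_predictions
#' @param predictions Prediction tibble.
#' @export
write_predictions <- function(predictions, path) {
  predictions <- validate_predictions(predictions)
  write_records(predictions[PREDICTION_FIELDS], path, "csv")
}

validate_predictions <- function(df) {
  df <- tibble::as_tibble(df)
  for (q in QUESTIONS) {
    bad <- setdiff(unique(df[[q]]), ANSWERS)
    if (length(bad)) {
      abort(sprintf("Invalid %s answer '%s'.", q, bad[1]),
            class = "notepheno_validation_error")
    }
  }
  if (any(!df$mode %in% c("MCP", "BCP"))) {
    abort("mode must be 'MCP' or 'BCP'.",
          class = "notepheno_validation_error")
  }
  bcp <- df$mode == "BCP"
  if (any(bcp & (df$verbal == "unknown" | df$ambulatory == "unknown"))) {
    bad_id <- df$note_id[bcp &
      (df$verbal == "unknown" | df$ambulatory == "unknown")][1]
    abort(sprintf(
      "Note '%s': 'unknown' answer under BCP mode (abstention not permitted).",
      bad_id), class = "notepheno_validation_error")
  }
  df
}

#' Read or write individual-level ground-truth labels
#'
#' One row per (patient, question) with a binary `label` and the `sources`
#' (instruments) that produced it, joined by `;` on disk.
#'
#' @param path CSV file.
#' @return A tibble with columns patient_id, question, label, sources.
#' @export
read_truth <- function(path) {
  df <- read_records(path, "csv",
                     c("patient_id", "question", "label", "sources"))
  validate_truth(df)
}

#' @rdname read_truth
#' @param truth Ground-truth tibble.
#' @export
write_truth <- function(truth, path) {
  truth <- validate_truth(truth)
  write_records(truth[c("patient_id", "question", "label", "sources")],
                path, "csv")
}

validate_truth <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(df$question %in% QUESTIONS)) {
    abort("question must be 'verbal' or 'ambulatory'.",
          class = "notepheno_validation_error")
  }
  if (!all(df$label %in% c("yes", "no"))) {
    abort("ground-truth label must be 'yes' or 'no'.",
          class = "notepheno_validation_error")
  }
  if (anyDuplicated(df[c("patient_id", "question")])) {
    abort("More than one ground-truth label for a (patient, question) pair.",
          class = "notepheno_validation_error")
  }
  df
}

# --- low-level record I/O ---------------------------------------------------

read_records <- function(path, dialect, required) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "notepheno_io_error")
  }
  if (dialect == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        abort(sprintf("Line %d: malformed JSON (%s).", i,
                                      conditionMessage(e)),
                              class = "notepheno_schema_error")
                      })
      missing <- setdiff(required, names(rec))
      if (length(missing)) {
        abort(sprintf("Line %d: missing required field '%s'.", i, missing[1]),
              class = "notepheno_schema_error")
      }
      rows[[i]] <- rec[required]
    }
    df <- tibble::as_tibble(do.call(rbind.data.frame,
                                    c(rows, stringsAsFactors = FALSE)))
    if (length(rows) == 0L) {
      df <- tibble::as_tibble(stats::setNames(
        rep(list(character()), length(required)), required))
    }
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      abort(sprintf("Missing required column '%s' in %s.", missing[1], path),
            class = "notepheno_schema_error")
    }
    df <- df[required]
    for (f in required) df[[f]] <- as.character(df[[f]])
    # A field that is NA in every row of a non-empty file means the column
    # was absent content-wise; blank cells surface as NA and are caught by
    # the per-type validators.
  }
  na_req <- setdiff(required, c("text", "sources"))
  for (f in na_req) {
    bad <- which(is.na(df[[f]]))
    if (length(bad)) {
      abort(sprintf("Row %d: missing required field '%s'.", bad[1], f),
            class = "notepheno_schema_error")
    }
  }
  df
}

write_records <- function(df, path, dialect) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

parse_iso_date <- function(x, field, ids) {
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- suppressWarnings(as.Date(x[ok], format = "%Y-%m-%d"))
  bad <- which(is.na(out))
  if (length(bad)) {
    abort(sprintf("Record '%s': unparseable %s '%s' (expect YYYY-MM-DD).",
                  ids[bad[1]], field, x[bad[1]]),
          class = "notepheno_parse_error")
  }
  out
}
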