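# Prompt construction, response parsing, and the pluggable extractor
# backend contract, plus a deterministic mock backend for desk-scale runs.

NOTE_MARKER <- "CLINICAL NOTE:\n"

#' Conversational prompt template
#'
#' The prompt has four components, delivered as a conversational exchange:
#' (1) a system message casting the model as a physician extracting verbal
#' and ambulatory ability from a clinical note, followed by a fixed
#' user/assistant confirmation turn; (2) definitions of the two abilities,
#' including the clarification that walking with a walking aid does not
#' count as walking without aid; (3) an exemplar of the required structured
#' output (two lines, `words: <answer>` and `walk: <answer>`); and (4) the
#' clinical note text, substituted at the `{}` placeholder. Multi-class
#' prompts (MCP) admit `unknown`; binary-class prompts (BCP) restrict
#' answers to yes/no.
#'
#' @param mode `"MCP"` or `"BCP"`.
#' @param system_text,definitions_text,output_format_text Optional
#'   overrides for the individual components.
#' @return A `prompt_template` object.
#' @export
prompt_template <- function(mode = c("MCP", "BCP"), system_text = NULL,
                            definitions_text = NULL,
                            output_format_text = NULL) {
  mode <- arg_match(mode)
  answers <- if (mode == "MCP") "'yes', 'no', or 'unknown'" else
    "'yes' or 'no'"
  system_text <- system_text %||% paste(
    "You are a medical physician reviewing a clinical note.",
    "Your goal is to extract the individual's verbal and ambulatory",
    "ability using only information found in the note.")
  definitions_text <- definitions_text %||% paste0(
    "Answer two questions about the individual described in the note.\n",
    "1. Does the individual use any words? Using words means producing ",
    "any number of words via motor speech.\n",
    "2. Can the individual walk without aid? Walking without aid means ",
    "walking independently without any assistance or walking devices; ",
    "someone who walks with a walking aid should not be considered ",
    "'able to walk'.\n",
    "Answer each question with ", answers,
    if (mode == "MCP") ", using 'unknown' when the note does not say."
    else ".")
  output_format_text <- output_format_text %||% paste0(
    "Respond in exactly this format:\nwords: <answer>\nwalk: <answer>")
  tpl <- structure(list(
    system_text = system_text,
    confirm_user = "Do you understand your role?",
    confirm_assistant = paste("Yes. I will read the clinical note and",
                              "answer both questions in the required",
                              "format."),
    definitions_text = definitions_text,
    output_format_text = output_format_text,
    mode = mode, note_placeholder = "{}"), class = "prompt_template")
  validate_template(tpl)
}

validate_template <- function(template) {
  assembled <- paste(template$system_text, template$confirm_user,
                     template$confirm_assistant, template$definitions_text,
                     template$output_format_text, final_user_text(template),
                     sep = "\n")
  n <- stringr::str_count(assembled,
                          stringr::fixed(template$note_placeholder))
  if (n != 1L) {
    abort(sprintf(
      "Prompt template must contain the note placeholder exactly once (found %d).",
      n), class = "notepheno_template_error")
  }
  template
}

final_user_text <- function(template) {
  paste0(template$definitions_text, "\n\n", template$output_format_text,
         "\n\n", NOTE_MARKER, template$note_placeholder)
}

#' Truncate a note to a backend's context limit
#'
#' Keeps the first `limit` characters and discards the rest; with
#' `limit = NULL` the text is returned unchanged. Truncation counts
#' characters, not tokens (a 10,000-character limit suits a small-context
#' backend).
#'
#' @param text Character vector.
#' @param limit Character budget, or `NULL` for none.
#' @return Truncated character vector.
#' @export
truncate_note <- function(text, limit = NULL) {
  if (is.null(limit)) return(text)
  if (!is.numeric(limit) || limit < 0) {
    abort("`limit` must be NULL or a nonnegative number.",
          class = "notepheno_config_error")
  }
  substr(text, 1L, as.integer(limit))
}

#' Assemble the message sequence for one note
#'
#' Produces the conversational sequence: system message, the fixed
#' confirmation exchange, and a final user message with the note text
#' substituted verbatim at the placeholder.
#'
#' @param template A [prompt_template()].
#' @param note_text The (already truncated, already scrubbed) note text.
#' @return A list of `list(role=, content=)` messages.
#' @export
build_prompt <- function(template, note_text) {
  stopifnot(inherits(template, "prompt_template"))
  validate_template(template)
  final <- final_user_text(template)
  parts <- strsplit(final, template$note_placeholder, fixed = TRUE)[[1]]
  final <- paste0(parts[1], note_text,
                  if (length(parts) > 1L) parts[2] else "")
  list(
    list(role = "system", content = template$system_text),
    list(role = "user", content = template$confirm_user),
    list(role = "assistant", content = template$confirm_assistant),
    list(role = "user", content = final)
  )
}

#' Parse a raw extractor response
#'
#' Tolerant parsing of the structured two-line answer: per-question answers
#' are located case-insensitively by key (`words`/`verbal` and
#' `walk`/`ambulatory`) followed by a separator and one of yes/no/unknown.
#' Under MCP an unparseable response degrades to `(unknown, unknown)` with
#' a warning; under BCP an unparseable or `unknown` answer is a protocol
#' violation and raises.
#'
#' @param raw Raw response string.
#' @param mode `"MCP"` or `"BCP"`.
#' @param note_id Used in warnings/errors to name the note.
#' @return Named character vector `c(verbal=, ambulatory=)`.
#' @export
parse_response <- function(raw, mode = c("MCP", "BCP"), note_id = NA) {
  mode <- arg_match(mode)
  verbal <- match_answer(raw, "(?:words?|verbal)")
  walk <- match_answer(raw, "(?:walks?|walking|ambulat\\w*)")
  if (is.na(verbal) || is.na(walk)) {
    if (mode == "BCP") {
      abort(sprintf("Note '%s': unparseable BCP response: %s", note_id,
                    substr(raw %||% "", 1, 80)),
            class = "notepheno_protocol_error")
    }
    warn(sprintf("Note '%s': unparseable response, recording unknown/unknown.",
                 note_id), class = "notepheno_parse_warning")
    return(c(verbal = "unknown", ambulatory = "unknown"))
  }
  if (mode == "BCP" && (verbal == "unknown" || walk == "unknown")) {
    abort(sprintf(
      "Note '%s': 'unknown' answer under BCP (abstention not permitted).",
      note_id), class = "notepheno_protocol_error")
  }
  c(verbal = verbal, ambulatory = walk)
}

match_answer <- function(raw, key_pattern) {
  if (is.null(raw) || is.na(raw)) return(NA_character_)
  pat <- paste0("(?i)\\b", key_pattern,
                "\\b\\s*[:=-]\\s*['\"]?(yes|no|unknown)\\b")
  m <- stringr::str_match(raw, pat)
  if (is.na(m[1, 2])) NA_character_ else tolower(m[1, 2])
}

#' Extractor backend contract
#'
#' A backend is an id, an optional context character limit (notes are
#' truncated to it before prompting), and a `complete(messages)` function
#' returning the raw response string. Any chat-completion client can be
#' wrapped by supplying its call as `complete`; deterministic backends must
#' return identical output for identical input. [mock_backend()] implements
#' the contract without any external service.
#'
#' @param backend_id Identifier recorded in predictions.
#' @param complete `function(messages) -> character(1)`.
#' @param context_char_limit Character budget, or `NULL`.
#' @return An `extractor_backend` object.
#' @export
extractor_backend <- function(backend_id, complete,
                              context_char_limit = NULL) {
  stopifnot(is.character(backend_id), is.function(complete))
  structure(list(backend_id = backend_id, complete = complete,
                 context_char_limit = context_char_limit),
            class = "extractor_backend")
}

#' Deterministic mock extractor backend
#'
#' A keyword/negation-pattern classifier over the synthetic template bank's
#' phrase inventory, standing in for a live language model so the pipeline
#' runs at desk scale. Within each question, negation patterns take
#' precedence (a note describing aided walking is "no" for walking without
#' aid); if no pattern fires the answer is `unknown` under MCP or the
#' configured fallback under BCP. A seeded error rate replaces each answer,
#' independently per question, with a uniform draw from the other
#' admissible answers -- the noise source for degradation experiments. The
#' injected noise is a deterministic function of (note text, seed), so
#' identical inputs always produce identical output.
#'
#' @param mode `"MCP"` or `"BCP"`.
#' @param error_rate Per-question probability of corrupting the answer.
#' @param seed Seed for the error stream.
#' @param bcp_fallback Answer recorded under BCP when no pattern fires
#'   (default `"no"`).
#' @param context_char_limit Optional character budget, to emulate a
#'   small-context model.
#' @return An `extractor_backend`.
#' @export
mock_backend <- function(mode = c("MCP", "BCP"), error_rate = 0, seed = 0L,
                         bcp_fallback = "no", context_char_limit = NULL) {
  mode <- arg_match(mode)
  assert_probability(error_rate, "error_rate")
  assert_choice(bcp_fallback, c("yes", "no"), "bcp_fallback")
  complete <- function(messages) {
    final <- messages[[length(messages)]]$content
    idx <- regexpr(NOTE_MARKER, final, fixed = TRUE)
    note_text <- if (idx > 0)
      substr(final, idx + nchar(NOTE_MARKER), nchar(final)) else final
    ans <- classify_note_text(note_text, mode, bcp_fallback)
    if (error_rate > 0) {
      ans <- with_seed(string_seed(note_text, salt = seed), {
        admissible <- if (mode == "MCP") ANSWERS else c("yes", "no")
        for (q in QUESTIONS) {
          if (stats::runif(1) < error_rate) {
            ans[[q]] <- sample1(setdiff(admissible, ans[[q]]))
          }
        }
        ans
      })
    }
    sprintf("words: %s\nwalk: %s", ans[["verbal"]], ans[["ambulatory"]])
  }
  extractor_backend(
    backend_id = sprintf("mock-%s-e%g", tolower(mode), error_rate),
    complete = complete, context_char_limit = context_char_limit)
}

# Keyword/negation classification of one note text.
classify_note_text <- function(text, mode, bcp_fallback = "no") {
  ans <- c(verbal = NA_character_, ambulatory = NA_character_)
  for (q in QUESTIONS) {
    pats <- MOCK_PATTERNS[[q]]
    hit_no <- any(vapply(pats$no, function(p)
      grepl(p, text, ignore.case = TRUE, perl = TRUE), logical(1)))
    hit_yes <- any(vapply(pats$yes, function(p)
      grepl(p, text, ignore.case = TRUE, perl = TRUE), logical(1)))
    ans[[q]] <- if (hit_no) "no" else if (hit_yes) "yes" else
      if (mode == "MCP") "unknown" else bcp_fallback
  }
  ans
}

#' Run extraction over a note corpus
#'
#' For each note: truncate to the backend's context limit, assemble the
#' conversational prompt, call the backend (with bounded retries and
#' exponential backoff on transient errors), and parse the answer. Exactly
#' one prediction or one failure record is produced per note; failures are
#' recorded, never silently dropped, and the run continues past them.
#'
#' @param notes Note tibble (scrubbed text).
#' @param template A [prompt_template()]; its mode is recorded in the
#'   predictions.
#' @param backend An [extractor_backend()].
#' @param max_attempts Attempts per note before recording a failure
#'   (default 3).
#' @param backoff_base Seconds of backoff after the first failed attempt
#'   (doubles per retry; default 0 so tests run instantly).
#' @return A list with `predictions` (one row per successful note:
#'   note_id, patient_id, note_type, specialty, verbal, ambulatory, mode,
#'   backend_id, n_attempts) and `failures` (note_id, error).
#' @export
extract_corpus <- function(notes, template, backend, max_attempts = 3,
                           backoff_base = 0) {
  stopifnot(inherits(template, "prompt_template"),
            inherits(backend, "extractor_backend"))
  notes <- tibble::as_tibble(notes)
  n <- nrow(notes)
  preds <- vector("list", n)
  fails <- vector("list", n)
  for (i in seq_len(n)) {
    txt <- truncate_note(notes$text[i], backend$context_char_limit)
    msgs <- build_prompt(template, txt)
    raw <- NULL
    attempt <- 0L
    last_err <- NULL
    while (is.null(raw) && attempt < max_attempts) {
      attempt <- attempt + 1L
      raw <- tryCatch(backend$complete(msgs), error = function(e) {
        last_err <<- conditionMessage(e)
        if (backoff_base > 0) Sys.sleep(backoff_base * 2^(attempt - 1L))
        NULL
      })
    }
    if (is.null(raw)) {
      fails[[i]] <- tibble::tibble(note_id = notes$note_id[i],
                                   error = last_err %||% "backend failure",
                                   n_attempts = attempt)
      next
    }
    ans <- tryCatch(
      parse_response(raw, template$mode, note_id = notes$note_id[i]),
      notepheno_protocol_error = function(e) e)
    if (inherits(ans, "error")) {
      fails[[i]] <- tibble::tibble(note_id = notes$note_id[i],
                                   error = conditionMessage(ans),
                                   n_attempts = attempt)
      next
    }
    preds[[i]] <- tibble::tibble(
      note_id = notes$note_id[i], patient_id = notes$patient_id[i],
      note_type = notes$note_type[i],
      specialty = if ("specialty" %in% names(notes))
        notes$specialty[i] else NA_character_,
      verbal = ans[["verbal"]], ambulatory = ans[["ambulatory"]],
      mode = template$mode, backend_id = backend$backend_id,
      n_attempts = attempt)
  }
  list(predictions = dplyr::bind_rows(preds),
       failures = dplyr::bind_rows(fails))
}
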