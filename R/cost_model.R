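# Expected API cost of a prompt-based extraction run.
#
# Token counts use the 4-characters-per-token approximation; per-call cost
# is (input tokens * input price) + (expected output tokens * output
# price), prices quoted per 1,000 tokens. Total cost is
#   P * N * (avg_input_chars / chars_per_token * input_cost_per_1k / 1000
#            + output_cost_per_1k / 1000 * tokens_per_output)
# with N notes and P prompting rounds per note. Arithmetic is exact;
# rounding (half-up to cents) happens only at presentation.

#' Cost-model parameters
#'
#' @param n_notes Number of notes, N.
#' @param prompts_per_note Prompting rounds per note, P (e.g. 2 when both a
#'   multi-class and a binary prompt are run over the corpus).
#' @param avg_input_chars Mean characters of the assembled prompt including
#'   the note (see [measure_avg_input_chars()]).
#' @param input_cost_per_1k,output_cost_per_1k Price per 1,000 tokens.
#' @param tokens_per_output Expected output tokens per response (default 13,
#'   matching the two-line structured answer).
#' @param chars_per_token Characters per token (default 4).
#' @return A `cost_params` list.
#' @export
cost_params <- function(n_notes, prompts_per_note, avg_input_chars,
                        input_cost_per_1k, output_cost_per_1k,
                        tokens_per_output = 13, chars_per_token = 4) {
  vals <- list(n_notes = n_notes, prompts_per_note = prompts_per_note,
               avg_input_chars = avg_input_chars,
               input_cost_per_1k = input_cost_per_1k,
               output_cost_per_1k = output_cost_per_1k,
               tokens_per_output = tokens_per_output,
               chars_per_token = chars_per_token)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort(sprintf("`%s` must be strictly positive.", nm),
            class = "notepheno_domain_error")
    }
  }
  structure(vals, class = "cost_params")
}

#' Expected total cost of an extraction run
#'
#' @param params A [cost_params()].
#' @return A `cost_estimate` list: `input_component` and `output_component`
#'   (per call), `per_note_cost` (per call, one prompt round), `total_cost`
#'   (exact), and `total_display` (rounded half-up to cents).
#' @export
expected_cost <- function(params) {
  stopifnot(inherits(params, "cost_params"))
  input_component <- params$avg_input_chars / params$chars_per_token *
    params$input_cost_per_1k / 1000
  output_component <- params$output_cost_per_1k / 1000 *
    params$tokens_per_output
  per_note <- input_component + output_component
  total <- params$prompts_per_note * params$n_notes * per_note
  structure(list(input_component = input_component,
                 output_component = output_component,
                 per_note_cost = per_note,
                 total_cost = total,
                 total_display = round_half_up(total, 2)),
            class = "cost_estimate")
}

#' @export
print.cost_estimate <- function(x, ...) {
  cat(sprintf("Expected total cost: $%.2f (per call $%.6f = input $%.6f + output $%.6f)\n",
              x$total_display, x$per_note_cost, x$input_component,
              x$output_component))
  invisible(x)
}

#' Mean prompt length in characters over a corpus
#'
#' Mean over notes of the character length of the fully assembled prompt
#' (all message contents with the note substituted), after any backend
#' truncation.
#'
#' @param notes Note tibble.
#' @param template A [prompt_template()].
#' @param context_char_limit Optional truncation limit applied to each note
#'   before assembly.
#' @return Mean character count (numeric scalar).
#' @export
measure_avg_input_chars <- function(notes, template,
                                    context_char_limit = NULL) {
  notes <- tibble::as_tibble(notes)
  if (nrow(notes) == 0L) {
    abort("Cannot measure prompt length on an empty corpus.",
          class = "notepheno_domain_error")
  }
  template_chars <- sum(vapply(build_prompt(template, ""), function(m)
    nchar(m$content), numeric(1)))
  note_chars <- nchar(truncate_note(notes$text, context_char_limit))
  mean(template_chars + note_chars)
}
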