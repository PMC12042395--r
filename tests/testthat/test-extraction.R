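# Prompt assembly, response parsing, mock backend, and corpus extraction.

test_that("truncation keeps exactly the leading character budget", {
  long <- strrep("a", 12000)
  expect_equal(nchar(truncate_note(long, 10000)), 10000)
  expect_equal(truncate_note(long, 10000), substr(long, 1, 10000))
  expect_identical(truncate_note(long, NULL), long)
  short <- strrep("b", 9999)
  expect_identical(truncate_note(short, 10000), short)
})

test_that("build_prompt substitutes the note verbatim in a conversational sequence", {
  tpl <- prompt_template("MCP")
  note <- "X walks independently.\nSecond line, with \"quotes\"."
  msgs <- build_prompt(tpl, note)
  expect_length(msgs, 4)
  expect_equal(vapply(msgs, `[[`, "", "role"),
               c("system", "user", "assistant", "user"))
  final <- msgs[[4]]$content
  expect_true(grepl(note, final, fixed = TRUE))
  expect_true(grepl("Does the individual use any words?", final,
                    fixed = TRUE))
  expect_true(grepl("Can the individual walk without aid?", final,
                    fixed = TRUE))
})

test_that("MCP prompts admit unknown while BCP prompts do not", {
  mcp <- paste(vapply(build_prompt(prompt_template("MCP"), "x"),
                      `[[`, "", "content"), collapse = "\n")
  bcp <- paste(vapply(build_prompt(prompt_template("BCP"), "x"),
                      `[[`, "", "content"), collapse = "\n")
  expect_true(grepl("'yes', 'no', or 'unknown'", mcp, fixed = TRUE))
  expect_false(grepl("unknown", bcp, fixed = TRUE))
})

test_that("templates without exactly one placeholder are rejected", {
  expect_error(prompt_template("MCP", definitions_text = "no marker {} {}"),
               class = "notepheno_template_error")
  tpl <- prompt_template("MCP")
  tpl$definitions_text <- paste0(tpl$definitions_text, " {}")
  expect_error(build_prompt(tpl, "x"), class = "notepheno_template_error")
})

test_that("response parsing tolerates case and format variation", {
  cases <- list(
    list(raw = "words: yes\nwalk: no", want = c("yes", "no")),
    list(raw = "WORDS: Unknown | WALK: YES", want = c("unknown", "yes")),
    list(raw = "Verbal = no; Ambulatory = no", want = c("no", "no")),
    list(raw = "words:yes\nwalk:unknown", want = c("yes", "unknown")),
    list(raw = "  words : 'no'\n  walk : 'yes'", want = c("no", "yes")),
    list(raw = "Walking- no\nWords- no", want = c("no", "no")))
  for (cs in cases) {
    got <- parse_response(cs$raw, "MCP")
    expect_equal(unname(got), cs$want, info = cs$raw)
  }
})

test_that("unparseable MCP responses degrade to unknown with a warning", {
  expect_warning(
    got <- parse_response("total garbage", "MCP", note_id = "n1"),
    class = "notepheno_parse_warning")
  expect_equal(unname(got), c("unknown", "unknown"))
})

test_that("BCP refuses abstention and unparseable output", {
  expect_error(parse_response("words: yes\nwalk: unknown", "BCP", "n2"),
               "n2", class = "notepheno_protocol_error")
  expect_error(parse_response("garbage", "BCP", "n3"),
               class = "notepheno_protocol_error")
})

test_that("the mock classifier reads the template-bank phrase inventory", {
  tpl <- prompt_template("MCP")
  ask <- function(text) {
    raw <- mock_backend("MCP")$complete(build_prompt(tpl, text))
    unname(parse_response(raw, "MCP"))
  }
  expect_equal(ask("She ambulates independently across the room."),
               c("unknown", "yes"))
  # aided walking does not count as walking without aid
  expect_equal(ask("He walks only with a posterior walker."),
               c("unknown", "no"))
  expect_equal(ask("Walks independently but uses a walking aid outdoors."),
               c("unknown", "no"))
  expect_equal(ask("The patient uses single words to ask for snacks."),
               c("yes", "unknown"))
  expect_equal(ask("The patient is nonverbal at this time."),
               c("no", "unknown"))
  expect_equal(ask("Vitals stable; follow up in clinic."),
               c("unknown", "unknown"))
})

test_that("extraction conserves note counts and records retries", {
  co <- generate_cohort(cohort_config(n_patients = 5, seed = 13))
  tpl <- prompt_template("MCP")
  res <- extract_corpus(co$notes, tpl, mock_backend("MCP"))
  expect_equal(nrow(res$predictions) + nrow(res$failures), nrow(co$notes))
  expect_equal(nrow(res$failures), 0)

  # flaky backend: fails twice, then answers
  calls <- new.env(); calls$n <- 0
  flaky <- extractor_backend("flaky", function(messages) {
    calls$n <- calls$n + 1
    if (calls$n <= 2) stop("transient service error")
    "words: yes\nwalk: yes"
  })
  one <- extract_corpus(co$notes[1, ], tpl, flaky)
  expect_equal(nrow(one$predictions), 1)
  expect_equal(one$predictions$n_attempts, 3L)

  # permanently failing backend: failure recorded, run continues
  dead <- extractor_backend("dead", function(messages) stop("down"))
  res2 <- extract_corpus(co$notes[1:3, ], tpl, dead, max_attempts = 2)
  expect_equal(nrow(res2$failures), 3)
  expect_equal(nrow(res2$predictions), 0)
})

test_that("BCP extraction never produces unknown and honors the fallback", {
  co <- generate_cohort(cohort_config(n_patients = 6, seed = 23))
  res <- extract_corpus(co$notes, prompt_template("BCP"),
                        mock_backend("BCP"))
  expect_false(any(res$predictions$verbal == "unknown"))
  expect_false(any(res$predictions$ambulatory == "unknown"))
})

test_that("mock extraction is deterministic for a fixed seed, including noise", {
  co <- generate_cohort(cohort_config(n_patients = 6, seed = 29))
  tpl <- prompt_template("MCP")
  b1 <- mock_backend("MCP", error_rate = 0.3, seed = 5L)
  b2 <- mock_backend("MCP", error_rate = 0.3, seed = 5L)
  expect_identical(extract_corpus(co$notes, tpl, b1)$predictions,
                   extract_corpus(co$notes, tpl, b2)$predictions)
  b3 <- mock_backend("MCP", error_rate = 0.3, seed = 6L)
  expect_false(identical(
    extract_corpus(co$notes, tpl, b1)$predictions$verbal,
    extract_corpus(co$notes, tpl, b3)$predictions$verbal) &&
    identical(extract_corpus(co$notes, tpl, b1)$predictions$ambulatory,
              extract_corpus(co$notes, tpl, b3)$predictions$ambulatory))
})

test_that("zero-noise extraction recovers every informative note's stance", {
  co <- generate_cohort(cohort_config(n_patients = 15,
                                      contradiction_rate = 0, seed = 37))
  scrubbed <- co$notes
  scrubbed$text <- scrub_leakage(scrubbed$text)
  res <- extract_corpus(scrubbed, prompt_template("MCP"),
                        mock_backend("MCP"))
  preds <- tidyr::pivot_longer(
    res$predictions[c("note_id", "verbal", "ambulatory")],
    cols = c("verbal", "ambulatory"),
    names_to = "question", values_to = "answer")
  merged <- dplyr::inner_join(co$note_tags, preds,
                              by = c("note_id", "question"))
  informative <- merged[merged$stance != "none", ]
  expect_gt(nrow(informative), 0)
  expect_true(all(informative$answer == informative$stance))
})

test_that("an empty corpus yields empty predictions", {
  res <- extract_corpus(make_notes(0), prompt_template("MCP"),
                        mock_backend("MCP"))
  expect_equal(nrow(res$predictions), 0)
  expect_equal(nrow(res$failures), 0)
})
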