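# Note selection and leakage scrubbing.

test_that("age_at follows the day-count / 365.25 convention", {
  expect_equal(age_at(as.Date("2010-01-01"), as.Date("2013-01-01")),
               1096 / 365.25)
  expect_equal(age_at(as.Date("2010-06-15"), as.Date("2010-06-15")), 0)
  # calendar-arithmetic cross-check on a decade with leap days
  dob <- as.Date("2010-06-15"); on <- as.Date("2020-06-14")
  expect_equal(age_at(dob, on), as.numeric(on - dob) / 365.25)
  expect_equal(round(age_at(dob, on), 3), 9.999)
  expect_error(age_at(on, dob), class = "notepheno_domain_error")
})

make_filter_fixture <- function() {
  pats <- tibble::tibble(
    patient_id = c("pa", "pb", "pc"),
    dob = as.Date(c("2015-01-01", "2005-01-01", "2019-06-01")),
    enrollment_date = as.Date(c("2023-01-01", "2023-01-01", "2023-01-01")))
  truth <- tibble::tibble(patient_id = c("pa", "pb"), question = "verbal",
                          label = "yes", sources = "CARS2")
  notes <- tibble::tibble(
    note_id = sprintf("n%02d", 1:10),
    patient_id = c(rep("pa", 6), "pb", "pb", "pc", "pa"),
    note_type = c(rep("progress", 8), "progress", "telephone"),
    specialty = c(rep("neurology", 9), "neurology"),
    encounter_date = as.Date(c(rep("2022-10-01", 6), "2021-01-01",
                               "2022-12-01", "2022-12-01", "2022-10-01")),
    text = c(rep(strrep("word ", 40), 9), "short"))
  list(pats = pats, truth = truth, notes = notes)
}

test_that("filter rules apply in order and the tally accounts for every removal", {
  fx <- make_filter_fixture()
  crit <- selection_criteria(min_age_years = 3, min_notes_per_patient = 5,
                             min_words = 10, window_years = 1.5)
  res <- filter_notes(fx$notes, fx$pats, fx$truth, crit)
  # n10: wrong note type; n09: no ground truth (pc); n07: outside window;
  # pb's one surviving note then fails min_notes; pa keeps 6
  expect_setequal(res$notes$patient_id, "pa")
  expect_equal(nrow(res$notes), 6)
  tally <- setNames(res$tally$n_removed, res$tally$rule)
  expect_equal(unname(tally["note_type"]), 1)
  expect_equal(unname(tally["ground_truth"]), 1)
  expect_equal(unname(tally["window"]), 1)
  expect_equal(unname(tally["min_notes_per_patient"]), 1)
  expect_equal(sum(res$tally$n_removed),
               nrow(fx$notes) - nrow(res$notes))
})

test_that("a patient left with fewer than the minimum notes loses them all", {
  notes <- make_notes(4, patient_id = rep("p1", 4))
  pats <- tibble::tibble(patient_id = "p1", dob = as.Date("2010-01-01"),
                         enrollment_date = as.Date("2023-01-01"))
  truth <- tibble::tibble(patient_id = "p1", question = "verbal",
                          label = "yes", sources = "CARS2")
  res <- filter_notes(notes, pats, truth,
                      selection_criteria(min_notes_per_patient = 5))
  expect_equal(nrow(res$notes), 0)
  expect_equal(res$tally$n_removed[res$tally$rule == "min_notes_per_patient"],
               4L)
})

test_that("the word-count threshold is inclusive at the boundary", {
  notes <- make_notes(2, patient_id = rep("p1", 2))
  notes$text <- c(paste(rep("w", 499), collapse = " "),
                  paste(rep("w", 500), collapse = " "))
  pats <- tibble::tibble(patient_id = "p1", dob = as.Date("2010-01-01"),
                         enrollment_date = as.Date("2023-01-01"))
  truth <- tibble::tibble(patient_id = "p1", question = "verbal",
                          label = "yes", sources = "CARS2")
  res <- filter_notes(notes, pats, truth,
                      selection_criteria(min_words = 500,
                                         min_notes_per_patient = 1))
  expect_equal(res$notes$note_id, "N002")
})

test_that("permissive criteria are the identity and filtering is idempotent", {
  co <- generate_cohort(cohort_config(n_patients = 15, seed = 21))
  truth <- resolve_cohort_truth(co$assessments, "BGR")
  open_crit <- selection_criteria(allowed_note_types = NULL,
                                  allowed_specialties = NULL,
                                  min_age_years = 0,
                                  min_notes_per_patient = 0, min_words = 0,
                                  window_years = NULL,
                                  require_ground_truth = FALSE)
  res <- filter_notes(co$notes, co$patients, truth, open_crit)
  expect_equal(nrow(res$notes), nrow(co$notes))

  crit <- selection_criteria(window_years = 1.5)
  once <- filter_notes(co$notes, co$patients, truth, crit)
  twice <- filter_notes(once$notes, co$patients, truth, crit)
  expect_equal(as.data.frame(twice$notes), as.data.frame(once$notes))
  expect_true(all(twice$tally$n_removed == 0))
})

test_that("scrubbing leaves phrase-free text byte-identical", {
  texts <- c("The patient walked into clinic unremarkably.",
             "", "gm fcs v ss interleaved but harmless")
  expect_identical(scrub_leakage(texts), texts)
})

test_that("a window that covers the whole string deletes it entirely", {
  expect_identical(scrub_leakage("abc vss def"), "")
  # 15 chars each side of 'vss' spans the full 11-char string
})

test_that("scrubbed output never contains a phrase, even for adversarial splices", {
  cases <- c("gmgmfcsfcs", "vvssss", "cfcfcscs",
             "xxgross motor function csxx",
             "GMFCS and vss and Viking Speech and CFCS",
             strrep("gmfcs", 4))
  out <- scrub_leakage(cases)
  for (p in c("gmfcs", "vss", "viking speech", "cfcs",
              "gross motor function")) {
    expect_false(any(grepl(p, tolower(out), fixed = TRUE)), info = p)
  }
  expect_identical(out, vapply(cases, scrub_oracle, character(1),
                               USE.NAMES = FALSE))
})

test_that("random adversarial texts match the brute-force span-merge oracle", {
  set.seed(99)
  for (i in 1:300) {
    txt <- adversarial_text(sample(3:20, 1))
    expect_identical(scrub_leakage(txt), scrub_oracle(txt), info = txt)
  }
})

test_that("scrub config controls phrases, window, and case sensitivity", {
  cfg <- scrub_config(phrases = "abc", window_chars = 1,
                      case_sensitive = TRUE)
  expect_identical(scrub_leakage("xxABCxx", cfg), "xxABCxx")
  expect_identical(scrub_leakage("xxabcxx", cfg), "xx")
  expect_error(scrub_config(phrases = character()),
               class = "notepheno_config_error")
})
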