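# Aggregation rules, evaluation metrics, informativeness, and paired
# comparison.

test_that("majority vote excludes unknowns and resolves ties to no", {
  expect_equal(aggregate_majority(c("yes", "yes", "no", "unknown"))$label,
               "yes")
  expect_equal(aggregate_majority(c("yes", "no"))$label, "no")
  allunk <- aggregate_majority(c("unknown", "unknown"))
  expect_equal(allunk$label, "no")
  expect_true(allunk$zero_evidence)
  expect_equal(allunk[c("n_yes", "n_no", "n_unknown")],
               list(n_yes = 0L, n_no = 0L, n_unknown = 2L))
  expect_error(aggregate_majority(character()),
               class = "notepheno_domain_error")
})

test_that("any-yes flags a single yes against any number of no votes", {
  expect_equal(aggregate_any_yes(c("no", "no", "yes"))$label, "yes")
  expect_equal(aggregate_any_yes(c("no", "unknown"))$label, "no")
  expect_equal(aggregate_any_yes(c(rep("no", 100), "yes"))$label, "yes")
})

test_that("any-yes 'yes' individuals are a superset of majority 'yes' individuals", {
  set.seed(41)
  for (i in 1:50) {
    answers <- sample(c("yes", "no", "unknown"), sample(1:20, 1),
                      replace = TRUE)
    maj <- aggregate_majority(answers)$label
    any_ <- aggregate_any_yes(answers)$label
    if (maj == "yes") expect_equal(any_, "yes")
  }
})

test_that("rules agree on unanimous non-unknown prediction sets", {
  for (lab in c("yes", "no")) {
    answers <- rep(lab, 7)
    expect_equal(aggregate_majority(answers)$label,
                 aggregate_any_yes(answers)$label)
  }
})

test_that("the evaluation reproduces the hand-computed weighted F1 example", {
  # truths: 8 yes, 2 no; predictions: 7 of 8 yes correct, 1 of 2 no correct
  truth <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:10), question = "verbal",
    label = c(rep("yes", 8), rep("no", 2)))
  pred <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:10), question = "verbal",
    label = c(rep("yes", 7), "no", "no", "yes"))
  rep_ <- evaluate(pred, truth, "verbal")
  expect_equal(rep_$per_class$f1[rep_$per_class$class == "yes"], 0.875)
  expect_equal(rep_$per_class$f1[rep_$per_class$class == "no"], 0.5)
  expect_equal(rep_$weighted_f1, 0.875 * 0.8 + 0.5 * 0.2)  # 0.80
  expect_equal(rep_$macro_f1, 0.6875)
})

test_that("perfect predictions score 1 and a missed minority class is weighted by prevalence", {
  truth <- tibble::tibble(patient_id = sprintf("p%d", 1:5),
                          question = "ambulatory", label = rep("yes", 5))
  pred <- truth
  expect_equal(evaluate(pred, truth, "ambulatory")$weighted_f1, 1)

  truth2 <- dplyr::bind_rows(truth, tibble::tibble(
    patient_id = "p6", question = "ambulatory", label = "no"))
  pred2 <- dplyr::bind_rows(pred, tibble::tibble(
    patient_id = "p6", question = "ambulatory", label = "yes"))
  rep2 <- evaluate(pred2, truth2, "ambulatory")
  f1_yes <- rep2$per_class$f1[rep2$per_class$class == "yes"]
  expect_equal(rep2$per_class$f1[rep2$per_class$class == "no"], 0)
  expect_equal(rep2$weighted_f1, f1_yes * 5 / 6 + 0 * 1 / 6)
})

test_that("zero-denominator metrics are 0 and flagged", {
  truth <- tibble::tibble(patient_id = c("p1", "p2"), question = "verbal",
                          label = c("no", "no"))
  pred <- tibble::tibble(patient_id = c("p1", "p2"), question = "verbal",
                         label = c("no", "no"))
  rep_ <- evaluate(pred, truth, "verbal")
  yes_row <- rep_$per_class[rep_$per_class$class == "yes", ]
  expect_equal(yes_row$precision, 0)
  expect_equal(yes_row$f1, 0)
  expect_true(yes_row$undefined)
  expect_equal(rep_$weighted_f1, 1)  # the yes class has zero weight
})

test_that("a predicted patient without a truth label raises", {
  pred <- tibble::tibble(patient_id = "p1", question = "verbal",
                         label = "yes")
  truth <- tibble::tibble(patient_id = "p2", question = "verbal",
                          label = "yes")
  expect_error(evaluate(pred, truth, "verbal"),
               class = "notepheno_domain_error")
})

test_that("metrics agree with the caret reference on random confusion tables", {
  set.seed(7)
  for (i in 1:100) {
    tab <- sample(1:40, 4, replace = TRUE)
    v <- labels_from_table(tab[1], tab[2], tab[3], tab[4])
    ours <- notepheno:::eval_labels(v$pred, v$truth)
    ref <- caret_reference(v$pred, v$truth)
    expect_equal(ours$weighted_f1, ref$weighted_f1, tolerance = 1e-12)
    expect_equal(ours$macro_f1, ref$macro_f1, tolerance = 1e-12)
    expect_equal(ours$avg_precision, ref$avg_precision, tolerance = 1e-12)
    expect_equal(ours$avg_recall, ref$avg_recall, tolerance = 1e-12)
  }
})

test_that("note-type informativeness counts non-unknown and correct predictions", {
  preds <- tibble::tibble(
    note_id = sprintf("n%02d", 1:12),
    patient_id = "p1",
    note_type = c(rep("physical therapy", 10), rep("speech", 2)),
    verbal = "unknown",
    ambulatory = c(rep("yes", 5), "no", rep("unknown", 2), "yes", "no",
                   "unknown", "unknown"),
    mode = "MCP", backend_id = "mock")
  truth <- tibble::tibble(patient_id = "p1", question = "ambulatory",
                          label = "yes")
  out <- note_type_informativeness(preds, truth, "ambulatory", min_n = 1)
  pt <- out[out$note_type == "physical therapy", ]
  expect_equal(pt$n_notes, 10L)
  expect_equal(pt$prop_non_unknown, 0.8)
  expect_equal(pt$correctness_non_unknown, 6 / 8)
  sp <- out[out$note_type == "speech", ]
  expect_equal(sp$prop_non_unknown, 0)
  expect_true(is.na(sp$correctness_non_unknown))
})

test_that("note types under the display threshold are omitted", {
  preds <- tibble::tibble(
    note_id = sprintf("n%03d", 1:99),
    patient_id = "p1",
    note_type = c(rep("big", 50), rep("small", 49)),
    verbal = "yes", ambulatory = "yes", mode = "MCP", backend_id = "mock")
  truth <- tibble::tibble(patient_id = "p1", question = "verbal",
                          label = "yes")
  out <- note_type_informativeness(preds, truth, "verbal", min_n = 50)
  expect_equal(out$note_type, "big")
})

test_that("identical paired samples are a degenerate no-evidence comparison", {
  x <- c(0.8, 0.85, 0.9, 0.7, 0.75)
  out <- compare_experiments(x, x)
  expect_true(out$degenerate)
  expect_true(is.na(out$p_value))
})

test_that("the signed-rank test matches the exhaustive sign-assignment oracle", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    a <- round(runif(n), 3)
    b <- a + round(runif(n, -0.3, 0.3), 4)
    d <- a - b
    if (any(d == 0) || any(duplicated(abs(d)))) next
    ours <- compare_experiments(a, b)
    oracle <- wsr_oracle(a, b)
    expect_equal(ours$statistic, oracle$statistic)
    expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-12)
  }
})

test_that("a consistent shift is detected as significant", {
  set.seed(61)
  a <- runif(20, 0.5, 0.9)
  b <- a + 0.05
  expect_lt(compare_experiments(a, b)$p_value, 0.05)
})

test_that("unpaired lengths raise", {
  expect_error(compare_experiments(1:5, 1:6),
               class = "notepheno_domain_error")
})
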