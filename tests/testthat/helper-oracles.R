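# Independent reference implementations used to check the package's
# computations, kept deliberately naive and separate from the code paths
# they verify.

# Brute-force leakage scrubber: per-character mask, expanded around every
# phrase match, deleted, repeated to fixpoint.
scrub_oracle <- function(text, phrases = c("gmfcs", "gross motor function",
                                           "gross motor function cs", "vss",
                                           "viking speech", "cfcs"),
                         window = 15) {
  repeat {
    n <- nchar(text)
    if (n == 0L) return(text)
    hay <- tolower(text)
    mask <- rep(FALSE, n)
    found <- FALSE
    for (p in phrases) {
      m <- gregexpr(tolower(p), hay, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      found <- TRUE
      len <- attr(m, "match.length")
      for (k in seq_along(m)) {
        s <- max(1L, m[k] - window)
        e <- min(n, m[k] + len[k] - 1L + window)
        mask[s:e] <- TRUE
      }
    }
    if (!found) return(text)
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    text <- paste(chars[!mask], collapse = "")
  }
}

# Adversarial text generator: phrase fragments in mixed casing glued at
# random, so concatenation effects (e.g. "gmgmfcsfcs") occur often.
adversarial_text <- function(k = 12) {
  pieces <- c("gm", "fcs", "gmfcs", "GMFCS", "vs", "ss", "vss", "VSS",
              "viking", " speech", "Viking Speech", "cf", "cs", "cfcs",
              "CfCs", "gross", " motor", " function", " function cs",
              "Gross Motor Function", " ", "a", "bq", "xyz", "walk", "m")
  paste(sample(pieces, k, replace = TRUE), collapse = "")
}

# Exhaustive-enumeration Wilcoxon signed-rank oracle for small n with no
# zero differences and no tied absolute differences. Matches the V
# statistic convention of a paired two-sided test on (a, b): d = a - b.
wsr_oracle <- function(a, b) {
  d <- a - b
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1L])
  }, numeric(1))
  list(statistic = v,
       p_value = min(1, 2 * min(mean(vs <= v), mean(vs >= v))))
}

# Expand a 2x2 confusion table into parallel label vectors.
labels_from_table <- function(tp, fp, fn, tn) {
  list(pred = c(rep("yes", tp + fp), rep("no", fn + tn)),
       truth = c(rep("yes", tp), rep("no", fp),
                 rep("yes", fn), rep("no", tn)))
}

# Reference classification metrics via caret, combined with the
# prevalence-weighted and macro averaging definitions.
caret_reference <- function(pred, truth) {
  pf <- factor(pred, levels = c("yes", "no"))
  tf <- factor(truth, levels = c("yes", "no"))
  by_yes <- caret::confusionMatrix(pf, tf, positive = "yes",
                                   mode = "prec_recall")$byClass
  by_no <- caret::confusionMatrix(pf, tf, positive = "no",
                                  mode = "prec_recall")$byClass
  n_yes <- sum(tf == "yes"); n_no <- sum(tf == "no"); n <- length(tf)
  list(
    precision_yes = unname(by_yes["Precision"]),
    recall_yes = unname(by_yes["Recall"]),
    f1_yes = unname(by_yes["F1"]),
    precision_no = unname(by_no["Precision"]),
    recall_no = unname(by_no["Recall"]),
    f1_no = unname(by_no["F1"]),
    weighted_f1 = unname(by_yes["F1"]) * n_yes / n +
      unname(by_no["F1"]) * n_no / n,
    macro_f1 = (unname(by_yes["F1"]) + unname(by_no["F1"])) / 2,
    avg_precision = (unname(by_yes["Precision"]) +
                       unname(by_no["Precision"])) / 2,
    avg_recall = (unname(by_yes["Recall"]) + unname(by_no["Recall"])) / 2)
}

# Small note tibble builder for I/O and filter tests.
make_notes <- function(n = 3, text = NULL, patient_id = NULL,
                       note_type = "progress", specialty = "neurology",
                       start_date = as.Date("2023-01-01")) {
  tibble::tibble(
    note_id = sprintf("N%03d", seq_len(n)),
    patient_id = patient_id %||% sprintf("P%03d", seq_len(n)),
    note_type = note_type, specialty = specialty,
    encounter_date = start_date + seq_len(n),
    text = text %||% sprintf("Note body %d with several words.", seq_len(n)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
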