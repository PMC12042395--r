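---
title: "Extracting verbal and ambulatory ability from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting verbal and ambulatory ability from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notepheno)
```

## The problem

Verbal and ambulatory abilities are functional biomarkers: objectively
assessable indicators that drive treatment planning and research in
intellectual and developmental disabilities and cerebral palsy. They are
usually captured with standardized instruments (GMFCS, Viking Speech Scale,
CFCS, CARS-2, M-CHAT-R), which are burdensome to administer and give only
snapshots. Clinical notes, accrued passively at every encounter, describe
the same abilities in free text. `notepheno` implements a reusable pipeline
that asks a language-model extractor two questions about each note --
*Does the individual use any words?* and *Can the individual walk without
aid?* -- and turns the note-level answers into per-patient binary labels
evaluated against assessment-derived ground truth.

The pipeline stages are: cohort ingestion (or simulation), note selection,
leakage scrubbing, prompt-based extraction, ground-truth mapping,
note-to-individual aggregation, evaluation, and cost estimation. Every
stage is exposed as an ordinary function over tibbles, and
`run_pipeline()` wires them together with persisted intermediates and a
manifest.

## Note selection

`selection_criteria()` captures the inclusion rules of a typical
deployment: progress notes only, an author-specialty whitelist, patients
with ground-truth labels, encounters at age $\ge 3$ years, optionally a
two-sided window of 1.5 years around the date the ground-truth annotations
were created, a minimum word count (0 for registry-style corpora, 500 for
clinic-style corpora dominated by templated documentation), and finally at
least 5 *surviving* notes per patient. The order is fixed and matters: the
per-patient count is evaluated on notes that survived all prior rules.
Thresholds are inclusive (`>=`), the literal reading of "at least".
Age uses exact day counts divided by 365.25. The window is two-sided
because its direction is not inherent in "within 1.5 years"; the anchor is
the patient's enrollment/annotation date.

## Leakage scrubbing

Ground-truth scale names appear verbatim in real notes ("GMFCS level
III"), which would let an extractor read the answer off the scale rather
than the clinical description. `scrub_leakage()` removes six phrases --
`gmfcs`, `gross motor function`, `gross motor function cs`, `vss`,
`viking speech`, `cfcs` -- plus 15 characters of context on each side.

Three semantics choices are deliberate and tested:

* matching is case-insensitive substring search (scale names are
  capitalized in practice);
* all match spans on the current text are expanded, clipped, **merged on
  overlap**, and deleted simultaneously, so nested phrases ("gross motor
  function" inside "gross motor function cs") cannot cause
  double-deletion;
* the pass repeats to a fixpoint, because deletion can juxtapose
  characters into a new match (`"gmgmfcsfcs"` needs two passes).

The test suite checks the postcondition (no phrase in the output, ever)
and byte-equality against a brute-force per-character oracle on tens of
thousands of adversarial splices.

## Prompting and extraction

`prompt_template()` assembles the four prompt components as a
conversational message sequence: a system message casting the model as a
physician extracting the two abilities; a fixed confirmation exchange; the
ability definitions -- including the clarification that *walking with a
walking aid does not count as walking without aid*, which materially
changes answers -- and the required output format; and the note text
substituted verbatim at the `{}` placeholder. Two modes exist: the
multi-class prompt (MCP) admits `unknown` as an abstention, the
binary-class prompt (BCP) forces yes/no. The expected response is two
structured lines (`words: <answer>` / `walk: <answer>`, about 13 tokens);
the exact exemplar is an editable convention, not ground truth.

`parse_response()` is tolerant (keys located case-insensitively, quotes
and separators ignored). Under MCP an unparseable response degrades to
`(unknown, unknown)` with a warning; under BCP it is a protocol violation
recorded as a per-note failure. `extract_corpus()` guarantees exactly one
prediction or failure record per note, truncates notes to a backend's
character budget first (characters, not tokens -- 10,000 characters
emulates a small-context model), and retries transient backend errors with
bounded backoff.

Backends are pluggable through `extractor_backend()`: an id, an optional
context limit, and a `complete(messages)` function. Any chat-completion
client can be wrapped this way; the package itself ships only
`mock_backend()`, a deterministic keyword/negation classifier over the
synthetic template bank's phrase inventory, with a seeded per-question
error rate for noise experiments. Within a question, negation patterns
take precedence -- a note mentioning both independent walking and a
walking aid is classified "no" -- mirroring the aided-walking
clarification in the prompt.

## Ground truth

`map_gmfcs()`, `map_vss()`, `map_cfcs()` and `map_binary_instrument()`
implement the published response-to-label tables. Two interval conventions
are ours to fix, because the tables print "3 to 4" and "4 to 18" without
bracket notation: the strata are taken as $[3, 4)$ and $[4, 18]$, a
contiguous non-overlapping cover in which age 4.0 falls in the older
stratum. Ages above 18 are rejected by default (`allow_adult = TRUE`
extends the adult rule upward); ages below 3 are always rejected, which is
moot under the age filter.

`resolve_ground_truth()` maps every applicable record for a (patient,
question) and requires unanimity: conflicting mapped labels raise an error
naming the instruments. Conflicts are never voted away -- none are
expected in well-formed data, and silent resolution would mask generator
or mapper bugs. Which instruments apply is a cohort-style decision:
registry style (`BGR`) uses CARS-2/telehealth for verbal and
GMFCS/M-CHAT-R for ambulatory; clinic styles (`CP_VSS`, `CP_CFCS`) use
GMFCS for ambulatory and exactly one of VSS or CFCS for verbal, so verbal
performance can be evaluated against each scale separately.

## Aggregation and evaluation

Two note-to-individual rules are implemented. **Majority**: unknowns are
discarded and the label is "yes" iff yes-votes strictly exceed no-votes;
ties and all-unknown patients resolve to "no" (the literal "otherwise"
reading). All-unknown patients are flagged `zero_evidence` and counted in
reports so the effect of that convention is quantifiable. **Any-yes**: one
"yes" note suffices. Any-yes exists because clinic corpora contain weekly
physical-therapy notes with identical copied history sections describing
aided mobility; these flood the majority vote with "no" answers for
patients who currently walk independently. Any-yes "yes" sets always
contain majority "yes" sets, so any-yes recall for the "yes" class
dominates majority recall -- a theorem the suite still checks empirically
on simulated cohorts.

`evaluate()` reports per-class precision/recall/F1 ("yes" as the positive
class of its own table), and combines them as

$$F1_{weighted} = F1_{yes}\cdot\frac{n_{yes}}{N} + F1_{no}\cdot\frac{n_{no}}{N},
\qquad F1_{macro} = \tfrac{1}{2}(F1_{yes} + F1_{no}),$$

with ground-truth class prevalences as weights. "Average precision/recall"
are reported as unweighted class means (the natural reading when the
weighted variant is singled out by name); prevalence-weighted variants are
emitted alongside. Metrics with a zero denominator are defined as 0 and
flagged, keeping the weighted sum defined. The implementation is checked
against caret's `confusionMatrix` on a thousand random confusion tables to
$10^{-12}$.

`note_type_informativeness()` reports, per note type, the proportion of
non-unknown answers and the correctness of those answers against the
individual's label, omitting types under a display threshold (default 50
notes); a type with only unknowns reports `NA` correctness rather than a
number. `compare_experiments()` wraps the two-sided Wilcoxon signed-rank
test with the standard zero-discard convention; all-zero differences are
reported as a degenerate no-evidence comparison rather than a p-value. The
pairing unit is the caller's choice -- per-question weighted F1 across
bootstrap resamples of individuals is a natural one.

## Cost model

`expected_cost()` implements the expected-cost identity

$$\mathrm{Total} = P \cdot N \cdot\left(\frac{\mathrm{avg\ input\ chars}}{4}\cdot\frac{\mathrm{input\ cost}}{1000} + \frac{\mathrm{output\ cost}}{1000}\cdot TpO\right)$$

with the 4-characters-per-token approximation and $TpO = 13$ expected
output tokens for the two-line answer. Arithmetic is kept exact;
`total_display` rounds half-up to cents at presentation only, which is
what makes the reference cost table reproduce to the cent.
`measure_avg_input_chars()` measures the assembled prompt (template plus
note, after any backend truncation) over a corpus.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage has a testable oracle. What
it emulates: per-patient note counts (5--30) and lengths; an author
specialty mixture in which physical-therapy templates speak to gait and
speech-therapy templates to word use (each specialty documents its primary
question at the full informative rate and the other at half); notes that
state an ability, omit it, or contradict the latent truth at configured
rates; scale-score mentions for the scrubber to remove; clinic-style
serial physical-therapy notes sharing an identical aided-mobility history
section; and assessment records drawn from exactly the scale classes that
map back to the latent labels, so the generator and the ground-truth
mapper verify each other in a round trip on every run.

Choices worth knowing:

* **Intake documentation.** Whenever the informative rate is positive, a
  patient's first note is an intake evaluation documenting both abilities.
  Specialty clinics document core functional status at intake; this is
  also what makes exact recovery at zero noise a guarantee rather than a
  high-probability event, so the zero-noise acceptance check is sharp.
* **Tags, not text, as the oracle.** Each note carries machine-readable
  stance tags (emitted separately from the text); tests compare
  predictions to tags, keeping the mock extractor and the generator
  decoupled.
* **Leakage placement.** Planted scale mentions carry at least 15
  characters of same-sentence padding on each side, so scrubbing them
  never clips a neighbouring informative sentence.
* **Reproducibility.** One substream per patient, derived from the cohort
  seed and the patient counter: a fixed seed gives byte-identical corpora,
  and growing the cohort leaves existing patients unchanged.
* **Ages** are sampled from 3 to 18 years, the population the selection
  filter retains; encounter dates stay within the 1.5-year window and
  above age 3, so the default filters are inert on synthetic corpora and
  the filter rules are exercised with crafted fixtures instead. Because
  ages are 3+, M-CHAT-R (a 16--30-month toddler screen) is mapped but
  never generated; registry-style verbal truth comes from CARS-2 plus the
  telehealth screener, ambulatory from GMFCS.

What it does **not** emulate: real clinical language diversity (the text
is templated), multilingual notes, temporal change in abilities (latent
abilities are static per patient; a time-varying latent state is a
deliberate non-goal and a natural extension point), or the note-count
distributions of any particular institution. Passing tests on synthetic
corpora therefore demonstrate the correctness of the pipeline machinery
and its contracts -- not the field performance of any particular language
model, which requires real corpora and a live backend behind the same
`extractor_backend()` contract.

## Problem sizes and numerical conventions

The test suite runs the end-to-end recovery check on a 200-patient
contradiction-free cohort (weighted F1 must be exactly 1.0 for both
questions); noise monotonicity on 20 seeds $\times$ 50-patient cohorts
over mock error rates $\{0, 0.1, 0.2, 0.3\}$ (mean weighted F1 must
strictly decrease); the any-yes dominance check on 8 clinic-style seeds;
the scrubber oracle on 10,000 adversarial strings; the metric oracle on
1,000 random confusion tables; and the ground-truth round trip on 10,000
generated patients. These sizes give sharp assertions at interactive
runtimes.

Currency is treated as an opaque unit. Rounding half-up at two decimals is
implemented directly (base `round()` is round-half-even). Word counts are
whitespace-delimited token counts. Dates are ISO-8601 on disk and `Date`
in memory.

## Known limitations

* The mock extractor's pattern inventory is matched to the synthetic
  template bank; it is a pipeline test instrument, not a clinical NLP
  model.
* Individual-level labels inherit the "ties and no-evidence mean no"
  convention; corpora where abstention is informative may prefer a
  three-valued individual label, which the counts in the aggregation
  output already support.
* The GMFCS stratum conventions ($[3,4)$, $[4,18]$) and the
  case-insensitive merged-span scrub are recorded interpretations of
  under-specified published procedures, not inferred intent.
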