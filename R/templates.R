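# Template bank for synthetic note text, plus the keyword/negation pattern
# inventory the mock extractor classifies against.
#
# The two are deliberately decoupled: the generator emits whole sentences
# from the bank, while the mock backend matches regular-expression patterns
# over free text. Tests that need ground truth about what a note states use
# the machine-readable tags emitted alongside each note, never the text.

SENTENCE_BANK <- list(
  ambulatory = list(
    yes = c(
      "The patient walks independently without any assistive device.",
      "She ambulates independently across the clinic hallway.",
      "He runs and climbs stairs without assistance at home.",
      "Independent ambulation was observed throughout the visit."),
    no = c(
      "The patient walks only with a posterior walker.",
      "He is non-ambulatory and relies on a manual wheelchair.",
      "She is unable to walk and is carried for longer distances.",
      "Upright mobility is achieved only with a gait trainer and close supervision.")),
  verbal = list(
    yes = c(
      "The patient uses single words to request preferred items.",
      "He speaks in short sentences during play.",
      "Verbal output includes several words used spontaneously.",
      "She has a vocabulary of more than twenty words."),
    no = c(
      "The patient is nonverbal at this time.",
      "He does not use any words to communicate.",
      "She communicates with gestures only and no spoken words were observed."))
)

# Historic-mobility sentence shared verbatim across a patient's serial
# physical-therapy notes when duplicated history sections are simulated.
# It describes aided mobility, so it draws "no" ambulatory predictions.
DUP_HISTORY_SENTENCES <- c(
  "Past mobility history notes that the patient has used a walker for household distances.",
  "Prior documentation records that the patient required a walker during therapy sessions.")

# Leakage sentences embed a scale mention (one of the scrub phrases) with at
# least 15 characters of same-sentence padding on both sides, so the scrub
# window stays within the sentence.
leakage_sentence <- function(latent) {
  kind <- sample(c("gmfcs", "vss", "cfcs"), 1L)
  roman <- c("I", "II", "III", "IV", "V")
  switch(kind,
    gmfcs = sprintf(
      "Standardized review noted GMFCS level %s at this encounter today.",
      roman[latent$gmfcs_class]),
    vss = sprintf(
      "Assessment battery included Viking Speech Scale level %d per the clinic record.",
      latent$vss_class),
    cfcs = sprintf(
      "Classification summary listed CFCS level %s for communication today.",
      roman[latent$cfcs_class]))
}

FILLER <- list(
  history = c(
    "The patient was seen in follow up for routine developmental care.",
    "Past medical history is significant for a complex perinatal course.",
    "Family history was reviewed and is unchanged from prior visits.",
    "Medications were reconciled at the start of the visit."),
  exam = c(
    "Vital signs were within normal limits for age.",
    "Cardiopulmonary examination was unremarkable.",
    "Skin examination showed no rashes or lesions.",
    "The patient appeared well nourished and in no acute distress."),
  plan = c(
    "Continue the current therapy schedule and home program.",
    "Return to clinic in three months or sooner as needed.",
    "Anticipatory guidance was provided to the family.",
    "Coordination with the school team will continue."),
  padding = c(
    "The family had no additional questions at the end of the visit.",
    "All findings were discussed with the caregiver in detail.",
    "The plan of care was reviewed and agreed upon by the family.",
    "Follow up laboratory studies are not indicated at this time.",
    "The patient tolerated the evaluation well without distress.",
    "Care coordination notes were updated in the chart."))

DEFAULT_SPECIALTIES <- c(
  "physical therapy" = 0.25, "speech therapy" = 0.15, "neurology" = 0.15,
  "developmental pediatrics" = 0.12, "pediatrics" = 0.10,
  "orthopedics" = 0.08, "psychology" = 0.08,
  "rehabilitation medicine" = 0.07)

# Which question a specialty's notes primarily speak to. The primary
# question is documented at the full informative rate, the other at half,
# mirroring that gait is charted by physical therapy and word use by speech
# therapy.
SPECIALTY_PRIMARY_QUESTION <- c(
  "physical therapy" = "ambulatory", "orthopedics" = "ambulatory",
  "rehabilitation medicine" = "ambulatory", "neurology" = "ambulatory",
  "speech therapy" = "verbal", "psychology" = "verbal",
  "developmental pediatrics" = "verbal", "pediatrics" = "verbal")

# Pattern inventory for the mock extractor. Negation patterns take
# precedence within a question: a note describing walking with an aid is
# classified "no" for walking without aid even if it also mentions walking.
MOCK_PATTERNS <- list(
  ambulatory = list(
    no = c("non-?ambulatory", "\\bwalker\\b", "gait trainer", "wheelchair",
           "unable to walk", "walking aid", "walks only with"),
    yes = c("walks independently", "ambulates independently",
            "independent ambulation", "runs and climbs",
            "without any assistive device")),
  verbal = list(
    no = c("non-?verbal", "does not use any words", "gestures only",
           "no spoken words"),
    yes = c("uses single words", "speaks in short sentences",
            "verbal output", "vocabulary of"))
)
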