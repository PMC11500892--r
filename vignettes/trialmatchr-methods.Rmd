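---
title: "Methods: explainable patient-to-trial matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable patient-to-trial matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmatchr)
```

## The matching model

`trialmatchr` screens one patient note against one protocol on four
eligibility criteria — cancer type, ECOG performance status, measurable
disease, genetic mutation — and reduces the comparison to a single number:

$$\mathrm{score} = \frac{\text{criteria met by the patient}}
                        {\text{criteria required by the protocol}}.$$

A criterion enters the denominator only when the protocol's *inclusion*
section poses it: a non-blocklisted cancer concept, an ECOG bound, a
"measurable disease"/"measuring" phrase (with no "non-measurable disease"
mention), or at least one eligible gene token. The decision rule is a
strict threshold: match iff `score > threshold` (default 0.5, i.e. more
evidence for than against). When no requirement is detected the score is
undefined and the decision is *indeterminate* — such pairs are excluded
from evaluation counts rather than silently coerced (a config switch,
`indeterminate_as_no_match`, restores a strictly binary matrix).

Exclusion-section evidence never changes the score. Patient findings that
fall under an exclusion-section concept or gene list are surfaced as
`exclusion_flags` for the human reviewer. This reflects the system's
design as a screening aid: the score is inclusion-driven, and the
explanation ledger is where disqualifying evidence appears.

Every required criterion emits one deterministic evidence line of the form
"Patient *i* has *finding* which does/does not match Protocol *j* which
requires *requirement*", so reports are diffable and every no-match
verdict is accompanied by at least one "does not match" line.

## Pre-processing assumptions

The mention stream is produced by taggers behind a simple contract
(JSON-lines of `{tagger, surface, start, end, tag}`); the bundled lexicon
tagger performs a longest-match-first, case-insensitive scan over token
n-grams (n ≤ 6) and exists so the whole system runs offline. Offsets are
0-based half-open throughout. Claimed spans that do not reproduce their
surface are re-anchored by searching the raw text within ±40 characters of
the claimed start (nearest occurrence wins, case-sensitive before
case-insensitive); spans that cannot be re-anchored are dropped rather
than guessed. Mentions whose rectified spans coincide exactly are merged
with the union of their (tag, tagger) pairs; partially overlapping spans
stay separate.

Abbreviations follow the parenthetical convention: for `LONG FORM (SHORT)`
with a 2–10 character, ≥50 %-uppercase short form, the long form is
recovered by initial-letter back-scanning (Schwartz–Hearst style) and
every later mention of the short form is expanded before matching. An
abbreviation *without* an in-document definition is deliberately left
unexpanded — downstream concept mapping may then misread it (e.g. a bare
lab-panel "ALT" resolving to "Atypical Lipomatous Tumor"), which is a
documented limitation of abbreviation-blind matching and is reproduced,
not patched, by this implementation.

Negation is the simplified sentence-scope variant of NegEx: any trigger
phrase ("not including", "except for", "no evidence of", "without",
"denies", ...) negates *every* mention in its sentence, with no
directional window. The trigger list is config-editable; the default is a
small documented extension of the two canonical examples. Sentence
boundaries therefore matter: the splitter is deterministic — newlines and
`.?!` followed by whitespace and an uppercase/digit/bullet start, never
inside parentheses, after single capital initials, or after a small
abbreviation guard list — and section spans partition the document
exactly, so negation and organ-combination rules have a well-defined,
testable scope.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.5 | strict decision cut on the score |
| `measurable_cm` | 1.0 / 1.5 | minimum longest dimension (cm) for solid-organ / lymph-node lesions |
| `size_comparator` | `>=` | boundary convention for the size rule |
| `rectify_window` | 40 | offset re-anchoring window (characters) |
| `generic_blocklist` | 5 codes | concepts too generic to identify a cancer |
| `synonyms_enabled` | `FALSE` | canonicalize gene tokens through the synonym table |

The size comparator deserves a note: "at least 1 cm" and "greater than
1 cm" are both defensible readings of the RECIST boundary, and the two
appear side by side in common usage. The package defaults to `>=`
(RECIST 1.1's "or above") and exposes `>` as a switch; the boundary cases
(`1.0` cm solid organ, `1.5` cm node) are pinned by tests under both
conventions. ECOG matching is *conservative interval containment*: an
implicit good-health patient is the interval [0, 1], and the whole
interval must sit inside the requirement's admissible set. This trades a
little recall for explainability — an implicit [0, 1] patient does not
satisfy an exact-0 requirement, and the evidence line says so.

## The concept thesaurus

Cancer-type resolution uses a flat concept store: `code`, preferred name,
synonyms, parent codes (a multi-parent DAG, matching the shape of the NCI
Thesaurus Neoplasm branch, root code C3262). Lookup normalizes terms by
lowercasing, stripping punctuation and sorting words, so word-order
variants collide onto the same key; preferred names take precedence over
synonyms, ambiguous synonym hits resolve deterministically
(fewest-parents, then code order), and subtype queries are reflexive
reachability over parent edges. The package ships a ~46-concept synthetic
miniature (`inst/extdata/neoplasm_fixture_synthetic.tsv`) in this dialect
so everything runs without downloads; a real thesaurus export in the same
dialect loads through the same `load_ontology()` path. The blocklist is
code-level; name-level aliases of a generic concept route to the same
code and are equally blocked.

## The synthetic corpus and what it shows

`generate_corpus()` emulates the study design this kind of system is
evaluated under: 12 patient notes × 6 protocols = 72 labelled pairs per
seed. Patient notes are template-rendered from structured profiles
(cancer concept, metastatic flag, ECOG 0–4 with explicit/implicit
rendering, lesions with sites and cm dimensions, mutation and
prior-therapy gene lists); protocols render inclusion/exclusion sections
in bulleted or numbered variants. Gold labels are computed from the
profiles alone — subtype via the ontology, ECOG membership, RECIST
thresholds, mutation intersection with true synonym resolution — and the
NLP pipeline is never consulted, so the gold standard is architecturally
independent of the system under test.

Two generator choices are deliberate and worth stating:

* **Unanimity gold vs threshold decision.** The gold rule ("all present
  requirements satisfied") and the decision rule (`score > 0.5`)
  disagree by construction whenever a patient meets more than half but
  not all of a protocol's requirements. The patient sampler
  rejection-samples profiles out of that disagreement zone (with a
  guaranteed-terminating fallback profile that fails every requirement the
  protocol pool can pose), so on a clean corpus the pipeline is expected
  to recover the gold labels exactly, and any miss is a genuine pipeline
  defect. Confounders are then the *only* engineered source of
  system-vs-gold divergence.
* **Confounders are the observed error modes**, not random noise:
  undefined abbreviations (the ALT case), negated cancer mentions, gene
  synonym swaps (CHEK2 for CHK2), expression variants ("BRCA1 mut"),
  and millimetre units. Each is injected per-patient from its own RNG
  stream, so enabling one confounder leaves every unaffected patient
  byte-identical — which is what makes the "changes predictions only
  where injected" property testable.

Consistency constraints between point-valued gold ECOG and interval-valued
implicit extraction are honoured by the sampler: implicit-poor renderings
are drawn only for ECOG 3–4, the `absent` rendering is reserved for
targeted tests, and protocol ECOG requirements come from the realistic
phase 1 pool (≤1, ≤2, 0–1, 0–2). Sentence templates avoid negation
triggers and stray metastasis cues except where a confounder plants them.

What passing tests on this corpus show: the extraction rules, section
tracking, score and decision logic are faithful to their specification,
end to end, under text the templates can produce. What they do not show:
robustness to real clinical prose — spelling noise, hedging, section
headers in the wild, abbreviations outside the parenthetical convention,
criteria types (prior therapy lines, lab values, washouts) that the four
extractors do not model. The corpus is a test harness, not a claim of
clinical realism.

## Numerical and degenerate-input choices

Scores are exact rational counts (`n_met / n_required`); percentages are
rounded half-up to two decimals, matching the convention used when
reporting confusion-matrix metrics (e.g. 14/19 → 73.68). Metrics with a
zero denominator are reported as absent, never as 0. Zero-requirement
protocols produce indeterminate decisions and are excluded from counts
with a logged total. Lesion sizes above 50 cm are treated as parse noise
and skipped with a warning, as are ECOG digits outside 0–4. Tie-breaks
are deterministic everywhere: nearest occurrence in offset rectification,
fewest-parents-then-code in synonym ambiguity, latest mention in implicit
ECOG conflicts, fixed cancer→ECOG→measurable→mutation ordering in
reports.

## Problem sizes used by the test suite

The default suite runs the full pipeline on five 12×6 corpora (360
pairs), checks the oracle equivalences on ≥1,000 random cases each
(normalization idempotence, subtype vs graph reachability, mutation
overlap vs set intersection, negation vs brute-force double loop), and
exercises every extractor on hand-built sentences. These sizes keep the
suite's runtime well under a minute while giving each property enough
random mass to be meaningful.

## Known limitations

* Only the four criteria are modelled; prior-treatment, lab-value and
  washout criteria are out of scope.
* Undefined abbreviations are knowingly mis-mappable (see above).
* Gene synonym resolution is off by default to mirror a
  thesaurus-less baseline; the bundled table is small and illustrative.
* The lexicon tagger is a deliberately simple stand-in behind the tagger
  contract; statistical NER models can be plugged in through the
  JSON-lines interchange but are not bundled.
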