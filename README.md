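# trialmatchr

Explainable, rule-based matching of oncology patients to phase 1 clinical
trial protocols from unstructured text.

## The problem

Screening patients for early-phase oncology trials means reading free-text
patient notes against free-text protocol eligibility criteria — a slow,
error-prone task usually done by hand. `trialmatchr` implements a fully
auditable NLP pipeline for the four criteria that gate most phase 1
oncology trials:

1. **Cancer type** — disease mentions are normalized (lowercase, words
   sorted) and resolved against a Neoplasm-branch concept thesaurus by a
   two-tier lookup (preferred names, then synonyms), with generic concepts
   ("Malignant Neoplasm", "Solid Neoplasm") blocklisted, organ + histology
   mentions combined within a sentence ("adenocarcinoma ... lung" → lung
   adenocarcinoma), and metastatic status tracked as a sub-variable. A
   patient matches when their cancer is a subtype of the protocol's
   required concept and the metastatic requirement is met.
2. **ECOG performance status** — explicit extraction around the "ECOG"
   keyword (comparator signs ≤/≥/-, single digits, ranges), plus an
   implicit fallback from functional-status phrases ("doing well" → 0–1,
   "wheelchair bound" → 2–4); matching is conservative interval
   containment.
3. **Measurable disease (RECIST 1.1)** — lesion sizes parsed from
   `(a x b) cm`, `(a x b x c) cm`, `a.b cm` and `mm` renderings, longest
   dimension retained, site normalized to solid organ / lymph node / bone;
   solid-organ lesions qualify at ≥ 1.0 cm, lymph nodes at ≥ 1.5 cm, bone
   never.
4. **Genetic mutation** — gene/mutation/DNA-tagged tokens compared by set
   intersection, with targeted-therapy contexts ("anti-HER2 therapy",
   "VEGF-targeted") excluded; an optional gene-synonym table canonicalizes
   tokens (off by default).

Each patient–protocol pair receives the matching score

```
score = number of criteria met by the patient
        --------------------------------------
        number of criteria required by the protocol
```

and a decision: **match** when `score > 0.5` (strict), **no match**
otherwise, **indeterminate** when the protocol poses no detectable
requirement. Every required criterion contributes one deterministic
evidence line, so a reviewer can see exactly why a score was assigned.

Pre-processing mirrors a multi-tagger setup: a pluggable tagger contract
(JSON-lines interchange) plus a built-in lexicon tagger, offset
rectification within a ±40-character window, merging of coincident spans,
parenthetical abbreviation detection with long-form expansion, and
sentence-scope negation.

## Worked example

```r
library(trialmatchr)

patient <- parse_document(paste(
  "The patient was diagnosed with metastatic lung adenocarcinoma.",
  "Current ECOG PS is 1.",
  "CT shows a (2.3 x 1.1) cm mass in the liver.",
  "Molecular profiling identified pathogenic alterations in ATM and TP53."),
  "patient", id = "1")

protocol <- parse_document(paste(
  "Inclusion Criteria:",
  "- Histologically confirmed metastatic adenocarcinoma.",
  "- ECOG 0-1.",
  "- Measurable disease per RECIST 1.1.",
  "- Documented pathogenic alteration in ATM, ATR.",
  "Exclusion Criteria:",
  "- Uncontrolled intercurrent illness.", sep = "\n"),
  "protocol", id = "1")

match_pair(patient, protocol)
```

prints

```
Patient 1 vs Protocol 1
  Matching score: 1 (4 of 4 required criteria met)
  Decision: match
  Evidence:
   - Patient 1 has cancer type Lung Adenocarcinoma (metastatic) which matches Protocol 1 which requires cancer type Adenocarcinoma (metastatic)
   - Patient 1 has ECOG status [1] which matches Protocol 1 which requires ECOG status of 0–1
   - Patient 1 has measurable disease which matches Protocol 1 which requires measurable disease
   - Patient 1 has mutations [ATM, TP53] which matches Protocol 1 which requires mutations [ATM, ATR]
```

All four protocol requirements were detected, the patient's lung
adenocarcinoma is a subtype of the required (metastatic) adenocarcinoma,
ECOG 1 lies in 0–1, the 2.3 cm liver lesion is measurable, and the gene
sets overlap on ATM — so the score is 4/4 and the pair is declared a match.

A synthetic evaluation corpus with gold labels (and optional error-mode
confounders such as unexpanded abbreviations or unresolved gene synonyms)
is one call away:

```r
bundle <- generate_corpus(12, 6, seed = 1)
res <- match_all(bundle$patients, bundle$protocols)
evaluate_predictions(res$predictions, bundle$gold)$metrics$percent
#> precision sensitivity specificity  accuracy
#>       100         100         100       100
```

A command-line wrapper with `match`, `batch`, `evaluate` and `synth`
subcommands is installed at `inst/cli/trialmatch`.

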