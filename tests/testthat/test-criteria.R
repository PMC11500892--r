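# Criterion extractors and per-criterion match rules.

proc <- function(txt, kind, lex = tiny_lexicon()) {
  d <- parse_document(txt, kind, id = "t")
  mm <- flag_negation(d, expand_mentions(
    merge_outputs(tag_with_lexicon(d, lex), d$raw_text),
    detect_abbreviations(d)
  ))
  list(doc = d, mentions = mm)
}

test_that("organ and histology in one sentence combine to a specific cancer", {
  ont <- tiny_ontology()
  x <- proc("Pathology shows adenocarcinoma arising in the lung.", "patient")
  f <- extract_cancer(x$doc, x$mentions, ont)
  expect_true("X3" %in% f$code)  # lung adenocarcinoma via combination
  expect_true("X2" %in% f$code)  # the generic histology is kept too
})

test_that("metastatic status is record-wide for patients, per-sentence for protocols", {
  ont <- tiny_ontology()
  x <- proc(paste("Known osteosarcoma since 2019.",
                  "Imaging later showed metastatic progression."), "patient")
  f <- extract_cancer(x$doc, x$mentions, ont)
  expect_true(all(f$metastatic))

  y <- proc(paste("Inclusion Criteria:",
                  "- Histologically confirmed metastatic adenocarcinoma.",
                  "- Prior osteosarcoma history acceptable.", sep = "\n"),
            "protocol")
  g <- extract_cancer(y$doc, y$mentions, ont)
  expect_true(g$metastatic[g$code == "X2"])
  expect_false(g$metastatic[g$code == "X5"])
})

test_that("negated cancer mentions yield no findings", {
  ont <- tiny_ontology()
  x <- proc("No evidence of sarcoma. Adenocarcinoma is confirmed.", "patient")
  f <- extract_cancer(x$doc, x$mentions, ont)
  expect_false("X4" %in% f$code)
  expect_true("X2" %in% f$code)
})

test_that("an undefined ALT abbreviation maps to the liposarcoma concept", {
  # known-limitation behaviour: without an in-document definition the
  # abbreviation is matched as-is and lands on Atypical Lipomatous Tumor
  ont <- load_fixture_ontology()
  lex <- default_lexicon(ont)
  x <- proc("Labs: AST and ALT 2.4 x ULN; albumin 3.1 g/dL.", "patient", lex)
  f <- extract_cancer(x$doc, x$mentions, ont)
  expect_true("C3697" %in% f$code)
})

test_that("cancer matching uses subtype closure and metastatic implication", {
  ont <- tiny_ontology()
  pf <- function(code, met, section = "body", source = "patient") {
    data.frame(code = code, name = concept_name(code, ont), term = "t",
               metastatic = met, surface = "s", start = 0L, end = 1L,
               sentence = 1L, section = section, source = source,
               stringsAsFactors = FALSE)
  }
  # patient lung adenocarcinoma (metastatic) vs protocol adenocarcinoma (met)
  r <- match_cancer(pf("X3", TRUE), pf("X2", TRUE, "inclusion", "protocol"),
                    ont)
  expect_true(r$required)
  expect_true(r$satisfied)
  # oracle: exhaustive pair check over the subtype closure
  expect_true(is_subtype("X3", "X2", ont) && TRUE >= TRUE)

  # no protocol findings: tumour-agnostic, nothing required
  none <- pf("X2", FALSE)[0, ]
  r2 <- match_cancer(pf("X3", TRUE), none, ont)
  expect_false(r2$required)
  expect_true(is.na(r2$satisfied))

  # metastatic required but patient non-metastatic: implication fails
  r3 <- match_cancer(pf("X2", FALSE), pf("X2", TRUE, "inclusion", "protocol"),
                     ont)
  expect_false(r3$satisfied)

  # exclusion-section finding flags a conflict without altering requirement
  r4 <- match_cancer(pf("X3", TRUE),
                     rbind(pf("X2", FALSE, "inclusion", "protocol"),
                           pf("X1", FALSE, "exclusion", "protocol")), ont)
  expect_true(r4$exclusion_conflict)
  expect_true(r4$satisfied)
})

test_that("cancer matching is monotone under protocol generalization", {
  ont <- tiny_ontology()
  set.seed(23)
  codes <- setdiff(names(ont$concepts), ont$blocklist)
  parents_of <- function(code) ont$concepts[[code]]$parents
  pf <- function(code, met, section, source) {
    data.frame(code = code, name = concept_name(code, ont), term = "t",
               metastatic = met, surface = "s", start = 0L, end = 1L,
               sentence = 1L, section = section, source = source,
               stringsAsFactors = FALSE)
  }
  for (i in 1:60) {
    p <- pf(sample(codes, 1), runif(1) < 0.5, "body", "patient")
    qc <- sample(codes, 1)
    q <- pf(qc, runif(1) < 0.5, "inclusion", "protocol")
    before <- match_cancer(p, q, ont)$satisfied
    for (anc in parents_of(qc)) {
      if (anc %in% ont$blocklist) next
      q2 <- q
      q2$code <- anc
      q2$name <- concept_name(anc, ont)
      after <- match_cancer(p, q2, ont)$satisfied
      if (isTRUE(before)) expect_true(after)
    }
  }
})

test_that("explicit ECOG extraction reads comparators, digits and ranges", {
  le <- extract_ecog(parse_document(
    "Inclusion Criteria:\n- ECOG \u2264 1.", "protocol"))
  expect_s3_class(le, "tm_ecog_requirement")
  expect_equal(le$comparator, "le")
  expect_equal(le$bound_high, 1L)

  rg <- extract_ecog(parse_document(
    "Inclusion Criteria:\n- ECOG 0-1.", "protocol"))
  expect_equal(rg$comparator, "range")
  expect_equal(c(rg$bound_low, rg$bound_high), c(0L, 1L))

  st <- extract_ecog(parse_document("ECOG performance status of 2.",
                                    "patient"))
  expect_s3_class(st, "tm_ecog_status")
  expect_equal(c(st$min_level, st$max_level), c(2L, 2L))
  expect_equal(st$source_kind, "explicit")

  expect_warning(
    out <- extract_ecog(parse_document("ECOG of 7 reported. The patient is doing well.",
                                       "patient")),
    "outside 0-4"
  )
  expect_equal(out$source_kind, "implicit")
})

test_that("implicit ECOG falls back to health phrases, latest mention wins", {
  poor <- extract_ecog(parse_document(
    "The patient is wheelchair bound most of the day.", "patient"))
  expect_equal(c(poor$min_level, poor$max_level), c(2L, 4L))
  expect_equal(poor$source_kind, "implicit")

  both <- extract_ecog(parse_document(
    "Previously the patient was doing well. Now the patient is bed bound.",
    "patient"))
  expect_equal(c(both$min_level, both$max_level), c(2L, 4L))

  expect_null(extract_ecog(parse_document("Nothing relevant here.",
                                          "patient")))
})

test_that("ECOG matching is conservative interval containment", {
  req01 <- ecog_requirement("range", 0L, 1L)
  r <- match_ecog(ecog_status(2L, 2L, "explicit"), req01)
  expect_false(r$satisfied)
  expect_equal(r$patient_desc, "ECOG status [2]")
  expect_equal(r$protocol_desc, "ECOG status of 0\u20131")

  expect_true(match_ecog(ecog_status(0L, 1L, "implicit"),
                         ecog_requirement("le", 0L, 1L))$satisfied)
  # oracle: interval subset check; [0,1] is not inside {0}
  expect_false(match_ecog(ecog_status(0L, 1L, "implicit"),
                          ecog_requirement("range", 0L, 0L))$satisfied)
  # absent requirement: criterion not required
  expect_false(match_ecog(ecog_status(1L, 1L, "explicit"), NULL)$required)
  # absent status with a requirement: required but unsatisfied
  expect_false(match_ecog(NULL, req01)$satisfied)
})

test_that("lesion sizes parse in all documented renderings with site lookup", {
  cfg <- default_config()
  x <- proc(paste(
    "CT shows a (2.3 x 1.1) cm mass in the liver.",
    "A 1.2 cm axillary lymph node is noted.",
    "A sclerotic lesion in the L4 vertebra measures 3.0 cm.",
    "A 12 mm nodule is seen in the liver."
  ), "patient")
  les <- extract_lesions(x$doc, x$mentions, cfg$site_map)
  expect_equal(nrow(les), 4L)
  # oracle: parse all numbers, take the maximum of each expression
  expect_equal(les$longest_dimension_cm[les$site_category == "solid_organ"],
               c(max(2.3, 1.1), 1.2))
  expect_equal(les$longest_dimension_cm[les$site_category == "lymph_node"],
               1.2)
  expect_equal(les$longest_dimension_cm[les$site_category == "bone"], 3.0)
})

test_that("measurability follows RECIST site thresholds", {
  mk <- function(cat, d) data.frame(site_category = cat,
                                    longest_dimension_cm = d,
                                    site_surface = NA, sentence = 1L,
                                    stringsAsFactors = FALSE)
  expect_false(assess_measurability(mk("bone", 3.0)))
  expect_true(assess_measurability(mk("lymph_node", 1.5)))
  expect_false(assess_measurability(mk("lymph_node", 1.4)))
  expect_false(assess_measurability(mk("solid_organ", 0.8)))
  expect_true(assess_measurability(mk("solid_organ", 1.0)))
  expect_false(assess_measurability(mk("unknown", 9.0)))
  # strict comparator variant
  expect_false(assess_measurability(mk("solid_organ", 1.0),
                                    comparator = ">"))
})

test_that("measurability is monotone in lesion size", {
  set.seed(31)
  mk <- function(cat, d) data.frame(site_category = cat,
                                    longest_dimension_cm = d,
                                    site_surface = NA, sentence = 1L,
                                    stringsAsFactors = FALSE)
  cats <- c("solid_organ", "lymph_node", "bone", "unknown")
  for (i in 1:200) {
    les <- do.call(rbind, lapply(1:sample(1:3, 1), function(k) {
      mk(sample(cats, 1), round(runif(1, 0.1, 3), 2))
    }))
    before <- assess_measurability(les)
    les2 <- les
    j <- sample(nrow(les2), 1)
    les2$longest_dimension_cm[j] <- les2$longest_dimension_cm[j] + runif(1, 0, 2)
    if (before) expect_true(assess_measurability(les2))
  }
})

test_that("protocol measurable-disease requirement detection", {
  req <- parse_document(
    "Inclusion Criteria:\n- Patients must have measurable disease per RECIST.",
    "protocol")
  expect_true(protocol_requires_measurable(req))
  non <- parse_document(
    "Inclusion Criteria:\n- Measurable or non-measurable disease allowed.",
    "protocol")
  expect_false(protocol_requires_measurable(non))
  silent <- parse_document("Inclusion Criteria:\n- ECOG 0-1.", "protocol")
  expect_false(protocol_requires_measurable(silent))
  # when not required the criterion drops out of the denominator
  r <- match_measurable(FALSE, FALSE)
  expect_false(r$required)
  expect_true(is.na(r$satisfied))
  expect_false(match_measurable(FALSE, TRUE)$satisfied)
  expect_true(match_measurable(TRUE, TRUE)$satisfied)
})

test_that("therapy-context gene mentions are excluded from matching", {
  x <- proc(paste(
    "The patient previously received anti-HER2 therapy.",
    "VEGF-targeted treatment was stopped.",
    "A pathogenic ATM mutation was found."
  ), "patient")
  mu <- extract_mutations(x$doc, x$mentions)
  expect_true(mu$therapy_context[mu$token == "HER2"])
  expect_true(mu$therapy_context[mu$token == "VEGF"])
  expect_false(mu$therapy_context[mu$token == "ATM"])
})

test_that("mutation matching is token overlap, with optional synonym table", {
  mk <- function(tokens, section = "body") {
    data.frame(token = tokens, surface = tokens,
               therapy_context = FALSE, negated = FALSE, section = section,
               start = 0L, end = 1L, stringsAsFactors = FALSE)
  }
  syn <- load_gene_synonyms()
  # CHEK2 vs CHK2: a false negative without synonyms, resolved with them
  off <- match_mutation(mk("CHEK2"), mk("CHK2", "inclusion"), NULL)
  expect_false(off$satisfied)
  on <- match_mutation(mk("CHEK2"), mk("CHK2", "inclusion"), syn)
  expect_true(on$satisfied)
  # expression variant "BRCA1 mut" vs BRCA1
  off2 <- match_mutation(mk("BRCA1 mut"), mk("BRCA1", "inclusion"), NULL)
  expect_false(off2$satisfied)
  expect_true(match_mutation(mk("BRCA1 mut"), mk("BRCA1", "inclusion"),
                             syn)$satisfied)
  # plain overlap
  expect_true(match_mutation(mk(c("ATM", "TP53")),
                             mk(c("ATM", "ATR"), "inclusion"))$satisfied)
  # negated or therapy-context mentions never contribute
  neg <- mk("ATM")
  neg$negated <- TRUE
  expect_false(match_mutation(neg, mk("ATM", "inclusion"))$satisfied)
  th <- mk("ATM")
  th$therapy_context <- TRUE
  expect_false(match_mutation(th, mk("ATM", "inclusion"))$satisfied)
})

test_that("synonyms-off mutation matching equals lowercase set intersection", {
  set.seed(37)
  mk <- function(tokens, section) {
    data.frame(token = tokens, surface = tokens,
               therapy_context = rep(FALSE, length(tokens)),
               negated = rep(FALSE, length(tokens)),
               section = rep(section, length(tokens)),
               start = rep(0L, length(tokens)), end = rep(1L, length(tokens)),
               stringsAsFactors = FALSE)
  }
  pool <- c("ATM", "atr", "BRCA1", "brca2", "TP53", "KRAS", "chk2", "EGFR")
  for (i in 1:250) {
    p <- sample(pool, sample(0:4, 1))
    q <- sample(pool, sample(1:4, 1))
    r <- match_mutation(mk(p, "body"), mk(q, "inclusion"), NULL)
    oracle <- length(intersect(tolower(p), tolower(q))) > 0
    expect_identical(r$satisfied, oracle)
  }
})
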