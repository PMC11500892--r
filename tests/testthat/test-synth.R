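# Synthetic corpus generator: determinism, rendering rules, gold labels.

test_that("rendering is byte-identical for the same profile and seed", {
  ont <- load_fixture_ontology()
  p <- patient_profile("1", "C3512", TRUE, 1, "explicit",
                       lesions = list(list(site_category = "solid_organ",
                                           dims = c(2.3, 1.1))),
                       mutations = c("ATM", "TP53"))
  r1 <- render_patient(p, 99, ont)
  r2 <- render_patient(p, 99, ont)
  expect_identical(r1$text, r2$text)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- render_patient(p, 100, ont)
  expect_false(identical(r1$text, r3$text))

  q <- protocol_profile("1", required_cancer = "C2852",
                        ecog_requirement = ecog_requirement("le", 0L, 1L),
                        requires_measurable = TRUE)
  expect_identical(render_protocol(q, 7, ont)$text,
                   render_protocol(q, 7, ont)$text)
})

test_that("implicit renderings use phrase lexicons and hide the ECOG keyword", {
  ont <- load_fixture_ontology()
  p <- patient_profile("2", "C4872", FALSE, 3, "implicit_poor")
  txt <- render_patient(p, 5, ont)$text
  expect_false(grepl("ECOG", txt))
  cfg <- default_config()
  expect_true(any(vapply(cfg$poor_health, grepl, logical(1), x = tolower(txt),
                         fixed = TRUE)))
  # the pipeline reads the interval 2-4 back out
  st <- extract_ecog(parse_document(txt, "patient"), cfg)
  expect_equal(c(st$min_level, st$max_level), c(2L, 4L))
})

test_that("profile invariants are enforced", {
  expect_error(patient_profile("x", "C3512", TRUE, 3, "implicit_good"),
               "implicit_good")
  expect_error(patient_profile("x", "C3512", TRUE, 1, "implicit_poor"),
               "implicit_poor")
  expect_error(patient_profile("x", "C3512", TRUE, 1,
                               mutations = "ATM", therapy_mentions = "ATM"),
               "disjoint")
  expect_error(protocol_profile("y"), "criterion")
})

test_that("the gene-synonym-swap confounder renders the synonym surface", {
  ont <- load_fixture_ontology()
  p <- patient_profile("4", "C3512", TRUE, 1, "explicit",
                       mutations = "CHK2",
                       confounders = "gene_synonym_swap")
  txt <- render_patient(p, 3, ont)$text
  expect_true(grepl("CHEK2", txt, fixed = TRUE))
  expect_false(grepl("\\bCHK2\\b", txt))
})

test_that("gold labels are computed from profiles without the pipeline", {
  ont <- load_fixture_ontology()
  syn <- load_gene_synonyms()
  p <- patient_profile("1", "C3512", TRUE, 1, "explicit",
                       lesions = list(list(site_category = "solid_organ",
                                           dims = 2.0)),
                       mutations = "CHEK2")
  q_all <- protocol_profile("1", required_cancer = "C2852",
                            requires_metastatic = TRUE,
                            ecog_requirement = ecog_requirement("le", 0L, 1L),
                            requires_measurable = TRUE,
                            required_mutations = "CHK2")
  expect_equal(gold_label(p, q_all, ont, syn), "match")
  # independent oracle computed inline from the same profiles
  oracle <- is_subtype("C3512", "C2852", ont) && p$metastatic &&
    (1 %in% 0:1) && (2.0 >= 1.0) && ("chk2" %in% "chk2")
  expect_true(oracle)
  # ECOG off by one flips the label
  q_ecog <- protocol_profile("2",
                             ecog_requirement = ecog_requirement("range", 0L, 0L))
  expect_equal(gold_label(p, q_ecog, ont, syn), "no_match")
  # synonym resolution is part of the ground truth
  q_mut <- protocol_profile("3",
                            ecog_requirement = ecog_requirement("le", 0L, 1L),
                            required_mutations = "CHK2")
  expect_equal(gold_label(p, q_mut, ont, syn), "match")
})

test_that("generate_corpus yields n_patients x n_protocols gold pairs", {
  b <- generate_corpus(12, 6, seed = 2)
  expect_length(b$patients, 12L)
  expect_length(b$protocols, 6L)
  expect_equal(nrow(b$gold), 72L)
  expect_equal(anyDuplicated(b$gold$pair_id), 0L)
  expect_true(all(b$gold$label %in% c("match", "no_match")))
})

test_that("corpus generation is reproducible and writes a readable bundle", {
  dir <- tempfile()
  b1 <- generate_corpus(4, 2, seed = 9, out_dir = dir)
  b2 <- generate_corpus(4, 2, seed = 9)
  expect_identical(lapply(b1$patients, `[[`, "raw_text"),
                   lapply(b2$patients, `[[`, "raw_text"))
  expect_identical(b1$gold, b2$gold)
  expect_true(file.exists(file.path(dir, "gold.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  docs <- read_manifest(file.path(dir, "manifest.json"))
  expect_length(docs, 6L)
  expect_identical(docs[[1]]$raw_text, b1$patients[[1]]$raw_text)
})

test_that("a confounder changes predictions only where it was injected", {
  ont <- load_fixture_ontology()
  lex <- default_lexicon(ont)
  clean <- generate_corpus(8, 4, seed = 21, index = ont)
  conf <- generate_corpus(8, 4, seed = 21,
                          confounder_rates = list(gene_synonym_swap = 0.6),
                          index = ont)
  affected <- vapply(conf$patient_profiles, function(p) {
    length(p$confounders) > 0
  }, logical(1))
  expect_true(any(affected))   # at rate 0.6 over 8 patients
  pred_clean <- match_all(clean$patients, clean$protocols, index = ont,
                          lex = lex)$predictions
  pred_conf <- match_all(conf$patients, conf$protocols, index = ont,
                         lex = lex)$predictions
  m <- merge(pred_clean, pred_conf, by = "pair_id",
             suffixes = c(".clean", ".conf"))
  changed <- m$decision.clean != m$decision.conf
  affected_ids <- vapply(conf$patient_profiles[affected], `[[`, "", "id")
  expect_true(all(m$patient_id.clean[changed] %in% affected_ids))
  # unaffected patients render byte-identically
  for (i in which(!affected)) {
    expect_identical(clean$patients[[i]]$raw_text,
                     conf$patients[[i]]$raw_text)
  }
})

test_that("annotation spans point at the planted surfaces", {
  b <- generate_corpus(3, 2, seed = 33)
  for (id in names(b$annotations)) {
    ann <- b$annotations[[id]]
    doc <- Filter(function(d) d$id == id, b$patients)[[1]]
    ok <- !is.na(ann$start)
    expect_true(all(ok))
    for (i in which(ok)) {
      expect_identical(
        trialmatchr:::substr0(doc$raw_text, ann$start[i], ann$end[i]),
        ann$surface[i]
      )
    }
  }
})
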