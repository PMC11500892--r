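# End-to-end pipeline: pre-processing, extraction, matching.

#' Pre-process a document into an annotated mention stream
#'
#' Runs the built-in lexicon tagger (plus any external tagger outputs
#' supplied through the interchange contract), merges by offset with
#' rectification, detects and expands abbreviations, and flags sentence-scope
#' negation.
#'
#' @param doc A `tm_document`.
#' @param lex A `tm_lexicon` (default: the bundled lexicon).
#' @param config Configuration list.
#' @param extra_outputs Optional list of `tm_tagger_output` from external
#'   taggers (e.g. read with [read_tagger_jsonl()]).
#' @return List with `mentions` (annotated data.frame) and `abbrev`
#'   (the `tm_abbrev` map).
#' @export
process_document <- function(doc, lex = NULL, config = default_config(),
                             extra_outputs = NULL) {
  if (is.null(lex)) lex <- default_lexicon()
  outputs <- c(list(tag_with_lexicon(doc, lex)), extra_outputs %||% list())
  mentions <- merge_outputs(outputs, doc$raw_text,
                            window = config$rectify_window %||% 40L)
  abbrev <- detect_abbreviations(doc)
  mentions <- expand_mentions(mentions, abbrev)
  mentions <- flag_negation(doc, mentions, config$negation_triggers)
  list(mentions = mentions, abbrev = abbrev)
}

# Criterion extraction for one processed document.
extract_all <- function(doc, mentions, index, config) {
  if (doc$kind == "patient") {
    lesions <- extract_lesions(doc, mentions, config$site_map)
    list(
      cancer = extract_cancer(doc, mentions, index),
      ecog = extract_ecog(doc, config),
      lesions = lesions,
      measurable = assess_measurability(lesions, config$measurable_cm,
                                        config$size_comparator),
      mutations = extract_mutations(doc, mentions)
    )
  } else {
    list(
      cancer = extract_cancer(doc, mentions, index),
      ecog = extract_ecog(doc, config),
      requires_measurable = protocol_requires_measurable(doc),
      mutations = extract_mutations(doc, mentions)
    )
  }
}

# Match pre-extracted patient and protocol findings.
match_extracted <- function(patient_doc, protocol_doc, p_ext, q_ext, index,
                            config, synonyms = NULL) {
  if (is.null(synonyms) && isTRUE(config$synonyms_enabled)) {
    synonyms <- load_gene_synonyms()
  }
  enabled <- config$criteria_enabled
  results <- list()
  if ("cancer_type" %in% enabled) {
    results <- c(results, list(match_cancer(p_ext$cancer, q_ext$cancer,
                                            index)))
  }
  if ("ecog" %in% enabled) {
    results <- c(results, list(match_ecog(p_ext$ecog, q_ext$ecog)))
  }
  if ("measurable" %in% enabled) {
    results <- c(results, list(match_measurable(p_ext$measurable,
                                                q_ext$requires_measurable)))
  }
  if ("mutation" %in% enabled) {
    syn <- if (isTRUE(config$synonyms_enabled)) synonyms else NULL
    results <- c(results, list(match_mutation(p_ext$mutations,
                                              q_ext$mutations, syn)))
  }
  build_report(patient_doc, protocol_doc, results, config)
}

#' Match one patient record against one protocol
#'
#' The full pipeline: pre-processing of both documents, extraction of the
#' four criteria, per-criterion matching, score, decision, and the
#' explanation report.
#'
#' @param patient_doc,protocol_doc `tm_document`s (or raw strings, which are
#'   parsed with ids `"patient"`/`"protocol"`).
#' @param index A `tm_ontology` (default: the bundled fixture thesaurus).
#' @param lex A `tm_lexicon` (default: derived from `index`).
#' @param config Configuration list.
#' @param synonyms Optional gene-synonym lookup; used only when
#'   `config$synonyms_enabled` is `TRUE`.
#' @return A `tm_report`.
#' @export
#' @examples
#' pt <- parse_document(paste(
#'   "The patient was diagnosed with metastatic lung adenocarcinoma.",
#'   "ECOG performance status of 1.",
#'   "CT shows a (2.3 x 1.1) cm mass in the liver."), "patient", id = "1")
#' pr <- parse_document(paste(
#'   "Inclusion Criteria:",
#'   "- Histologically confirmed metastatic adenocarcinoma.",
#'   "- ECOG 0-1.",
#'   "- Measurable disease per RECIST 1.1.", sep = "\n"),
#'   "protocol", id = "1")
#' match_pair(pt, pr)
match_pair <- function(patient_doc, protocol_doc, index = NULL, lex = NULL,
                       config = default_config(), synonyms = NULL) {
  if (is.character(patient_doc)) {
    patient_doc <- parse_document(patient_doc, "patient", id = "patient")
  }
  if (is.character(protocol_doc)) {
    protocol_doc <- parse_document(protocol_doc, "protocol", id = "protocol")
  }
  if (is.null(index)) index <- load_fixture_ontology(config$generic_blocklist)
  if (is.null(lex)) lex <- default_lexicon(index)
  p_ext <- extract_all(patient_doc,
                       process_document(patient_doc, lex, config)$mentions,
                       index, config)
  q_ext <- extract_all(protocol_doc,
                       process_document(protocol_doc, lex, config)$mentions,
                       index, config)
  match_extracted(patient_doc, protocol_doc, p_ext, q_ext, index, config,
                  synonyms)
}

#' Match every patient against every protocol
#'
#' Each document is pre-processed and extracted once; all pairs are then
#' matched. The returned prediction table has one row per pair.
#'
#' @param patients,protocols Lists of `tm_document`s.
#' @param index,lex,config,synonyms As in [match_pair()].
#' @return List with `reports` (list of `tm_report`) and `predictions`
#'   (data.frame: `patient_id`, `protocol_id`, `pair_id`, `n_met`,
#'   `n_required`, `score`, `decision`).
#' @export
match_all <- function(patients, protocols, index = NULL, lex = NULL,
                      config = default_config(), synonyms = NULL) {
  if (is.null(index)) index <- load_fixture_ontology(config$generic_blocklist)
  if (is.null(lex)) lex <- default_lexicon(index)
  p_exts <- lapply(patients, function(d) {
    extract_all(d, process_document(d, lex, config)$mentions, index, config)
  })
  q_exts <- lapply(protocols, function(d) {
    extract_all(d, process_document(d, lex, config)$mentions, index, config)
  })
  if (isTRUE(config$synonyms_enabled) && is.null(synonyms)) {
    synonyms <- load_gene_synonyms()
  }
  reports <- list()
  rows <- list()
  for (i in seq_along(patients)) {
    for (j in seq_along(protocols)) {
      rep <- match_extracted(patients[[i]], protocols[[j]], p_exts[[i]],
                             q_exts[[j]], index, config, synonyms)
      reports[[length(reports) + 1L]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rep$patient_id, protocol_id = rep$protocol_id,
        pair_id = paste0("patient", rep$patient_id, "_protocol",
                         rep$protocol_id),
        n_met = rep$n_met, n_required = rep$n_required,
        score = rep$score, decision = rep$decision, stringsAsFactors = FALSE
      )
    }
  }
  list(reports = reports, predictions = do.call(rbind, rows))
}
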