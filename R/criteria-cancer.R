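#' Extract cancer-type findings from a document
#'
#' Three passes over the merged, expanded, negation-flagged mention stream:
#' \enumerate{
#'   \item Every non-negated `disease` mention (expanded surface preferred)
#'     is mapped to a thesaurus concept with [map_to_concept()]; blocklisted
#'     generic concepts yield no finding.
#'   \item Organ+histology combination: for each sentence containing both a
#'     detected cancer finding and a non-negated `organ` mention, the
#'     combined string `"<organ> <cancer>"` is looked up and, on success,
#'     added as a more specific finding.
#'   \item Metastatic status. Patient records: if any
#'     `Metastasis`/`Secondary_Malignant`-tagged mention or the token
#'     "metastatic" occurs anywhere in the record, every finding is flagged
#'     metastatic. Protocols: a finding is metastatic only when a metastatic
#'     cue occurs in its own sentence.
#' }
#' Negated mentions yield no findings.
#'
#' @param doc A `tm_document`.
#' @param mentions Mention data.frame (merged, expanded, negation-flagged).
#' @param index A `tm_ontology`.
#' @return data.frame of findings: `code`, `name`, `term`, `metastatic`,
#'   `surface`, `start`, `end`, `sentence`, `section`, `source`.
#' @export
extract_cancer <- function(doc, mentions, index) {
  stopifnot(inherits(doc, "tm_document"), inherits(index, "tm_ontology"))
  empty <- data.frame(
    code = character(0), name = character(0), term = character(0),
    metastatic = logical(0), surface = character(0), start = integer(0),
    end = integer(0), sentence = integer(0), section = character(0),
    source = character(0), stringsAsFactors = FALSE
  )
  if (nrow(mentions) == 0L) return(empty)

  rows <- list()
  add <- function(code, term, surface, start, end) {
    si <- sentence_index(doc, start, end)
    rows[[length(rows) + 1L]] <<- data.frame(
      code = code, name = concept_name(code, index), term = term,
      metastatic = FALSE, surface = surface,
      start = as.integer(start), end = as.integer(end),
      sentence = si, section = section_of(doc, start), source = doc$kind,
      stringsAsFactors = FALSE
    )
  }

  terms <- match_surface(mentions)
  dis <- which(has_tag(mentions, "disease") & !mentions$negated)
  for (i in dis) {
    code <- map_to_concept(terms[i], index)
    if (!is.null(code)) {
      add(code, terms[i], mentions$surface[i], mentions$start[i],
          mentions$end[i])
    }
  }
  findings <- if (length(rows)) do.call(rbind, rows) else empty

  # organ + histology combination, sentence-scoped
  org <- which(has_tag(mentions, "organ") & !mentions$negated)
  if (nrow(findings) > 0L && length(org) > 0L) {
    for (i in org) {
      si <- sentence_index(doc, mentions$start[i], mentions$end[i])
      if (is.na(si)) next
      in_sen <- which(findings$sentence == si)
      for (f in in_sen) {
        combined <- paste(mentions$surface[i], findings$term[f])
        code2 <- map_to_concept(combined, index)
        if (is.null(code2)) next
        if (any(findings$code == code2 & findings$sentence == si)) next
        rows2 <- findings[f, , drop = FALSE]
        rows2$code <- code2
        rows2$name <- concept_name(code2, index)
        rows2$term <- combined
        rows2$surface <- combined
        findings <- rbind(findings, rows2)
      }
    }
  }
  if (nrow(findings) == 0L) return(empty)
  rownames(findings) <- NULL

  met_tags <- c("Metastasis", "Secondary_Malignant")
  if (doc$kind == "patient") {
    met_any <- any(has_tag(mentions, met_tags)) ||
      grepl("\\bmetastatic\\b", tolower(doc$raw_text))
    findings$metastatic <- met_any
  } else {
    met_sent <- unique(stats::na.omit(vapply(
      which(has_tag(mentions, met_tags)),
      function(i) sentence_index(doc, mentions$start[i], mentions$end[i]),
      NA_integer_
    )))
    findings$metastatic <- findings$sentence %in% met_sent
  }
  findings[order(findings$start), , drop = FALSE]
}

fmt_cancer <- function(name, metastatic) {
  paste0("cancer type ", name, ifelse(metastatic, " (metastatic)", ""))
}

#' Match patient and protocol cancer findings
#'
#' The protocol's requirement is built from its non-negated inclusion-section
#' findings. The criterion is satisfied when some patient finding is a
#' subtype of some required concept and the metastatic implication holds
#' (a metastatic requirement forces a metastatic patient finding). Patient
#' findings that are subtypes of exclusion-section protocol findings are
#' surfaced as exclusion conflicts (they never alter the score).
#'
#' @param patient,protocol Finding data.frames from [extract_cancer()].
#' @param index A `tm_ontology`.
#' @return A `tm_criterion_result`.
#' @export
match_cancer <- function(patient, protocol, index) {
  req <- protocol[protocol$section == "inclusion", , drop = FALSE]
  req <- req[!duplicated(paste(req$code, req$metastatic)), , drop = FALSE]
  required <- nrow(req) > 0L

  satisfied <- NA
  p_desc <- q_desc <- NA_character_
  if (required) {
    satisfied <- FALSE
    q_desc <- paste(unique(fmt_cancer(req$name, req$metastatic)),
                    collapse = " or ")
    p_desc <- if (nrow(patient) == 0L) {
      "no cancer type detected"
    } else {
      paste(unique(fmt_cancer(patient$name, patient$metastatic)),
            collapse = ", ")
    }
    for (p in seq_len(nrow(patient))) {
      for (q in seq_len(nrow(req))) {
        if (is_subtype(patient$code[p], req$code[q], index) &&
            (!req$metastatic[q] || patient$metastatic[p])) {
          satisfied <- TRUE
          p_desc <- fmt_cancer(patient$name[p], patient$metastatic[p])
          q_desc <- fmt_cancer(req$name[q], req$metastatic[q])
          break
        }
      }
      if (isTRUE(satisfied)) break
    }
  }

  exc <- protocol[protocol$section == "exclusion", , drop = FALSE]
  notes <- character(0)
  if (nrow(exc) > 0L && nrow(patient) > 0L) {
    for (q in seq_len(nrow(exc))) {
      hit <- vapply(patient$code,
                    function(pc) is_subtype(pc, exc$code[q], index),
                    logical(1))
      if (any(hit)) {
        notes <- c(notes, sprintf(
          "patient cancer type %s falls under protocol exclusion \"%s\"",
          patient$name[which(hit)[1]], exc$name[q]
        ))
      }
    }
  }
  criterion_result("cancer_type", required, satisfied, p_desc, q_desc,
                   exclusion_conflict = length(notes) > 0L,
                   exclusion_notes = notes)
}
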