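# The matching score, decision rule and explanation report.

#' Construct a criterion result
#'
#' One row of the explanation ledger: whether the protocol requires the
#' criterion, whether the patient satisfies it (`NA` when not required),
#' human-readable descriptions of both sides, and any exclusion-section
#' conflicts.
#'
#' @param criterion One of `"cancer_type"`, `"ecog"`, `"measurable"`,
#'   `"mutation"`.
#' @param required Logical: does the protocol require this criterion?
#' @param satisfied Logical or `NA` (must be `NA` iff not required).
#' @param patient_desc,protocol_desc Descriptions used in evidence lines.
#' @param exclusion_conflict Logical.
#' @param exclusion_notes Character vector of conflict descriptions.
#' @return A `tm_criterion_result`.
#' @export
criterion_result <- function(criterion, required, satisfied,
                             patient_desc = NA_character_,
                             protocol_desc = NA_character_,
                             exclusion_conflict = FALSE,
                             exclusion_notes = character(0)) {
  criterion <- match.arg(criterion,
                         c("cancer_type", "ecog", "measurable", "mutation"))
  if (!required && !is.na(satisfied)) {
    stop_invalid("satisfied must be NA when the criterion is not required")
  }
  if (required && is.na(satisfied)) {
    stop_invalid("satisfied must be TRUE/FALSE when the criterion is required")
  }
  structure(
    list(criterion = criterion, required = isTRUE(required),
         satisfied = satisfied, patient_desc = patient_desc,
         protocol_desc = protocol_desc,
         exclusion_conflict = isTRUE(exclusion_conflict),
         exclusion_notes = exclusion_notes),
    class = "tm_criterion_result"
  )
}

#' Matching score: criteria met over criteria required
#'
#' `score = n_met / n_required` where `n_required` counts criteria the
#' protocol requires and `n_met` those the patient additionally satisfies.
#' With no required criterion the score is undefined (`NA`) and the decision
#' becomes indeterminate.
#'
#' @param results List of `tm_criterion_result` (at most one per criterion).
#' @return List `n_met`, `n_required`, `score`.
#' @export
#' @examples
#' # a protocol requiring all four criteria, two of them met
#' rs <- list(
#'   criterion_result("cancer_type", TRUE, TRUE),
#'   criterion_result("ecog", TRUE, TRUE),
#'   criterion_result("measurable", TRUE, FALSE),
#'   criterion_result("mutation", TRUE, FALSE)
#' )
#' compute_score(rs)$score  # 0.5
compute_score <- function(results) {
  stopifnot(length(results) <= 4L)
  crits <- vapply(results, `[[`, "", "criterion")
  if (anyDuplicated(crits)) stop_invalid("duplicate criterion results")
  required <- vapply(results, `[[`, TRUE, "required")
  met <- vapply(results, function(r) isTRUE(r$satisfied), logical(1))
  n_required <- sum(required)
  n_met <- sum(met & required)
  list(n_met = n_met, n_required = n_required,
       score = if (n_required > 0L) n_met / n_required else NA_real_)
}

#' Threshold decision on a matching score
#'
#' A pair is a match only when the score strictly exceeds the threshold
#' (default 0.5, "greater evidence of matching than non-matching"); an
#' undefined score gives `indeterminate`.
#'
#' @param score Numeric score or `NA`.
#' @param config Configuration list (uses `threshold`).
#' @return `"match"`, `"no_match"` or `"indeterminate"`.
#' @export
decide <- function(score, config = default_config()) {
  if (is.null(score) || is.na(score)) return("indeterminate")
  if (score > config$threshold) "match" else "no_match"
}

criterion_order <- c("cancer_type", "ecog", "measurable", "mutation")

evidence_line <- function(patient_id, protocol_id, r) {
  sprintf("Patient %s has %s which %s Protocol %s which requires %s",
          patient_id, r$patient_desc,
          if (isTRUE(r$satisfied)) "matches" else "does not match",
          protocol_id, r$protocol_desc)
}

#' Assemble the match report for one patient-protocol pair
#'
#' Orders the criterion results (cancer, ECOG, measurable, mutation),
#' computes the score and decision, renders one deterministic evidence line
#' per required criterion, and collects exclusion-section conflicts as
#' flags for the human reviewer (flags never alter the score).
#'
#' @param patient,protocol `tm_document`s (ids are used in evidence lines).
#' @param results List of `tm_criterion_result`.
#' @param config Configuration list.
#' @return A `tm_report`.
#' @export
build_report <- function(patient, protocol, results,
                         config = default_config()) {
  crits <- vapply(results, `[[`, "", "criterion")
  results <- results[order(match(crits, criterion_order))]
  sc <- compute_score(results)
  decision <- decide(sc$score, config)
  req <- Filter(function(r) r$required, results)
  explanation <- vapply(req, function(r) {
    evidence_line(patient$id, protocol$id, r)
  }, "")
  flags <- unlist(lapply(results, function(r) {
    if (r$exclusion_conflict) {
      sprintf("Patient %s: %s of Protocol %s", patient$id,
              r$exclusion_notes, protocol$id)
    }
  })) %||% character(0)
  structure(
    list(patient_id = patient$id, protocol_id = protocol$id,
         criterion_results = results, n_met = sc$n_met,
         n_required = sc$n_required, score = sc$score, decision = decision,
         explanation = explanation, exclusion_flags = flags),
    class = "tm_report"
  )
}

#' @export
print.tm_report <- function(x, ...) {
  cat(sprintf("Patient %s vs Protocol %s\n", x$patient_id, x$protocol_id))
  cat(sprintf("  Matching score: %s (%d of %d required criteria met)\n",
              if (is.na(x$score)) "undefined" else format(round(x$score, 2)),
              x$n_met, x$n_required))
  cat(sprintf("  Decision: %s\n", x$decision))
  if (length(x$explanation)) {
    cat("  Evidence:\n")
    for (e in x$explanation) cat("   - ", e, "\n", sep = "")
  }
  for (r in x$criterion_results) {
    if (!r$required) {
      cat(sprintf("   - Criterion %s not required by the protocol\n",
                  r$criterion))
    }
  }
  if (length(x$exclusion_flags)) {
    cat("  Exclusion flags:\n")
    for (f in x$exclusion_flags) cat("   ! ", f, "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a match report to JSON
#'
#' @param report A `tm_report`.
#' @param path Optional output path; with `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    patient_id = report$patient_id,
    protocol_id = report$protocol_id,
    n_met = report$n_met,
    n_required = report$n_required,
    score = if (is.na(report$score)) NULL else report$score,
    decision = report$decision,
    criteria = lapply(report$criterion_results, function(r) {
      list(name = r$criterion, required = r$required,
           satisfied = if (is.na(r$satisfied)) NULL else r$satisfied,
           evidence = if (r$required) {
             evidence_line(report$patient_id, report$protocol_id, r)
           } else NULL)
    }),
    exclusion_flags = report$exclusion_flags
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
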