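# Evaluation against gold labels: confusion matrix and the four metrics.

#' Confusion matrix of match decisions against gold labels
#'
#' Predictions and gold labels are joined on pair id; the id sets must be
#' identical. Indeterminate predictions (no requirement detected) are
#' excluded from the counts by default, with the excluded total recorded in
#' the `n_indeterminate` attribute; set `indeterminate_as_no_match` in the
#' configuration to coerce them to `no_match` for a strictly binary matrix.
#'
#' @param predictions data.frame with columns `pair_id` and `decision`
#'   (`"match"`, `"no_match"`, `"indeterminate"`).
#' @param gold data.frame with columns `pair_id` and `label` (`"match"`,
#'   `"no_match"`).
#' @param config Configuration list.
#' @return A `tm_confusion`: list `tp`, `fn`, `fp`, `tn` with attribute
#'   `n_indeterminate`.
#' @export
confusion <- function(predictions, gold, config = default_config()) {
  stopifnot(all(c("pair_id", "decision") %in% names(predictions)),
            all(c("pair_id", "label") %in% names(gold)))
  if (anyDuplicated(predictions$pair_id) || anyDuplicated(gold$pair_id)) {
    stop_invalid("duplicate pair ids")
  }
  if (!setequal(predictions$pair_id, gold$pair_id)) {
    stop_invalid("prediction and gold pair-id sets differ")
  }
  m <- merge(predictions[, c("pair_id", "decision")],
             gold[, c("pair_id", "label")], by = "pair_id")
  ind <- m$decision == "indeterminate"
  n_ind <- sum(ind)
  if (isTRUE(config$indeterminate_as_no_match)) {
    m$decision[ind] <- "no_match"
  } else {
    m <- m[!ind, , drop = FALSE]
  }
  cm <- structure(
    list(
      tp = sum(m$decision == "match" & m$label == "match"),
      fn = sum(m$decision == "no_match" & m$label == "match"),
      fp = sum(m$decision == "match" & m$label == "no_match"),
      tn = sum(m$decision == "no_match" & m$label == "no_match")
    ),
    class = "tm_confusion"
  )
  attr(cm, "n_indeterminate") <- n_ind
  cm
}

#' Build a confusion matrix from raw counts
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `tm_confusion`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "tm_confusion")
}

#' @export
print.tm_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("gold match", "gold no-match"),
                              c("pred match", "pred no-match")))
  print(m)
  invisible(x)
}

#' Precision, sensitivity, specificity and accuracy
#'
#' `precision = tp/(tp+fp)`, `sensitivity = tp/(tp+fn)`,
#' `specificity = tn/(tn+fp)`, `accuracy = (tp+tn)/total`. A metric with a
#' zero denominator is reported as `NA` (absent), never as 0. Percent
#' renderings are rounded half-up to 2 decimals.
#'
#' @param cm A `tm_confusion`.
#' @return List with the four fractions and a `percent` named vector.
#' @export
#' @examples
#' metrics(confusion_matrix(14, 11, 5, 42))$percent
metrics <- function(cm) {
  stopifnot(inherits(cm, "tm_confusion"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  out <- list(
    precision = frac(cm$tp, cm$tp + cm$fp),
    sensitivity = frac(cm$tp, cm$tp + cm$fn),
    specificity = frac(cm$tn, cm$tn + cm$fp),
    accuracy = frac(cm$tp + cm$tn, total)
  )
  out$percent <- vapply(out, function(x) {
    if (is.na(x)) NA_real_ else round_half_up(100 * x, 2)
  }, 0.0)
  out
}

#' Evaluate predictions against a gold-label file
#'
#' @param predictions Prediction data.frame (see [confusion()]) or a path to
#'   a JSON-lines report file.
#' @param gold Gold data.frame or path to a CSV with columns
#'   `patient_id,protocol_id,label`.
#' @param config Configuration list.
#' @return List with `confusion` and `metrics`.
#' @export
evaluate_predictions <- function(predictions, gold,
                                 config = default_config()) {
  if (is.character(gold)) {
    gold <- utils::read.csv(gold, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  if (!"pair_id" %in% names(gold)) {
    gold$pair_id <- paste0("patient", gold$patient_id, "_protocol",
                           gold$protocol_id)
  }
  if (is.character(predictions)) {
    lines <- readLines(predictions, warn = FALSE)
    recs <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
    predictions <- data.frame(
      patient_id = vapply(recs, `[[`, "", "patient_id"),
      protocol_id = vapply(recs, `[[`, "", "protocol_id"),
      decision = vapply(recs, `[[`, "", "decision"),
      stringsAsFactors = FALSE
    )
  }
  if (!"pair_id" %in% names(predictions)) {
    predictions$pair_id <- paste0("patient", predictions$patient_id,
                                  "_protocol", predictions$protocol_id)
  }
  cm <- confusion(predictions, gold, config)
  list(confusion = cm, metrics = metrics(cm))
}
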