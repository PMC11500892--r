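# ECOG performance status: explicit regex extraction around the "ECOG"
# keyword, with an implicit functional-status fallback for patient records.

ecog_regex <- paste0(
  "(?i)\\bECOG\\b",
  "(?:\\s+performance\\s+status|\\s+PS)?",
  "(?:\\s+score)?",
  "(?:\\s+(?:of|is))?",
  "\\s*:?\\s*",
  "(<=|>=|=|\u2264|\u2265)?",
  "\\s*([0-9])",
  "(?:\\s*[-\u2013]\\s*([0-9]))?"
)

#' Extract ECOG performance status or requirement
#'
#' Explicit extraction looks for the keyword "ECOG" anywhere in the text and
#' captures an optional comparator sign and a single digit or digit range.
#' Protocol documents yield an `tm_ecog_requirement` (comparator defaults to
#' `le` when no sign is given); patient documents yield a `tm_ecog_status`
#' interval (`[d, d]` for a single digit). Digits outside 0-4 raise a parse
#' warning and the hit is skipped.
#'
#' When a patient record has no explicit hit, implicit extraction scans the
#' good-health and poor-health phrase lexicons: good maps to the interval
#' `[0, 1]`, poor to `[2, 4]`; when both occur, the phrase latest in the
#' record wins. With no hit at all the result is `NULL`.
#'
#' @param doc A `tm_document`.
#' @param config Configuration list (phrase lexicons).
#' @return `tm_ecog_status`, `tm_ecog_requirement`, or `NULL`.
#' @export
extract_ecog <- function(doc, config = default_config()) {
  text <- doc$raw_text
  m <- gregexpr(ecog_regex, text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      cs <- attr(m, "capture.start")[k, ]
      cl <- attr(m, "capture.length")[k, ]
      cap <- function(j) {
        if (cl[j] == 0L) NA_character_
        else substring(text, cs[j], cs[j] + cl[j] - 1L)
      }
      d1 <- as.integer(cap(2))
      d2 <- if (!is.na(cap(3))) as.integer(cap(3)) else NA_integer_
      if (d1 > 4L || (!is.na(d2) && d2 > 4L)) {
        warning("ECOG value outside 0-4 skipped in document ", doc$id,
                call. = FALSE)
        next
      }
      sign <- cap(1)
      span <- c(as.integer(m[k]) - 1L,
                as.integer(m[k]) - 1L + attr(m, "match.length")[k])
      if (doc$kind == "protocol") {
        if (!is.na(d2)) {
          lo <- min(d1, d2); hi <- max(d1, d2)
          return(ecog_requirement("range", lo, hi, span))
        }
        comparator <- switch(
          if (is.na(sign)) "le" else sign,
          "<=" = "le", "\u2264" = "le",
          ">=" = "ge", "\u2265" = "ge",
          "=" = "eq", "le"
        )
        lo <- switch(comparator, le = 0L, ge = d1, eq = d1)
        hi <- switch(comparator, le = d1, ge = 4L, eq = d1)
        return(ecog_requirement(comparator, lo, hi, span))
      } else {
        if (!is.na(d2)) {
          return(ecog_status(min(d1, d2), max(d1, d2), "explicit", span))
        }
        return(ecog_status(d1, d1, "explicit", span))
      }
    }
  }
  if (doc$kind != "patient") return(NULL)

  # implicit: phrase lexicons, latest mention wins
  lower <- tolower(text)
  best_pos <- -1L
  best_cls <- NULL
  scan <- function(phrases, cls) {
    for (ph in phrases) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ph), "\\b")
      mm <- gregexpr(pat, lower, perl = TRUE)[[1]]
      if (mm[1] == -1L) next
      pos <- max(as.integer(mm))
      if (pos > best_pos) {
        best_pos <<- pos
        best_cls <<- cls
      }
    }
  }
  scan(tolower(config$good_health), "good")
  scan(tolower(config$poor_health), "poor")
  if (is.null(best_cls)) return(NULL)
  if (best_cls == "good") ecog_status(0L, 1L, "implicit", c(best_pos - 1L, best_pos))
  else ecog_status(2L, 4L, "implicit", c(best_pos - 1L, best_pos))
}

ecog_status <- function(min_level, max_level, source_kind, evidence = NULL) {
  stopifnot(min_level >= 0L, min_level <= max_level, max_level <= 4L)
  structure(list(min_level = as.integer(min_level),
                 max_level = as.integer(max_level),
                 source_kind = source_kind, evidence = evidence),
            class = "tm_ecog_status")
}

ecog_requirement <- function(comparator, bound_low, bound_high,
                             evidence = NULL) {
  comparator <- match.arg(comparator, c("le", "ge", "range", "eq"))
  stopifnot(bound_low >= 0L, bound_high <= 4L, bound_low <= bound_high)
  structure(list(comparator = comparator,
                 bound_low = as.integer(bound_low),
                 bound_high = as.integer(bound_high), evidence = evidence),
            class = "tm_ecog_requirement")
}

# Admissible ECOG levels under a requirement.
ecog_admissible <- function(req) {
  switch(req$comparator,
         le = seq.int(0L, req$bound_high),
         ge = seq.int(req$bound_low, 4L),
         range = seq.int(req$bound_low, req$bound_high),
         eq = req$bound_low)
}

ecog_status_desc <- function(status) {
  if (is.null(status)) return("no ECOG status recorded")
  lv <- if (status$min_level == status$max_level) {
    as.character(status$min_level)
  } else {
    paste0(status$min_level, "\u2013", status$max_level)
  }
  sprintf("ECOG status [%s]", lv)
}

ecog_req_desc <- function(req) {
  switch(req$comparator,
         range = sprintf("ECOG status of %d\u2013%d", req$bound_low,
                         req$bound_high),
         le = sprintf("ECOG status of \u2264%d", req$bound_high),
         ge = sprintf("ECOG status of \u2265%d", req$bound_low),
         eq = sprintf("ECOG status of %d", req$bound_low))
}

#' Match patient ECOG status against a protocol requirement
#'
#' Conservative interval containment: the criterion is satisfied only when
#' the entire patient status interval lies inside the requirement's
#' admissible set. An implicit poor-health interval `[2, 4]` therefore never
#' satisfies a 0-1 requirement, and an implicit good-health interval `[0, 1]`
#' does not satisfy an exact-0 requirement.
#'
#' @param status `tm_ecog_status` or `NULL`.
#' @param req `tm_ecog_requirement` or `NULL`.
#' @return A `tm_criterion_result`.
#' @export
match_ecog <- function(status, req) {
  required <- !is.null(req)
  satisfied <- NA
  p_desc <- q_desc <- NA_character_
  if (required) {
    adm <- ecog_admissible(req)
    satisfied <- !is.null(status) &&
      all(seq.int(status$min_level, status$max_level) %in% adm)
    p_desc <- ecog_status_desc(status)
    q_desc <- ecog_req_desc(req)
  }
  criterion_result("ecog", required, satisfied, p_desc, q_desc)
}
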