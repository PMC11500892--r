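# Measurable disease under RECIST 1.1 site and size rules.

size_paren_regex <- paste0(
  "\\(\\s*([0-9]+(?:\\.[0-9]+)?)",
  "\\s*[x\u00d7]\\s*([0-9]+(?:\\.[0-9]+)?)",
  "(?:\\s*[x\u00d7]\\s*([0-9]+(?:\\.[0-9]+)?))?",
  "\\s*\\)\\s*(cm|mm)"
)
size_bare_regex <- "([0-9]+(?:\\.[0-9]+)?)\\s*(cm|mm)\\b"

# Parse all tumour-size expressions in one sentence; returns numeric vector
# of longest dimensions in cm (one element per size expression).
parse_sizes <- function(sentence) {
  out <- numeric(0)
  masked <- sentence
  m <- gregexpr(size_paren_regex, sentence, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      frag <- substring(sentence, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      nums <- as.numeric(regmatches(frag,
                                    gregexpr("[0-9]+(?:\\.[0-9]+)?", frag))[[1]])
      unit <- if (grepl("mm\\s*$", frag, ignore.case = TRUE)) "mm" else "cm"
      d <- max(nums)
      if (unit == "mm") d <- d / 10
      if (is.finite(d) && d <= 50) out <- c(out, d)
      else warning("implausible lesion size skipped: ", frag, call. = FALSE)
      blank <- strrep(" ", attr(m, "match.length")[k])
      substring(masked, m[k], m[k] + attr(m, "match.length")[k] - 1L) <- blank
    }
  }
  m2 <- gregexpr(size_bare_regex, masked, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m2[1] != -1L) {
    for (k in seq_along(m2)) {
      frag <- substring(masked, m2[k],
                        m2[k] + attr(m2, "match.length")[k] - 1L)
      d <- as.numeric(regmatches(frag, regexpr("[0-9]+(?:\\.[0-9]+)?",
                                               frag)))
      if (grepl("mm\\s*$", frag, ignore.case = TRUE)) d <- d / 10
      if (is.finite(d) && d <= 50) out <- c(out, d)
      else warning("implausible lesion size skipped: ", frag, call. = FALSE)
    }
  }
  out
}

#' Extract lesion findings from a patient record
#'
#' Tumour sizes are parsed per sentence with the patterns `(a x b) cm`,
#' `(a x b x c) cm` and bare `a cm` (also `mm`, converted to cm; `x` or the
#' multiplication sign; optional spaces). The longest dimension of each size
#' expression is retained. The lesion site is taken from the anatomic-site
#' mention in the same sentence, normalized through the configured site map
#' to `solid_organ`, `lymph_node` or `bone`; with no site mention the
#' category is `unknown`.
#'
#' @param doc A patient `tm_document`.
#' @param mentions Mention data.frame.
#' @param site_map Named character vector `surface -> category`; defaults
#'   from [default_config()].
#' @return data.frame of lesions: `site_category`, `longest_dimension_cm`,
#'   `site_surface`, `sentence`.
#' @export
extract_lesions <- function(doc, mentions,
                            site_map = default_config()$site_map) {
  stopifnot(inherits(doc, "tm_document"))
  sen <- doc$sentences
  rows <- list()
  for (i in seq_len(nrow(sen))) {
    s_txt <- substr0(doc$raw_text, sen$start[i], sen$end[i])
    sizes <- parse_sizes(s_txt)
    if (length(sizes) == 0L) next
    category <- "unknown"
    site_surface <- NA_character_
    if (nrow(mentions) > 0L) {
      in_sen <- which(mentions$start >= sen$start[i] &
                        mentions$end <= sen$end[i] &
                        has_tag(mentions, c("organ", "site")) &
                        !mentions$negated)
      for (j in in_sen) {
        key <- tolower(mentions$surface[j])
        if (!is.na(site_map[key])) {
          category <- unname(site_map[key])
          site_surface <- mentions$surface[j]
          break
        }
      }
    }
    for (d in sizes) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_category = category, longest_dimension_cm = d,
        site_surface = site_surface, sentence = i, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(site_category = character(0),
                      longest_dimension_cm = numeric(0),
                      site_surface = character(0), sentence = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Does any lesion qualify as measurable disease?
#'
#' RECIST 1.1 site rules: a solid-organ lesion qualifies at 1.0 cm, a lymph
#' node at 1.5 cm (short-axis convention); bone and unknown-site lesions
#' never qualify. The boundary comparator defaults to `>=` ("1 cm or above")
#' and can be set to `>` for the strict reading.
#'
#' @param lesions Lesion data.frame from [extract_lesions()].
#' @param thresholds Named numeric: `solid_organ`, `lymph_node` minimum in cm.
#' @param comparator `">="` (default) or `">"`.
#' @return Logical scalar.
#' @export
assess_measurability <- function(lesions,
                                 thresholds = default_config()$measurable_cm,
                                 comparator = default_config()$size_comparator) {
  if (nrow(lesions) == 0L) return(FALSE)
  cmp <- if (comparator == ">") `>` else `>=`
  ok <- vapply(seq_len(nrow(lesions)), function(i) {
    cat_i <- lesions$site_category[i]
    if (!cat_i %in% names(thresholds)) return(FALSE)
    isTRUE(cmp(lesions$longest_dimension_cm[i], thresholds[[cat_i]]))
  }, logical(1))
  any(ok)
}

#' Does a protocol require measurable disease?
#'
#' `TRUE` iff the inclusion section contains "measurable disease" or
#' "measuring" (case-insensitive) and contains no mention of
#' "non-measurable disease".
#'
#' @param doc A protocol `tm_document`.
#' @return Logical scalar.
#' @export
protocol_requires_measurable <- function(doc) {
  stopifnot(inherits(doc, "tm_document"))
  inc <- tolower(section_text(doc, "inclusion"))
  if (!nzchar(inc)) return(FALSE)
  (grepl("measurable disease", inc, fixed = TRUE) ||
     grepl("measuring", inc, fixed = TRUE)) &&
    !grepl("non-measurable disease", inc, fixed = TRUE)
}

#' Match the measurable-disease criterion
#'
#' When the protocol does not require measurable disease the criterion is
#' omitted from the score denominator (patients with and without measurable
#' disease both qualify).
#'
#' @param patient_measurable Logical from [assess_measurability()].
#' @param required Logical from [protocol_requires_measurable()].
#' @return A `tm_criterion_result`.
#' @export
match_measurable <- function(patient_measurable, required) {
  satisfied <- NA
  p_desc <- q_desc <- NA_character_
  if (required) {
    satisfied <- isTRUE(patient_measurable)
    p_desc <- if (patient_measurable) "measurable disease"
              else "no measurable disease"
    q_desc <- "measurable disease"
  }
  criterion_result("measurable", required, satisfied, p_desc, q_desc)
}
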