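#' Detect parenthetical abbreviation definitions
#'
#' Scans for the convention `LONG FORM (SHORT)`: a 2-10 character
#' parenthetical whose characters are at least half uppercase letters, with a
#' long form recovered from the words preceding the parenthesis by
#' initial-letter back-scanning (Schwartz-Hearst style: each short-form
#' character must be accounted for, in order, working backwards; the first
#' short-form character must start a word). Only the first definition of each
#' short form is kept.
#'
#' @param doc A `tm_document`.
#' @return A `tm_abbrev` map: named list `short form -> list(long_form,
#'   def_start, def_end)` where the span covers the parenthetical content.
#' @export
#' @examples
#' d <- parse_document(
#'   "Staging used response evaluation criteria in solid tumors (RECIST).",
#'   "patient"
#' )
#' detect_abbreviations(d)$entries$RECIST$long_form
detect_abbreviations <- function(doc) {
  stopifnot(inherits(doc, "tm_document"))
  text <- doc$raw_text
  entries <- list()
  m <- gregexpr("\\(([^()\n]{1,60})\\)", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      inner <- substring(text, starts[k] + 1L, starts[k] + lens[k] - 2L)
      short <- trimws(inner)
      if (nchar(short) < 2L || nchar(short) > 10L) next
      n_upper <- nchar(gsub("[^A-Z]", "", short))
      if (n_upper / nchar(short) < 0.5) next
      if (!is.null(entries[[short]])) next
      # candidate long form: words before '(' in the same sentence
      pre_end0 <- starts[k] - 1L                       # 0-based end of prefix
      si <- sentence_index(doc, max(0L, pre_end0 - 1L))
      pre_start0 <- if (is.na(si)) 0L else doc$sentences$start[si]
      prefix <- substr0(text, pre_start0, pre_end0)
      max_words <- min(nchar(short) + 5L, nchar(short) * 2L)
      wm <- gregexpr("\\S+", prefix)[[1]]
      if (wm[1] == -1L) next
      w_starts <- as.integer(wm)
      take_from <- w_starts[max(1L, length(w_starts) - max_words + 1L)]
      candidate <- trimws(substring(prefix, take_from))
      long_form <- find_long_form(short, candidate)
      if (is.null(long_form)) next
      entries[[short]] <- list(
        long_form = long_form,
        def_start = starts[k],                         # 0-based: content start
        def_end = starts[k] + lens[k] - 2L
      )
    }
  }
  structure(list(entries = entries), class = "tm_abbrev")
}

# Schwartz-Hearst long-form recovery: match short-form characters backwards
# through the candidate; the first character must begin a word.
find_long_form <- function(short, candidate) {
  s <- tolower(gsub("[^A-Za-z0-9]", "", short))
  if (nchar(s) == 0L) return(NULL)
  l <- tolower(candidate)
  sc <- strsplit(s, "")[[1]]
  lc <- strsplit(l, "")[[1]]
  si <- length(sc)
  li <- length(lc)
  while (si > 0L) {
    ch <- sc[si]
    while (li > 0L &&
           (lc[li] != ch ||
            (si == 1L && li > 1L && grepl("[a-z0-9]", lc[li - 1L])))) {
      li <- li - 1L
    }
    if (li == 0L) return(NULL)
    li <- li - 1L
    si <- si - 1L
  }
  # expand to the start of the word containing position li + 1
  start <- li + 1L
  lf <- trimws(substring(candidate, start))
  if (nchar(lf) == 0L) NULL else lf
}

#' Expand abbreviated mentions to their long forms
#'
#' Every mention whose surface equals a known short form (outside its
#' defining parenthesis) gains `expanded = long form`; downstream matching
#' prefers the expanded surface. Mentions of undefined abbreviations are left
#' unexpanded, which downstream concept mapping may then misinterpret -- a
#' documented limitation of abbreviation-blind matching.
#'
#' @param mentions Mention data.frame.
#' @param abbrev A `tm_abbrev` from [detect_abbreviations()].
#' @return The mentions with the `expanded` column filled where applicable.
#' @export
expand_mentions <- function(mentions, abbrev) {
  if (length(abbrev$entries) == 0L || nrow(mentions) == 0L) return(mentions)
  for (i in seq_len(nrow(mentions))) {
    e <- abbrev$entries[[mentions$surface[i]]]
    if (is.null(e)) next
    inside_def <- mentions$start[i] < e$def_end && mentions$end[i] > e$def_start
    if (!inside_def) mentions$expanded[i] <- e$long_form
  }
  mentions
}

#' Sentence-scope negation flagging
#'
#' For each sentence containing at least one trigger phrase
#' (case-insensitive substring), every mention whose span lies within that
#' sentence is marked `negated = TRUE`. This is the simplified sentence-level
#' variant of NegEx: scope is the whole sentence, not a directional window.
#'
#' @param doc A `tm_document` with sentence spans.
#' @param mentions Mention data.frame.
#' @param triggers Character vector of lowercase trigger phrases; defaults to
#'   `default_config()$negation_triggers`.
#' @return The mentions with `negated` updated; no other field changes.
#' @export
flag_negation <- function(doc, mentions,
                          triggers = default_config()$negation_triggers) {
  stopifnot(inherits(doc, "tm_document"))
  if (nrow(mentions) == 0L || length(triggers) == 0L) return(mentions)
  triggers <- tolower(triggers[nzchar(triggers)])
  sen <- doc$sentences
  for (i in seq_len(nrow(sen))) {
    s_txt <- tolower(substr0(doc$raw_text, sen$start[i], sen$end[i]))
    hit <- any(vapply(triggers, function(tr) grepl(tr, s_txt, fixed = TRUE),
                      logical(1)))
    if (!hit) next
    inside <- mentions$start >= sen$start[i] & mentions$end <= sen$end[i]
    mentions$negated[inside] <- TRUE
  }
  mentions
}

# Surface used for downstream matching: long form when available.
match_surface <- function(mentions) {
  ifelse(is.na(mentions$expanded), mentions$surface, mentions$expanded)
}
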