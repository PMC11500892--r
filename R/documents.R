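#' Parse a patient record or protocol into a document model
#'
#' Turns raw text into a `tm_document`: the raw text, labelled sections and
#' sentence spans. Protocol documents are segmented at case-insensitive,
#' line-anchored "Inclusion Criteria" / "Exclusion Criteria" headings (colon
#' optional); any text before the first heading becomes a `body` section.
#' Patient documents are a single `body` section. All spans are 0-based,
#' half-open character offsets into `text`.
#'
#' Section spans partition `[0, nchar(text))`, so concatenating the section
#' texts in order reconstructs the input exactly. Sentence spans are computed
#' by a deterministic rule-based splitter that breaks at newlines and at
#' `.?!` followed by whitespace and an uppercase/digit/bullet start, but not
#' inside parentheses, after single capital-letter initials, or after common
#' abbreviations.
#'
#' @param text Document text (non-empty).
#' @param kind `"patient"` or `"protocol"`.
#' @param id Document identifier (defaults to `"doc"`).
#' @return A `tm_document` list with elements `id`, `kind`, `raw_text`,
#'   `sections` (data.frame: `label`, `start`, `end`, `content_start`) and
#'   `sentences` (data.frame: `start`, `end`).
#' @export
#' @examples
#' d <- parse_document("Inclusion Criteria:\nA\nExclusion Criteria:\nB", "protocol")
#' d$sections$label
parse_document <- function(text, kind = c("patient", "protocol"), id = "doc") {
  kind <- match.arg(kind)
  if (!is_string(text) || nchar(text) == 0L || !grepl("[^[:space:]]", text)) {
    stop_invalid("document text must be a non-empty string")
  }
  n <- nchar(text)

  if (kind == "patient") {
    sections <- data.frame(
      label = "body", start = 0L, end = n, content_start = 0L,
      stringsAsFactors = FALSE
    )
  } else {
    pat <- "(?mi)^[ \\t]*(inclusion|exclusion)[ \\t]+criteria:?[ \\t]*$"
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      sections <- data.frame(
        label = "body", start = 0L, end = n, content_start = 0L,
        stringsAsFactors = FALSE
      )
    } else {
      starts <- as.integer(m) - 1L                       # 0-based
      lens <- attr(m, "match.length")
      labels <- tolower(sub(
        "^[ \\t]*([A-Za-z]+).*$", "\\1",
        substring(text, starts + 1L, starts + lens), perl = TRUE
      ))
      if (anyDuplicated(labels)) {
        stop_invalid("protocol has more than one ", labels[duplicated(labels)][1],
                     " section heading")
      }
      ends <- c(starts[-1], n)
      sections <- data.frame(
        label = labels, start = starts, end = ends,
        content_start = starts + lens, stringsAsFactors = FALSE
      )
      if (starts[1] > 0L) {
        sections <- rbind(
          data.frame(label = "body", start = 0L, end = starts[1],
                     content_start = 0L, stringsAsFactors = FALSE),
          sections
        )
      }
    }
  }

  structure(
    list(id = id, kind = kind, raw_text = text, sections = sections,
         sentences = sentence_spans(text)),
    class = "tm_document"
  )
}

#' @export
print.tm_document <- function(x, ...) {
  cat(sprintf("<tm_document %s [%s], %d chars, %d section(s), %d sentence(s)>\n",
              x$id, x$kind, nchar(x$raw_text), nrow(x$sections),
              nrow(x$sentences)))
  invisible(x)
}

#' Section label at a character offset
#'
#' @param doc A `tm_document`.
#' @param offset 0-based character offset, `0 <= offset < nchar(raw_text)`.
#' @return `"inclusion"`, `"exclusion"` or `"body"`.
#' @export
section_of <- function(doc, offset) {
  stopifnot(inherits(doc, "tm_document"))
  if (!is.numeric(offset) || length(offset) != 1L || is.na(offset) ||
      offset < 0 || offset >= nchar(doc$raw_text)) {
    stop_invalid("offset out of range [0, ", nchar(doc$raw_text), ")")
  }
  s <- doc$sections
  hit <- which(s$start <= offset & offset < s$end)
  s$label[hit[1]]
}

#' Text of a section, excluding its heading line
#'
#' @param doc A `tm_document`.
#' @param label Section label; returns `""` when the section is absent.
#' @return The section content as a string.
#' @export
section_text <- function(doc, label) {
  s <- doc$sections
  i <- which(s$label == label)
  if (length(i) == 0L) return("")
  substr0(doc$raw_text, s$content_start[i[1]], s$end[i[1]])
}

# Common clinical/reference abbreviations that do not end a sentence.
.sentence_abbrevs <- c(
  "dr", "mr", "mrs", "ms", "vs", "e.g", "i.e", "etc", "fig", "no", "st", "approx"
)

#' Rule-based sentence spans
#'
#' @param text Document text.
#' @return data.frame with 0-based half-open `start`/`end` spans, ordered,
#'   non-overlapping, covering every non-whitespace character.
#' @export
sentence_spans <- function(text) {
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  breaks <- integer(0)                       # break AFTER this 1-based index
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- max(0L, depth - 1L)
    if (ch == "\n") {
      breaks <- c(breaks, i)
    } else if (ch %in% c(".", "?", "!") && depth == 0L && i < n) {
      if (!chars[i + 1L] %in% c(" ", "\t")) next
      k <- i + 1L
      while (k <= n && chars[k] %in% c(" ", "\t")) k <- k + 1L
      if (k > n || !grepl("[A-Z0-9(\\-\u2022*]", chars[k])) next
      if (ch == ".") {
        # abbreviation guard: token immediately before the period
        j <- i - 1L
        while (j >= 1L && grepl("[A-Za-z.]", chars[j])) j <- j - 1L
        tok <- if (j + 1L <= i - 1L) {
          paste(chars[seq.int(j + 1L, i - 1L)], collapse = "")
        } else ""
        if (nchar(tok) == 1L && grepl("[A-Z]", tok)) next
        if (tolower(tok) %in% .sentence_abbrevs) next
      }
      breaks <- c(breaks, i)
    }
  }
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, n)                    # 1-based inclusive segments
  out <- list()
  for (s in seq_along(seg_start)) {
    a <- seg_start[s]; b <- seg_end[s]
    if (a > b) next
    while (a <= b && grepl("[[:space:]]", chars[a])) a <- a + 1L
    while (b >= a && grepl("[[:space:]]", chars[b])) b <- b - 1L
    if (a > b) next
    out[[length(out) + 1L]] <- c(a - 1L, b)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Index (1-based row) of the sentence containing a span, or NA.
sentence_index <- function(doc, start, end = start + 1L) {
  s <- doc$sentences
  hit <- which(s$start <= start & end <= s$end)
  if (length(hit) == 0L) {
    # mention may sit in trimmed whitespace or straddle; fall back to start
    hit <- which(s$start <= start & start < s$end)
  }
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

sentence_text <- function(doc, i) {
  substr0(doc$raw_text, doc$sentences$start[i], doc$sentences$end[i])
}

#' Read a batch manifest of documents
#'
#' The manifest is a JSON array of objects `{id, kind, path}`; paths are
#' resolved relative to the manifest file.
#'
#' @param path Manifest path.
#' @return List of `tm_document`s.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_invalid("manifest not found: ", path)
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  lapply(entries, function(e) {
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    txt <- paste(readLines(p, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    parse_document(txt, kind = e$kind, id = as.character(e$id))
  })
}
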