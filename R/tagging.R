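#' @title Entity mentions and the tagger contract
#' @description
#' Entity mentions are kept in a data.frame with one row per mention:
#' `surface` (the tagged text), `start`/`end` (0-based half-open span into
#' the raw text), `tag` and `tagger` (list-columns: the set of tag labels and
#' the taggers that produced them), `negated`, `expanded` (abbreviation long
#' form or `NA`) and `unrectifiable`. Any external tagger can feed the
#' pipeline by emitting the JSON-lines dialect read by
#' [read_tagger_jsonl()]; the built-in [tag_with_lexicon()] tagger covers
#' fully offline use.
#' @name tagging
NULL

# Empty mention data.frame with the canonical columns.
mention_df <- function(surface = character(), start = integer(),
                       end = integer(), tag = list(), tagger = list()) {
  df <- data.frame(
    surface = surface, start = as.integer(start), end = as.integer(end),
    stringsAsFactors = FALSE
  )
  df$tag <- tag
  df$tagger <- tagger
  df$negated <- rep(FALSE, nrow(df))
  df$expanded <- rep(NA_character_, nrow(df))
  df$unrectifiable <- rep(FALSE, nrow(df))
  df
}

normalize_lexicon_key <- function(x) {
  squish(gsub("[^a-z0-9]+", " ", tolower(x)))
}

#' Build a lexicon
#'
#' A lexicon maps normalized surface strings to a single tag label
#' (`disease`, `gene`, `organ`, `site`, `Metastasis`, `Secondary_Malignant`,
#' ...). Keys are lowercased with punctuation collapsed to spaces.
#'
#' @param entries Named character vector: `names` are surface strings,
#'   values are tag labels.
#' @return A `tm_lexicon`.
#' @export
lexicon <- function(entries) {
  stopifnot(is.character(entries), length(entries) > 0L,
            !is.null(names(entries)))
  keys <- normalize_lexicon_key(names(entries))
  if (any(keys == "")) stop_invalid("lexicon keys must be non-empty")
  ent <- entries
  names(ent) <- keys
  ent <- ent[!duplicated(names(ent))]
  structure(list(entries = ent), class = "tm_lexicon")
}

#' Read a lexicon from a TSV file (`surface<TAB>tag`)
#' @param path File path; lines starting with `#` are ignored.
#' @return A `tm_lexicon`.
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  lexicon(stats::setNames(tab[[2]], tab[[1]]))
}

#' Derive disease lexicon entries from an ontology
#'
#' Every preferred name and synonym in the concept store becomes a
#' `disease`-tagged lexicon entry, emulating a thesaurus-backed NER tagger.
#'
#' @param index A `tm_ontology` from [load_ontology()].
#' @return Named character vector suitable for [lexicon()].
#' @export
lexicon_from_ontology <- function(index) {
  surfaces <- unlist(lapply(index$concepts, function(cc) {
    c(cc$preferred_name, cc$synonyms)
  }), use.names = FALSE)
  surfaces <- unique(surfaces[nzchar(surfaces)])
  stats::setNames(rep("disease", length(surfaces)), surfaces)
}

#' The built-in default lexicon
#'
#' Disease entries derived from the bundled synthetic Neoplasm-branch
#' thesaurus, plus the packaged gene/organ/site/metastasis entries
#' (`inst/extdata/lexicon_extras.tsv`).
#'
#' @param index Ontology to derive disease entries from; defaults to the
#'   bundled fixture thesaurus.
#' @return A `tm_lexicon`.
#' @export
default_lexicon <- function(index = load_fixture_ontology()) {
  extras_path <- system.file("extdata", "lexicon_extras.tsv",
                             package = "trialmatchr", mustWork = TRUE)
  tab <- utils::read.delim(extras_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  extras <- stats::setNames(tab[[2]], tab[[1]])
  # expression variants ("BRCA1 mut") for every gene entry
  genes <- names(extras)[extras == "gene"]
  variants <- stats::setNames(rep("gene", length(genes)),
                              paste(genes, "mut"))
  lexicon(c(lexicon_from_ontology(index), extras, variants))
}

#' Tag a document with a lexicon
#'
#' Case-insensitive, longest-match-first scan over token n-grams (n <= 6).
#' Matches cannot overlap within this tagger; each match yields one
#' single-tag mention.
#'
#' @param doc A `tm_document`.
#' @param lex A `tm_lexicon`.
#' @param tagger_name Name recorded as the mention source.
#' @return A `tm_tagger_output`: list of `tagger_name` and `mentions`
#'   (data.frame with a plain character `tag` column).
#' @export
tag_with_lexicon <- function(doc, lex, tagger_name = "lexicon") {
  stopifnot(inherits(doc, "tm_document"), inherits(lex, "tm_lexicon"))
  if (length(lex$entries) == 0L) stop_invalid("lexicon is empty")
  env <- list2env(as.list(lex$entries), hash = TRUE)
  text <- doc$raw_text
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  out <- list()
  if (m[1] != -1L) {
    starts <- as.integer(m)                 # 1-based
    lens <- attr(m, "match.length")
    toks <- tolower(substring(text, starts, starts + lens - 1L))
    nt <- length(toks)
    i <- 1L
    while (i <= nt) {
      matched <- FALSE
      for (n in seq.int(min(6L, nt - i + 1L), 1L)) {
        key <- paste(toks[i:(i + n - 1L)], collapse = " ")
        tag <- env[[key]]
        if (!is.null(tag)) {
          s0 <- starts[i] - 1L
          e0 <- starts[i + n - 1L] + lens[i + n - 1L] - 1L
          out[[length(out) + 1L]] <- list(
            surface = substr0(text, s0, e0), start = s0, end = e0, tag = tag
          )
          i <- i + n
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  mentions <- if (length(out)) {
    data.frame(
      surface = vapply(out, `[[`, "", "surface"),
      start = vapply(out, `[[`, 0L, "start"),
      end = vapply(out, `[[`, 0L, "end"),
      tag = vapply(out, `[[`, "", "tag"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(surface = character(0), start = integer(0), end = integer(0),
               tag = character(0), stringsAsFactors = FALSE)
  }
  structure(list(tagger_name = tagger_name, mentions = mentions),
            class = "tm_tagger_output")
}

# Search for `surface` near the claimed start. Returns list(start, end, ok).
rectify_span <- function(raw_text, surface, start, window = 40L) {
  len <- nchar(surface)
  n <- nchar(raw_text)
  if (start >= 0L && start + len <= n &&
      substr0(raw_text, start, start + len) == surface) {
    return(list(start = start, end = start + len, ok = TRUE))
  }
  lo <- max(0L, start - window)
  hi <- min(n - len, start + window)
  if (hi >= lo) {
    cand <- seq.int(lo, hi)
    pieces <- substring(raw_text, cand + 1L, cand + len)
    for (exact in c(TRUE, FALSE)) {
      hits <- if (exact) which(pieces == surface)
              else which(tolower(pieces) == tolower(surface))
      if (length(hits)) {
        best <- cand[hits][which.min(abs(cand[hits] - start))]
        return(list(start = best, end = best + len, ok = TRUE))
      }
    }
  }
  list(start = start, end = start + len, ok = FALSE)
}

#' Rectify a mention's offsets against the raw text
#'
#' If the claimed span does not reproduce the surface string, the raw text is
#' searched within `window` characters of the claimed start (case-sensitive
#' first, then case-insensitive; nearest occurrence wins). On failure the
#' mention is flagged `unrectifiable` and excluded from merging.
#'
#' @param mention A list or one-row data.frame with `surface`, `start`, `end`.
#' @param raw_text The document text.
#' @param window Search window in characters (default 40).
#' @return The mention with a corrected span, or with `unrectifiable = TRUE`.
#' @export
rectify_offsets <- function(mention, raw_text, window = 40L) {
  stopifnot(window > 0L)
  r <- rectify_span(raw_text, mention$surface[[1]],
                    as.integer(mention$start[[1]]), as.integer(window))
  mention$start <- r$start
  mention$end <- r$end
  mention$unrectifiable <- !r$ok
  mention
}

#' Merge multi-tagger outputs by offset position
#'
#' Each mention is offset-rectified; unrectifiable mentions are dropped.
#' Mentions whose rectified spans coincide exactly are merged into one
#' mention carrying the union of (tag, tagger) pairs. Partially overlapping
#' spans are kept separate.
#'
#' @param outputs List of `tm_tagger_output` over the same document.
#' @param raw_text The document text.
#' @param window Rectification window (default 40).
#' @return Mention data.frame (see [tagging]) sorted by span start.
#' @export
merge_outputs <- function(outputs, raw_text, window = 40L) {
  if (inherits(outputs, "tm_tagger_output")) outputs <- list(outputs)
  rows <- list()
  for (out in outputs) {
    mm <- out$mentions
    tagger <- out$tagger_name %||% "unknown"
    for (k in seq_len(nrow(mm))) {
      r <- rectify_span(raw_text, mm$surface[k], mm$start[k], window)
      if (!r$ok) next
      tags <- if (is.list(mm$tag)) mm$tag[[k]] else mm$tag[k]
      tgs <- if (!is.null(mm$tagger) && is.list(mm$tagger)) mm$tagger[[k]]
             else rep(tagger, length(tags))
      rows[[length(rows) + 1L]] <- list(
        start = r$start, end = r$end,
        surface = substr0(raw_text, r$start, r$end),
        tag = tags, tagger = tgs
      )
    }
  }
  if (length(rows) == 0L) return(mention_df())
  key <- vapply(rows, function(r) paste(r$start, r$end), "")
  groups <- split(rows, key)
  merged <- lapply(groups, function(g) {
    pairs <- unique(do.call(rbind, lapply(g, function(r) {
      data.frame(tag = r$tag, tagger = r$tagger, stringsAsFactors = FALSE)
    })))
    list(start = g[[1]]$start, end = g[[1]]$end, surface = g[[1]]$surface,
         tag = pairs$tag, tagger = pairs$tagger)
  })
  ord <- order(
    vapply(merged, `[[`, 0L, "start"),
    vapply(merged, `[[`, 0L, "end")
  )
  merged <- merged[ord]
  df <- mention_df(
    surface = vapply(merged, `[[`, "", "surface"),
    start = vapply(merged, `[[`, 0L, "start"),
    end = vapply(merged, `[[`, 0L, "end"),
    tag = lapply(merged, `[[`, "tag"),
    tagger = lapply(merged, `[[`, "tagger")
  )
  df
}

# TRUE for mentions carrying any of the given tag labels.
has_tag <- function(mentions, labels) {
  vapply(mentions$tag, function(tg) any(tg %in% labels), logical(1))
}

#' Read tagger output in the JSON-lines interchange dialect
#'
#' One mention per line:
#' `{"tagger": str, "surface": str, "start": int, "end": int, "tag": str}`.
#'
#' @param path JSON-lines file.
#' @return List of `tm_tagger_output`, one per tagger name present.
#' @export
read_tagger_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  by_tagger <- split(recs, vapply(recs, `[[`, "", "tagger"))
  lapply(names(by_tagger), function(nm) {
    rs <- by_tagger[[nm]]
    structure(list(
      tagger_name = nm,
      mentions = data.frame(
        surface = vapply(rs, `[[`, "", "surface"),
        start = vapply(rs, function(r) as.integer(r$start), 0L),
        end = vapply(rs, function(r) as.integer(r$end), 0L),
        tag = vapply(rs, `[[`, "", "tag"),
        stringsAsFactors = FALSE
      )
    ), class = "tm_tagger_output")
  })
}
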