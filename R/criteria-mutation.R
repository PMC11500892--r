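# Genetic mutation mentions and token-overlap matching.

#' Extract mutation-relevant mentions
#'
#' Keeps mentions tagged `gene`, `mutation` or `DNA`. A mention gets
#' `therapy_context = TRUE` when it names a targeted-therapy rather than a
#' tumour alteration: immediately preceded by "anti" plus hyphen/space (as in
#' "anti-HER2 therapy") or immediately followed by hyphen/space plus
#' "targeted" (as in "VEGF-targeted"). Therapy-context and negated mentions
#' are excluded from matching.
#'
#' @param doc A `tm_document`.
#' @param mentions Mention data.frame.
#' @return data.frame: `token`, `surface`, `therapy_context`, `negated`,
#'   `section`, `start`, `end`.
#' @export
extract_mutations <- function(doc, mentions) {
  stopifnot(inherits(doc, "tm_document"))
  keep <- which(has_tag(mentions, c("gene", "mutation", "DNA")))
  if (length(keep) == 0L) {
    return(data.frame(token = character(0), surface = character(0),
                      therapy_context = logical(0), negated = logical(0),
                      section = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  text <- doc$raw_text
  out <- lapply(keep, function(i) {
    s <- mentions$start[i]
    e <- mentions$end[i]
    pre <- substr0(text, max(0L, s - 8L), s)
    post <- substr0(text, e, min(nchar(text), e + 10L))
    therapy <- grepl("(?i)\\banti[-\u2013 ]$", pre, perl = TRUE) ||
      grepl("(?i)^[-\u2013 ]targeted\\b", post, perl = TRUE)
    data.frame(token = mentions$surface[i], surface = mentions$surface[i],
               therapy_context = therapy, negated = mentions$negated[i],
               section = section_of(doc, s), start = s, end = e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Load the gene-synonym table
#'
#' Reads a TSV `canonical<TAB>synonyms` (`|`-separated) and returns a
#' lowercase lookup `variant -> canonical` that also covers "`<gene> mut`"
#' expression variants of every canonical symbol and synonym.
#'
#' @param path Table path; defaults to the bundled table.
#' @return Named character vector (names are lowercase variants).
#' @export
load_gene_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_synonyms.tsv",
                        package = "trialmatchr", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
  map <- character(0)
  for (i in seq_len(nrow(tab))) {
    canonical <- tolower(tab[[1]][i])
    syns <- tolower(strsplit(tab[[2]][i], "|", fixed = TRUE)[[1]])
    variants <- unique(c(canonical, syns,
                         paste(c(canonical, syns), "mut")))
    map[variants] <- canonical
  }
  map
}

# Canonicalize gene tokens. Without a synonym table this is plain
# lowercasing; with one, expression variants ("BRCA1 mut") are standardized
# by stripping the trailing " mut" and variants are resolved through the
# table.
canonicalize_genes <- function(tokens, synonyms) {
  toks <- tolower(tokens)
  if (is.null(synonyms)) return(toks)
  toks <- sub(" mut$", "", toks)
  hit <- synonyms[toks]
  ifelse(is.na(hit), toks, unname(hit))
}

#' Match patient and protocol mutation mentions
#'
#' The protocol requirement is built from eligible (non-negated,
#' non-therapy-context) inclusion-section mentions. Tokens are compared
#' case-insensitively; the criterion is satisfied when the token
#' intersection is non-empty. With a synonym table supplied, tokens are
#' canonicalized before intersecting (default off, so unresolved synonyms
#' such as CHEK2 vs CHK2 fail to match). Protocol mutation mentions inside
#' exclusion sections are reported as exclusion conflicts, never as
#' requirements.
#'
#' @param patient,protocol Mention data.frames from [extract_mutations()].
#' @param synonyms `NULL`, or a lookup from [load_gene_synonyms()].
#' @return A `tm_criterion_result`.
#' @export
match_mutation <- function(patient, protocol, synonyms = NULL) {
  eligible <- function(df) df[!df$therapy_context & !df$negated, , drop = FALSE]
  pat <- eligible(patient)
  prot <- eligible(protocol)
  req <- prot[prot$section == "inclusion", , drop = FALSE]
  required <- nrow(req) > 0L

  satisfied <- NA
  p_desc <- q_desc <- NA_character_
  if (required) {
    p_tok <- canonicalize_genes(pat$token, synonyms)
    q_tok <- canonicalize_genes(req$token, synonyms)
    overlap <- intersect(p_tok, q_tok)
    satisfied <- length(overlap) > 0L
    p_desc <- if (nrow(pat) == 0L) "no eligible mutation mentions"
              else sprintf("mutations [%s]",
                           paste(sort(unique(pat$token)), collapse = ", "))
    q_desc <- sprintf("mutations [%s]",
                      paste(sort(unique(req$token)), collapse = ", "))
  }

  exc <- prot[prot$section == "exclusion", , drop = FALSE]
  notes <- character(0)
  if (nrow(exc) > 0L && nrow(pat) > 0L) {
    clash <- intersect(canonicalize_genes(pat$token, synonyms),
                       canonicalize_genes(exc$token, synonyms))
    if (length(clash) > 0L) {
      notes <- sprintf(
        "patient mutation %s appears in the protocol exclusion criteria",
        toupper(clash)
      )
    }
  }
  criterion_result("mutation", required, satisfied, p_desc, q_desc,
                   exclusion_conflict = length(notes) > 0L,
                   exclusion_notes = notes)
}
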