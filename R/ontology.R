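#' Normalize a term for thesaurus lookup
#'
#' Lowercases, strips punctuation to spaces, collapses whitespace, sorts the
#' words lexicographically and re-joins them. Word-order variants of the same
#' name ("Lung Adenocarcinoma", "Adenocarcinoma, Lung") normalize
#' identically. Idempotent.
#'
#' @param term Non-empty string.
#' @return Normalized string.
#' @export
#' @examples
#' normalize_term("Lung Adenocarcinoma")  # "adenocarcinoma lung"
normalize_term <- function(term) {
  if (!is_string(term) || !grepl("[^[:space:]]", term)) {
    stop_invalid("term must be a non-empty string")
  }
  x <- squish(gsub("[^a-z0-9]+", " ", tolower(term)))
  if (x == "") stop_invalid("term normalizes to the empty string: ", term)
  paste(sort(strsplit(x, " ", fixed = TRUE)[[1]]), collapse = " ")
}

#' Load a concept store (Neoplasm-branch thesaurus dialect)
#'
#' Reads a flat TSV with header
#' `code<TAB>preferred_name<TAB>synonyms<TAB>parents` (synonyms and parents
#' `|`-separated, empty allowed) and builds lookup indexes: preferred names
#' and synonyms are indexed under [normalize_term()]. Parent edges must
#' resolve within the file and the parent graph must be acyclic (multi-parent
#' DAGs are supported).
#'
#' @param path TSV file path.
#' @param blocklist Character vector of concept codes too generic to identify
#'   a cancer type; [map_to_concept()] never returns them.
#' @return A `tm_ontology`: `concepts` (named list of concept records),
#'   `preferred_index`, `synonym_index`, `blocklist`.
#' @export
load_ontology <- function(path, blocklist = default_config()$generic_blocklist) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "#",
                           na.strings = character(0))
  needed <- c("code", "preferred_name", "synonyms", "parents")
  if (!all(needed %in% names(tab))) {
    stop_invalid("ontology file must have columns: ",
                 paste(needed, collapse = ", "))
  }
  if (anyDuplicated(tab$code)) stop_invalid("duplicate concept codes")
  split_bar <- function(x) {
    if (is.na(x) || x == "") character(0)
    else strsplit(x, "|", fixed = TRUE)[[1]]
  }
  concepts <- lapply(seq_len(nrow(tab)), function(i) {
    list(code = tab$code[i], preferred_name = tab$preferred_name[i],
         synonyms = split_bar(tab$synonyms[i]),
         parents = split_bar(tab$parents[i]))
  })
  names(concepts) <- tab$code
  all_parents <- unique(unlist(lapply(concepts, `[[`, "parents")))
  if (!all(all_parents %in% tab$code)) {
    stop_invalid("dangling parent code(s): ",
                 paste(setdiff(all_parents, tab$code), collapse = ", "))
  }

  pref <- new.env(hash = TRUE, parent = emptyenv())
  syn <- new.env(hash = TRUE, parent = emptyenv())
  for (cc in concepts) {
    assign(normalize_term(cc$preferred_name), cc$code, envir = pref)
    for (s in cc$synonyms) {
      key <- normalize_term(s)
      assign(key, unique(c(syn[[key]], cc$code)), envir = syn)
    }
  }
  ont <- structure(
    list(concepts = concepts, preferred_index = pref, synonym_index = syn,
         blocklist = intersect(blocklist, tab$code)),
    class = "tm_ontology"
  )
  check_acyclic(ont)
  ont
}

# Depth-first cycle check over parent edges.
check_acyclic <- function(ont) {
  state <- new.env(hash = TRUE, parent = emptyenv())  # 1 = visiting, 2 = done
  visit <- function(code) {
    st <- state[[code]]
    if (identical(st, 2L)) return(invisible())
    if (identical(st, 1L)) stop_invalid("cycle in ontology at ", code)
    assign(code, 1L, envir = state)
    for (p in ont$concepts[[code]]$parents) visit(p)
    assign(code, 2L, envir = state)
  }
  for (code in names(ont$concepts)) visit(code)
  invisible(ont)
}

#' The bundled synthetic Neoplasm-branch fixture thesaurus
#'
#' A ~46-concept miniature of the NCI Thesaurus Neoplasm branch (root code
#' C3262) constructed for offline use: same flat dialect, plausible codes,
#' multi-parent DAG shape, generic concepts for the blocklist. It is a
#' synthetic stand-in, not an NCI Thesaurus export; a real export in the same
#' dialect loads through [load_ontology()] unchanged.
#'
#' @param blocklist Blocklisted codes (defaults from [default_config()]).
#' @return A `tm_ontology`.
#' @export
load_fixture_ontology <- function(blocklist = default_config()$generic_blocklist) {
  load_ontology(
    system.file("extdata", "neoplasm_fixture_synthetic.tsv",
                package = "trialmatchr", mustWork = TRUE),
    blocklist = blocklist
  )
}

#' Map a term to a concept code
#'
#' Two-tier lookup of the normalized term: preferred names first, synonyms
#' only when no preferred name matches. Hits on the generic blocklist return
#' `NULL`. A multi-code synonym hit is resolved deterministically:
#' fewest-parents first (the more general concept), then lexicographic code
#' order.
#'
#' @param term The surface string to map.
#' @param index A `tm_ontology`.
#' @return A concept code, or `NULL` when the term does not map.
#' @export
map_to_concept <- function(term, index) {
  stopifnot(inherits(index, "tm_ontology"))
  key <- tryCatch(normalize_term(term), error = function(e) NULL)
  if (is.null(key)) return(NULL)
  hit <- index$preferred_index[[key]]
  if (!is.null(hit)) {
    if (hit %in% index$blocklist) return(NULL)
    return(hit)
  }
  hits <- index$synonym_index[[key]]
  hits <- setdiff(hits, index$blocklist)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    np <- vapply(hits, function(h) length(index$concepts[[h]]$parents), 0L)
    hits <- hits[order(np, hits)]
  }
  hits[1]
}

#' Is one concept a subtype of another?
#'
#' `TRUE` iff `ancestor` is reachable from `child` via parent edges;
#' reflexive (`child == ancestor` is `TRUE`), so a cancer matches a protocol
#' requiring exactly that cancer.
#'
#' @param child,ancestor Concept codes present in the store.
#' @param index A `tm_ontology`.
#' @return Logical scalar.
#' @export
is_subtype <- function(child, ancestor, index) {
  stopifnot(inherits(index, "tm_ontology"))
  if (is.null(index$concepts[[child]])) stop_invalid("unknown code: ", child)
  if (is.null(index$concepts[[ancestor]])) {
    stop_invalid("unknown code: ", ancestor)
  }
  if (child == ancestor) return(TRUE)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  queue <- index$concepts[[child]]$parents
  while (length(queue)) {
    code <- queue[[1]]
    queue <- queue[-1]
    if (code == ancestor) return(TRUE)
    if (!is.null(seen[[code]])) next
    assign(code, TRUE, envir = seen)
    queue <- c(queue, index$concepts[[code]]$parents)
  }
  FALSE
}

#' Preferred name of a concept
#' @param code Concept code.
#' @param index A `tm_ontology`.
#' @return The preferred name string.
#' @export
concept_name <- function(code, index) {
  cc <- index$concepts[[code]]
  if (is.null(cc)) stop_invalid("unknown code: ", code)
  cc$preferred_name
}

# All codes whose subtype closure includes `code` (descendants + self).
descendants_of <- function(code, index) {
  codes <- names(index$concepts)
  codes[vapply(codes, function(k) is_subtype(k, code, index), logical(1))]
}
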