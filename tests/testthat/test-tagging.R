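test_that("lexicon tagging is longest-match-first and case-insensitive", {
  d <- parse_document("Biopsy revealed Mucinous Adenocarcinoma in the specimen.",
                      "patient")
  out <- tag_with_lexicon(d, tiny_lexicon())
  dis <- out$mentions[out$mentions$tag == "disease", ]
  expect_equal(nrow(dis), 1L)
  expect_equal(dis$surface, "Mucinous Adenocarcinoma")
  # oracle: exhaustive n-gram enumeration finds no longer lexicon match
  toks <- regmatches(d$raw_text, gregexpr("[A-Za-z0-9]+", d$raw_text))[[1]]
  keys <- unlist(lapply(seq_along(toks), function(i) {
    vapply(i:min(length(toks), i + 5), function(j) {
      tolower(paste(toks[i:j], collapse = " "))
    }, "")
  }))
  in_lex <- keys[keys %in% names(tiny_lexicon()$entries)]
  expect_equal(max(lengths(strsplit(in_lex, " "))), 2L)
})

test_that("gene symbols are tagged and unmatched text yields no mentions", {
  d <- parse_document("Pathogenic BRCA1 alteration reported.", "patient")
  out <- tag_with_lexicon(d, tiny_lexicon())
  expect_true(any(out$mentions$surface == "BRCA1" &
                    out$mentions$tag == "gene"))
  d2 <- parse_document("Nothing relevant appears in this line.", "patient")
  expect_equal(nrow(tag_with_lexicon(d2, tiny_lexicon())$mentions), 0L)
})

test_that("coincident spans from several taggers merge into one mention", {
  raw <- "Dx: mucinous adenocarcinoma confirmed."
  s <- regexpr("mucinous adenocarcinoma", raw) - 1L
  e <- s + nchar("mucinous adenocarcinoma")
  mk <- function(name, tag) {
    structure(list(tagger_name = name, mentions = data.frame(
      surface = "mucinous adenocarcinoma", start = s, end = e, tag = tag,
      stringsAsFactors = FALSE
    )), class = "tm_tagger_output")
  }
  merged <- merge_outputs(list(mk("BERN2", "disease"),
                               mk("SciSpacy", "ENTITY"),
                               mk("DeepPhe", "Adenocarcinoma")), raw)
  expect_equal(nrow(merged), 1L)
  expect_setequal(merged$tag[[1]], c("disease", "ENTITY", "Adenocarcinoma"))
  expect_setequal(merged$tagger[[1]], c("BERN2", "SciSpacy", "DeepPhe"))
  expect_identical(trialmatchr:::substr0(raw, merged$start, merged$end),
                   merged$surface)
})

test_that("disjoint spans from two taggers concatenate without merging", {
  raw <- "sarcoma here and adenocarcinoma there"
  mk <- function(name, surf) {
    s <- regexpr(surf, raw, fixed = TRUE) - 1L
    structure(list(tagger_name = name, mentions = data.frame(
      surface = surf, start = s, end = s + nchar(surf), tag = "disease",
      stringsAsFactors = FALSE
    )), class = "tm_tagger_output")
  }
  merged <- merge_outputs(list(mk("A", "sarcoma"), mk("B", "adenocarcinoma")),
                          raw)
  # brute-force pairwise comparison: no two spans coincide
  key <- paste(merged$start, merged$end)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(merged), 2L)
  expect_true(all(diff(merged$start) > 0))
})

test_that("offset rectification searches a +/- 40 character window", {
  raw <- paste0(strrep("x", 50), "adenocarcinoma", strrep("y", 50))
  m <- list(surface = "adenocarcinoma", start = 53L, end = 67L)  # off by +3
  r <- rectify_offsets(m, raw)
  expect_false(r$unrectifiable)
  expect_equal(r$start, 50L)
  expect_identical(trialmatchr:::substr0(raw, r$start, r$end), "adenocarcinoma")

  ok <- rectify_offsets(list(surface = "adenocarcinoma", start = 50L,
                             end = 64L), raw)
  expect_equal(ok$start, 50L)
  expect_false(ok$unrectifiable)

  # exhaustive substring search confirms absence within the window
  far <- list(surface = "sarcoma", start = 5L, end = 12L)
  expect_false(grepl("sarcoma", substr(raw, 1, 5 + 40 + 7)))
  expect_true(rectify_offsets(far, raw)$unrectifiable)
})

test_that("merge invariants hold: surface fidelity, idempotence, size bound", {
  set.seed(7)
  lex <- tiny_lexicon()
  for (rep in 1:20) {
    words <- sample(c(names(lex$entries), random_words(10)), 12,
                    replace = TRUE)
    raw <- paste(words, collapse = " ")
    d <- parse_document(raw, "patient")
    o1 <- tag_with_lexicon(d, lex, "t1")
    o2 <- tag_with_lexicon(d, lex, "t2")
    merged <- merge_outputs(list(o1, o2), raw)
    # every mention reproduces the raw text at its span
    if (nrow(merged) > 0) {
      expect_identical(
        vapply(seq_len(nrow(merged)), function(i) {
          trialmatchr:::substr0(raw, merged$start[i], merged$end[i])
        }, ""),
        merged$surface
      )
    }
    # idempotence: re-merging the merged stream changes nothing
    again <- merge_outputs(
      list(structure(list(tagger_name = "merged", mentions = merged),
                     class = "tm_tagger_output")), raw)
    expect_equal(again$start, merged$start)
    expect_equal(again$end, merged$end)
    expect_equal(lapply(again$tag, sort), lapply(merged$tag, sort))
    # size bound: merged size <= sum of inputs, equal iff no coincidences
    expect_lte(nrow(merged), nrow(o1$mentions) + nrow(o2$mentions))
  }
})

test_that("external tagger JSON-lines round-trip through the contract", {
  f <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"tagger":"ext","surface":"BRCA1","start":11,"end":16,"tag":"gene"}',
    '{"tagger":"ext","surface":"sarcoma","start":20,"end":27,"tag":"disease"}'
  ), f)
  outs <- read_tagger_jsonl(f)
  expect_length(outs, 1L)
  expect_equal(outs[[1]]$tagger_name, "ext")
  expect_equal(outs[[1]]$mentions$surface, c("BRCA1", "sarcoma"))
  raw <- "Gene panel: BRCA1 and sarcoma mentioned."
  merged <- merge_outputs(outs, raw)
  expect_equal(nrow(merged), 2L)
})
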