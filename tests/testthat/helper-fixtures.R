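# Shared fixtures built in code.

# Write an ontology data.frame (code, preferred_name, synonyms, parents) to
# a temp TSV and load it.
make_ontology <- function(df, blocklist = character(0)) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_ontology(f, blocklist = blocklist)
}

# A tiny three-level ontology used across criterion tests.
tiny_ontology <- function(blocklist = "X0") {
  make_ontology(data.frame(
    code = c("X0", "X1", "X2", "X3", "X4", "X5"),
    preferred_name = c("Malignant Neoplasm", "Carcinoma", "Adenocarcinoma",
                       "Lung Adenocarcinoma", "Sarcoma", "Osteosarcoma"),
    synonyms = c("Cancer", "", "", "Adenocarcinoma of the Lung", "", ""),
    parents = c("", "X0", "X1", "X2", "X0", "X4"),
    stringsAsFactors = FALSE
  ), blocklist = blocklist)
}

tiny_lexicon <- function() {
  lexicon(c(
    "adenocarcinoma" = "disease",
    "lung adenocarcinoma" = "disease",
    "mucinous adenocarcinoma" = "disease",
    "sarcoma" = "disease",
    "osteosarcoma" = "disease",
    "solid tumors" = "disease",
    "malignant neoplasm" = "disease",
    "lung" = "organ",
    "liver" = "organ",
    "axillary lymph node" = "site",
    "l4 vertebra" = "site",
    "metastatic" = "Metastasis",
    "BRCA1" = "gene",
    "HER2" = "gene",
    "VEGF" = "gene",
    "ATM" = "gene",
    "CHEK2" = "gene",
    "CHK2" = "gene"
  ))
}

# Random mention data.frame over a text, for property tests.
random_words <- function(n, alphabet = letters[1:6], min_len = 2,
                         max_len = 6) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, "")
}

# Construct a random single-parent-or-DAG ontology frame with n concepts.
random_dag_frame <- function(n) {
  codes <- sprintf("N%02d", seq_len(n))
  parents <- vapply(seq_len(n), function(i) {
    if (i == 1L) return("")
    k <- sample(1:min(2, i - 1), 1)
    paste(sample(codes[seq_len(i - 1)], k), collapse = "|")
  }, "")
  data.frame(
    code = codes,
    preferred_name = paste("concept", random_words(n, letters, 5, 8),
                           seq_len(n)),
    synonyms = "",
    parents = parents,
    stringsAsFactors = FALSE
  )
}

expect_no_error <- function(expr) expect_error(expr, NA)
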