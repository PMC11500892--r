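# Synthetic corpus generator: seeded patient notes, protocols and gold
# labels with controllable error-mode confounders. Gold labels are computed
# from the structured profiles alone (never by running the NLP pipeline).

.confounder_names <- c("undefined_abbrev", "negated_cancer",
                       "gene_synonym_swap", "expression_variant",
                       "size_in_mm")

# Cancers a synthetic patient may carry (leaf-ish concepts).
.patient_cancer_pool <- c(
  "C3512",  # Lung Adenocarcinoma
  "C4872",  # Breast Carcinoma
  "C7700",  # Ovarian Serous Adenocarcinoma
  "C5105",  # Colorectal Adenocarcinoma
  "C8294",  # Pancreatic Adenocarcinoma
  "C2919",  # Prostate Adenocarcinoma
  "C3099",  # Hepatocellular Carcinoma
  "C9385",  # Renal Cell Carcinoma
  "C3510",  # Cutaneous Melanoma
  "C3158",  # Leiomyosarcoma
  "C9145",  # Osteosarcoma
  "C3058"   # Glioblastoma
)

# Cancers a protocol may require (mid-level or leaf; no hematologic branch).
.protocol_cancer_pool <- c(
  "C2852",  # Adenocarcinoma
  "C3512",  # Lung Adenocarcinoma
  "C2926",  # Lung Non-Small Cell Carcinoma
  "C4872",  # Breast Carcinoma
  "C4908",  # Ovarian Carcinoma
  "C5105",  # Colorectal Adenocarcinoma
  "C3224",  # Melanoma
  "C9306",  # Sarcoma
  "C3099",  # Hepatocellular Carcinoma
  "C9385"   # Renal Cell Carcinoma
)

.mutation_pool <- c("ATM", "ATR", "BRCA1", "BRCA2", "CHK2", "PALB2",
                    "RAD51C", "TP53", "KRAS", "EGFR", "PIK3CA")
.extra_gene_pool <- c("MSH2", "MLH1", "NBN", "FGFR2", "IDH1")
.therapy_gene_pool <- c("HER2", "VEGF", "EGFR")
.swap_map <- c(CHK2 = "CHEK2", HER2 = "ERBB2", TP53 = "p53")

# Organ + histology phrasings that exercise the combination pass.
.combo_renderings <- list(
  C3512 = c(head = "adenocarcinoma", organ = "lung"),
  C5105 = c(head = "adenocarcinoma", organ = "colon"),
  C4872 = c(head = "carcinoma", organ = "breast")
)

#' Construct a synthetic patient profile
#'
#' The structured ground truth behind a rendered patient note.
#'
#' @param id Patient identifier.
#' @param cancer_concept Concept code of the patient's cancer.
#' @param metastatic Logical.
#' @param ecog Integer 0-4.
#' @param ecog_rendering `"explicit"`, `"implicit_good"`, `"implicit_poor"`
#'   or `"absent"`; implicit_good requires `ecog <= 1`, implicit_poor
#'   `ecog >= 2`.
#' @param lesions List of `list(site_category, dims)` with dims in cm.
#' @param mutations Character vector of gene tokens.
#' @param therapy_mentions Gene tokens mentioned only as targeted therapies;
#'   must be disjoint from `mutations`.
#' @param confounders Subset of `"undefined_abbrev"`, `"negated_cancer"`,
#'   `"gene_synonym_swap"`, `"expression_variant"`, `"size_in_mm"`.
#' @return A `tm_patient_profile`.
#' @export
patient_profile <- function(id, cancer_concept, metastatic, ecog,
                            ecog_rendering = "explicit", lesions = list(),
                            mutations = character(0),
                            therapy_mentions = character(0),
                            confounders = character(0)) {
  ecog_rendering <- match.arg(ecog_rendering,
                              c("explicit", "implicit_good",
                                "implicit_poor", "absent"))
  if (!is.numeric(ecog) || ecog < 0 || ecog > 4) {
    stop_invalid("ecog must be in 0-4")
  }
  if (ecog_rendering == "implicit_good" && ecog > 1) {
    stop_invalid("implicit_good rendering requires ecog <= 1")
  }
  if (ecog_rendering == "implicit_poor" && ecog < 2) {
    stop_invalid("implicit_poor rendering requires ecog >= 2")
  }
  if (length(intersect(mutations, therapy_mentions)) > 0L) {
    stop_invalid("therapy_mentions must be disjoint from mutations")
  }
  if (!all(confounders %in% .confounder_names)) {
    stop_invalid("unknown confounder name")
  }
  structure(
    list(id = as.character(id), cancer_concept = cancer_concept,
         metastatic = isTRUE(metastatic), ecog = as.integer(ecog),
         ecog_rendering = ecog_rendering, lesions = lesions,
         mutations = mutations, therapy_mentions = therapy_mentions,
         confounders = confounders),
    class = "tm_patient_profile"
  )
}

#' Construct a synthetic protocol profile
#'
#' @param id Protocol identifier.
#' @param required_cancer Concept code or `NULL` (tumour-agnostic).
#' @param requires_metastatic Logical (only meaningful with a required
#'   cancer).
#' @param ecog_requirement A `tm_ecog_requirement` or `NULL`.
#' @param requires_measurable Logical.
#' @param required_mutations Character vector of gene tokens.
#' @param exclusion_items Character vector of exclusion bullet strings.
#' @return A `tm_protocol_profile`.
#' @export
protocol_profile <- function(id, required_cancer = NULL,
                             requires_metastatic = FALSE,
                             ecog_requirement = NULL,
                             requires_measurable = FALSE,
                             required_mutations = character(0),
                             exclusion_items = character(0)) {
  any_req <- !is.null(required_cancer) || !is.null(ecog_requirement) ||
    isTRUE(requires_measurable) || length(required_mutations) > 0L
  if (!any_req) stop_invalid("protocol profile must have >= 1 criterion")
  structure(
    list(id = as.character(id), required_cancer = required_cancer,
         requires_metastatic = isTRUE(requires_metastatic),
         ecog_requirement = ecog_requirement,
         requires_measurable = isTRUE(requires_measurable),
         required_mutations = required_mutations,
         exclusion_items = exclusion_items),
    class = "tm_protocol_profile"
  )
}

pick <- function(xs) xs[[sample.int(length(xs), 1L)]]

fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

join_and <- function(xs) {
  n <- length(xs)
  if (n == 1L) return(xs)
  if (n == 2L) return(paste(xs, collapse = " and "))
  paste0(paste(xs[-n], collapse = ", "), " and ", xs[n])
}

# Admissible ECOG levels of a requirement, from the profile alone.
.profile_ecog_admissible <- function(req) {
  switch(req$comparator,
         le = seq.int(0L, req$bound_high),
         ge = seq.int(req$bound_low, 4L),
         range = seq.int(req$bound_low, req$bound_high),
         eq = req$bound_low)
}

# Gene canonicalization used by gold labeling (true synonym resolution,
# independent of the matching module).
.profile_canon_genes <- function(tokens, synonyms) {
  toks <- sub(" mut$", "", tolower(tokens))
  hit <- synonyms[toks]
  ifelse(is.na(hit), toks, unname(hit))
}

# Per-requirement satisfaction checks from the structured profiles alone.
profile_checks <- function(patient, protocol, index, synonyms) {
  checks <- logical(0)
  if (!is.null(protocol$required_cancer)) {
    checks["cancer_type"] <-
      is_subtype(patient$cancer_concept, protocol$required_cancer, index) &&
      (!protocol$requires_metastatic || patient$metastatic)
  }
  if (!is.null(protocol$ecog_requirement)) {
    checks["ecog"] <- patient$ecog %in%
      .profile_ecog_admissible(protocol$ecog_requirement)
  }
  if (protocol$requires_measurable) {
    ok <- vapply(patient$lesions, function(l) {
      d <- max(l$dims)
      (l$site_category == "solid_organ" && d >= 1.0) ||
        (l$site_category == "lymph_node" && d >= 1.5)
    }, logical(1))
    checks["measurable"] <- length(ok) > 0L && any(ok)
  }
  if (length(protocol$required_mutations) > 0L) {
    checks["mutation"] <- length(intersect(
      .profile_canon_genes(patient$mutations, synonyms),
      .profile_canon_genes(protocol$required_mutations, synonyms)
    )) > 0L
  }
  checks
}

#' Gold label for a patient-protocol pair
#'
#' The expert ground truth the evaluation compares against: `match` iff
#' every requirement present in the protocol profile is satisfied by the
#' patient profile directly -- subtype via the ontology, metastatic
#' implication, ECOG membership in the admissible set, RECIST measurability
#' from the structured lesions, and mutation intersection with true synonym
#' resolution. The NLP pipeline is never invoked.
#'
#' @param patient A `tm_patient_profile`.
#' @param protocol A `tm_protocol_profile`.
#' @param index A `tm_ontology`.
#' @param synonyms Gene-synonym lookup (defaults to the bundled table).
#' @return `"match"` or `"no_match"`.
#' @export
gold_label <- function(patient, protocol, index = load_fixture_ontology(),
                       synonyms = load_gene_synonyms()) {
  checks <- profile_checks(patient, protocol, index, synonyms)
  if (all(checks)) "match" else "no_match"
}

.site_surfaces <- list(
  solid_organ = c("liver", "lung", "pancreas", "kidney"),
  lymph_node = c("axillary lymph node", "mediastinal lymph node",
                 "supraclavicular lymph node"),
  bone = c("L4 vertebra", "iliac bone", "rib")
)

render_lesion <- function(lesion, in_mm = FALSE) {
  site <- pick(.site_surfaces[[lesion$site_category]])
  dims <- lesion$dims
  if (length(dims) >= 2L && !in_mm) {
    size <- sprintf("(%s) cm", paste(fmt_num(dims), collapse = " x "))
    tmpl <- pick(c("Imaging demonstrates a %s mass in the %s.",
                   "CT shows a %s lesion in the %s."))
    sprintf(tmpl, size, site)
  } else {
    d <- max(dims)
    size <- if (in_mm) sprintf("%s mm", fmt_num(round(d * 10)))
            else sprintf("%s cm", fmt_num(d))
    if (lesion$site_category == "lymph_node") {
      sprintf(pick(c("A %s %s is noted.", "There is a %s %s.")), size, site)
    } else if (lesion$site_category == "bone") {
      sprintf(pick(c("A sclerotic lesion in the %2$s measures %1$s.",
                     "A %s sclerotic lesion is present in the %s.")),
              size, site)
    } else {
      sprintf(pick(c("A %s lesion is seen in the %s.",
                     "Follow-up imaging shows a %s nodule in the %s.")),
              size, site)
    }
  }
}

#' Render a synthetic patient note
#'
#' Deterministic for a given seed: assembles template sentences for history
#' (direct cancer name or an organ + histology phrasing), metastatic status,
#' lesions (RECIST-style size renderings), ECOG (explicit score or implicit
#' functional-status phrase), molecular results and prior targeted
#' therapies, then injects the profile's confounders. Gold annotations
#' record every planted surface with its character span.
#'
#' @param profile A `tm_patient_profile`.
#' @param seed Integer seed.
#' @param index A `tm_ontology` (names for concept codes).
#' @return List `text` and `annotations` (data.frame: `kind`, `value`,
#'   `surface`, `start`, `end`).
#' @export
render_patient <- function(profile, seed, index = load_fixture_ontology()) {
  stopifnot(inherits(profile, "tm_patient_profile"))
  with_seed(seed, {
    sent <- character(0)
    ann <- list()
    note_ann <- function(kind, value, surface) {
      ann[[length(ann) + 1L]] <<- list(kind = kind, value = value,
                                       surface = surface)
    }
    sent <- c(sent, sprintf("Clinical note for patient %s.", profile$id))

    name <- tolower(concept_name(profile$cancer_concept, index))
    combo <- .combo_renderings[[profile$cancer_concept]]
    use_combo <- !is.null(combo) && stats::runif(1) < 0.5
    year <- sample(2015:2023, 1L)
    if (use_combo) {
      sent <- c(sent, sprintf(
        "Oncologic history is notable for %s arising in the %s, first diagnosed in %d.",
        combo[["head"]], combo[["organ"]], year))
      note_ann("cancer", profile$cancer_concept,
               sprintf("%s arising in the %s", combo[["head"]],
                       combo[["organ"]]))
      if (profile$metastatic) {
        sent <- c(sent, "There is metastatic spread to distant sites.")
        note_ann("metastatic", TRUE, "metastatic")
      }
    } else {
      met_prefix <- if (profile$metastatic) "metastatic " else ""
      sent <- c(sent, sprintf("The patient was diagnosed with %s%s in %d.",
                              met_prefix, name, year))
      note_ann("cancer", profile$cancer_concept, name)
      if (profile$metastatic) note_ann("metastatic", TRUE, "metastatic")
    }
    if (!profile$metastatic) {
      sent <- c(sent, "Imaging shows disease confined to the primary site.")
    }

    mm_left <- "size_in_mm" %in% profile$confounders
    for (l in profile$lesions) {
      in_mm <- mm_left && length(l$dims) >= 1L
      if (in_mm) mm_left <- FALSE
      s <- render_lesion(l, in_mm = in_mm)
      sent <- c(sent, s)
      note_ann("lesion", sprintf("%s:%s", l$site_category,
                                 fmt_num(max(l$dims))), s)
    }

    if (profile$ecog_rendering == "explicit") {
      s <- sprintf(pick(c("ECOG performance status of %d.",
                          "Current ECOG PS is %d.")), profile$ecog)
      sent <- c(sent, s)
      note_ann("ecog", profile$ecog, s)
    } else if (profile$ecog_rendering == "implicit_good") {
      s <- pick(c("The patient remains active and is doing well.",
                  "The patient is in good health and fully active."))
      sent <- c(sent, s)
      note_ann("ecog", profile$ecog, s)
    } else if (profile$ecog_rendering == "implicit_poor") {
      s <- pick(c("The patient is wheelchair bound with limited activity.",
                  "The patient is largely bed bound and fatigued."))
      sent <- c(sent, s)
      note_ann("ecog", profile$ecog, s)
    }

    if (length(profile$mutations) > 0L) {
      shown <- profile$mutations
      if ("gene_synonym_swap" %in% profile$confounders) {
        swap <- .swap_map[shown]
        shown <- unname(ifelse(is.na(swap), shown, swap))
      }
      if ("expression_variant" %in% profile$confounders) {
        shown[1] <- paste(shown[1], "mut")
      }
      sent <- c(sent, sprintf(
        pick(c("Molecular profiling identified pathogenic alterations in %s.",
               "Genomic testing revealed alterations in %s.")),
        join_and(shown)))
      for (k in seq_along(shown)) {
        note_ann("mutation", profile$mutations[k], shown[k])
      }
    } else {
      sent <- c(sent, "Tumor genomic profiling revealed no actionable alterations.")
    }

    for (g in profile$therapy_mentions) {
      s <- sprintf(pick(c("The patient previously received anti-%s therapy.",
                          "%s-targeted therapy was administered previously.")),
                   g)
      sent <- c(sent, s)
      note_ann("therapy", g, s)
    }

    if ("negated_cancer" %in% profile$confounders) {
      others <- setdiff(.patient_cancer_pool, profile$cancer_concept)
      other <- pick(others)
      s <- sprintf("No evidence of %s.", tolower(concept_name(other, index)))
      sent <- c(sent, s)
      note_ann("negated_cancer", other, s)
    }
    if ("undefined_abbrev" %in% profile$confounders) {
      s <- "Laboratory review: AST and ALT 2.4 x ULN; albumin 3.1 g/dL."
      sent <- c(sent, s)
      note_ann("undefined_abbrev", "ALT", s)
    }

    text <- paste(sent, collapse = " ")
    ann_df <- if (length(ann)) {
      rows <- lapply(ann, function(a) {
        m <- regexpr(a$surface, text, fixed = TRUE)
        data.frame(kind = a$kind, value = as.character(a$value),
                   surface = a$surface,
                   start = if (m > 0) as.integer(m) - 1L else NA_integer_,
                   end = if (m > 0) {
                     as.integer(m) - 1L + attr(m, "match.length")
                   } else NA_integer_,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    } else {
      data.frame(kind = character(0), value = character(0),
                 surface = character(0), start = integer(0),
                 end = integer(0), stringsAsFactors = FALSE)
    }
    list(text = text, annotations = ann_df)
  })
}

render_ecog_req <- function(req) {
  if (req$comparator == "range") {
    sprintf(pick(c("ECOG performance status %d-%d.", "ECOG %d-%d.")),
            req$bound_low, req$bound_high)
  } else if (req$comparator == "le") {
    sprintf(pick(c("ECOG performance status \u2264 %d.", "ECOG <= %d.")),
            req$bound_high)
  } else if (req$comparator == "ge") {
    sprintf("ECOG \u2265 %d.", req$bound_low)
  } else {
    sprintf("ECOG performance status of %d.", req$bound_low)
  }
}

#' Render a synthetic protocol document
#'
#' Produces a protocol with "Inclusion Criteria:" / "Exclusion Criteria:"
#' headings, criteria in randomized template variants (bulleted or
#' numbered), and the profile's exclusion items.
#'
#' @param profile A `tm_protocol_profile`.
#' @param seed Integer seed.
#' @param index A `tm_ontology`.
#' @return List `text` and `gold_requirements` (the profile echoed back).
#' @export
render_protocol <- function(profile, seed,
                            index = load_fixture_ontology()) {
  stopifnot(inherits(profile, "tm_protocol_profile"))
  with_seed(seed, {
    numbered <- stats::runif(1) < 0.4
    bullet <- function(i) if (numbered) sprintf("%d. ", i) else "- "
    inc <- character(0)
    if (!is.null(profile$required_cancer)) {
      name <- tolower(concept_name(profile$required_cancer, index))
      met <- if (profile$requires_metastatic) "metastatic " else ""
      inc <- c(inc, sprintf(
        pick(c("Histologically confirmed %s%s.",
               "Patients must have %s%s.")), met, name))
    } else {
      inc <- c(inc, "Patients with advanced solid tumors are eligible.")
    }
    if (!is.null(profile$ecog_requirement)) {
      inc <- c(inc, render_ecog_req(profile$ecog_requirement))
    }
    if (profile$requires_measurable) {
      inc <- c(inc, pick(c("Measurable disease per RECIST 1.1.",
                           "Patients must have measurable disease.")))
    } else if (stats::runif(1) < 0.3) {
      inc <- c(inc, "Both measurable disease and non-measurable disease allowed.")
    }
    if (length(profile$required_mutations) > 0L) {
      genes <- paste(profile$required_mutations, collapse = ", ")
      inc <- c(inc, sprintf(
        pick(c("A known functional mutation in any of the following DDR genes: %s.",
               "Documented pathogenic alteration in %s.")), genes))
    }
    exc <- profile$exclusion_items
    if (length(exc) == 0L) exc <- "Uncontrolled intercurrent illness."

    lines <- c(
      sprintf("Protocol %s: a phase 1 open-label study of an investigational agent.",
              profile$id),
      "Inclusion Criteria:",
      paste0(vapply(seq_along(inc), bullet, ""), inc),
      "Exclusion Criteria:",
      paste0(vapply(seq_along(exc), bullet, ""), exc)
    )
    list(text = paste(lines, collapse = "\n"), gold_requirements = profile)
  })
}

sample_protocol_profile <- function(id) {
  required_cancer <- NULL
  requires_met <- FALSE
  if (stats::runif(1) < 0.6) {
    required_cancer <- pick(.protocol_cancer_pool)
    requires_met <- stats::runif(1) < 0.4
  }
  kind <- pick(c("le1", "le1", "range01", "range01", "le2", "range02"))
  req <- switch(kind,
                le1 = ecog_requirement("le", 0L, 1L),
                le2 = ecog_requirement("le", 0L, 2L),
                range01 = ecog_requirement("range", 0L, 1L),
                range02 = ecog_requirement("range", 0L, 2L))
  requires_measurable <- stats::runif(1) < 0.5
  required_mutations <- character(0)
  if (stats::runif(1) < 0.4) {
    required_mutations <- sample(.mutation_pool, sample(2:4, 1L))
  }
  exclusion_items <- character(0)
  if (stats::runif(1) < 0.7) {
    pool <- c(
      "Known active brain metastases.",
      sprintf("Prior %s-targeted therapy.", pick(.therapy_gene_pool)),
      "Uncontrolled intercurrent illness."
    )
    exclusion_items <- sample(pool, sample(1:2, 1L))
  }
  protocol_profile(id, required_cancer, requires_met, req,
                   requires_measurable, required_mutations, exclusion_items)
}

sample_lesions <- function(measurable) {
  lesions <- list()
  if (measurable) {
    ndim <- sample(1:3, 1L)
    dims <- round(stats::runif(ndim, 1.1, 3.5), 1)
    cat1 <- pick(c("solid_organ", "solid_organ", "lymph_node"))
    if (cat1 == "lymph_node") dims <- pmax(dims, 1.6)
    lesions <- c(lesions, list(list(site_category = cat1, dims = dims)))
  } else if (stats::runif(1) < 0.8) {
    cat1 <- pick(c("bone", "solid_organ", "lymph_node"))
    dims <- switch(cat1,
                   bone = round(stats::runif(1, 1.0, 4.0), 1),
                   solid_organ = round(stats::runif(1, 0.3, 0.9), 1),
                   lymph_node = round(stats::runif(1, 0.5, 1.4), 1))
    lesions <- c(lesions, list(list(site_category = cat1, dims = dims)))
  }
  if (stats::runif(1) < 0.3) {
    lesions <- c(lesions, list(list(
      site_category = "bone", dims = round(stats::runif(1, 1.0, 4.0), 1)
    )))
  }
  lesions
}

sample_patient_profile <- function(id, protocols, index) {
  anchor <- protocols[[sample.int(length(protocols), 1L)]]
  compatible <- stats::runif(1) < 0.55
  if (compatible) {
    cancer <- if (!is.null(anchor$required_cancer)) {
      opts <- intersect(descendants_of(anchor$required_cancer, index),
                        .patient_cancer_pool)
      if (length(opts) == 0L) anchor$required_cancer else pick(opts)
    } else {
      pick(.patient_cancer_pool)
    }
    metastatic <- anchor$requires_metastatic || stats::runif(1) < 0.5
    adm <- intersect(.profile_ecog_admissible(anchor$ecog_requirement), 0:2)
    ecog <- pick(adm)
    rendering <- if (ecog <= 1L && stats::runif(1) < 0.4) "implicit_good"
                 else "explicit"
    lesions <- sample_lesions(TRUE)
    mutations <- character(0)
    if (length(anchor$required_mutations) > 0L) {
      mutations <- unique(c(pick(anchor$required_mutations),
                            if (stats::runif(1) < 0.4)
                              pick(.extra_gene_pool)))
    } else if (stats::runif(1) < 0.5) {
      mutations <- sample(.extra_gene_pool, sample(1:2, 1L))
    }
  } else {
    cancer <- pick(.patient_cancer_pool)
    metastatic <- stats::runif(1) < 0.4
    ecog <- sample(0:4, 1L, prob = c(0.15, 0.2, 0.2, 0.25, 0.2))
    rendering <- if (ecog >= 3L && stats::runif(1) < 0.4) "implicit_poor"
                 else if (ecog <= 1L && stats::runif(1) < 0.3) "implicit_good"
                 else "explicit"
    lesions <- sample_lesions(stats::runif(1) < 0.5)
    mutations <- if (stats::runif(1) < 0.5) {
      sample(c(.mutation_pool, .extra_gene_pool), sample(1:2, 1L))
    } else character(0)
  }
  therapy <- if (stats::runif(1) < 0.3) {
    setdiff(pick(.therapy_gene_pool), mutations)
  } else character(0)
  patient_profile(id, cancer, metastatic, ecog, rendering, lesions,
                  mutations, therapy)
}

# A profile failing every requirement any pool protocol can pose: used as a
# guaranteed-consistent fallback when rejection sampling does not converge.
degraded_patient_profile <- function(id) {
  patient_profile(
    id, cancer_concept = "C3171", metastatic = FALSE, ecog = 4L,
    ecog_rendering = "explicit",
    lesions = list(list(site_category = "bone", dims = 2.0))
  )
}

# TRUE when some protocol's requirement checks land strictly between half
# and all satisfied: there the unanimity gold label and the threshold
# decision rule disagree by construction, so clean corpora avoid it.
profile_divergent <- function(patient, protocols, index, synonyms) {
  for (q in protocols) {
    checks <- profile_checks(patient, q, index, synonyms)
    if (length(checks) > 0L && any(!checks) && mean(checks) > 0.5) {
      return(TRUE)
    }
  }
  FALSE
}

#' Generate a synthetic evaluation corpus
#'
#' Samples protocol and patient profiles, renders them to text, computes
#' profile-level gold labels for all `n_patients * n_protocols` pairs, and
#' optionally writes the bundle to disk (patient/protocol text files, a
#' gold-label CSV, annotation JSON, and a batch manifest). Fully
#' reproducible from the seed.
#'
#' Patient profiles are rejection-sampled so that, absent confounders, no
#' pair satisfies more than half but fewer than all of a protocol's
#' requirements; on such clean corpora the threshold decision coincides with
#' the unanimity gold label on every pair, making confounders the only
#' source of system-vs-gold divergence.
#'
#' @param n_patients,n_protocols Corpus dimensions (defaults 12 and 6).
#' @param confounder_rates Named list/vector of per-patient injection
#'   probabilities for `"undefined_abbrev"`, `"negated_cancer"`,
#'   `"gene_synonym_swap"`, `"expression_variant"`, `"size_in_mm"`
#'   (missing names default to 0).
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param index A `tm_ontology`.
#' @return A `tm_corpus` bundle: `patients`/`protocols` (lists of
#'   `tm_document`), the profiles, `gold` (data.frame with `pair_id` and
#'   `label`), `annotations`, and `paths` when written.
#' @export
generate_corpus <- function(n_patients = 12L, n_protocols = 6L,
                            confounder_rates = list(), seed = 1L,
                            out_dir = NULL,
                            index = load_fixture_ontology()) {
  stopifnot(n_patients >= 1L, n_protocols >= 1L)
  synonyms <- load_gene_synonyms()

  prot_profiles <- with_seed(derive_seed(seed, 1L), {
    lapply(seq_len(n_protocols), function(j) {
      sample_protocol_profile(as.character(j))
    })
  })

  pat_profiles <- with_seed(derive_seed(seed, 2L), {
    lapply(seq_len(n_patients), function(i) {
      for (attempt in seq_len(80L)) {
        cand <- sample_patient_profile(as.character(i), prot_profiles, index)
        if (!profile_divergent(cand, prot_profiles, index, synonyms)) {
          return(cand)
        }
      }
      degraded_patient_profile(as.character(i))
    })
  })

  # Confounder assignment draws from its own stream so that changing a rate
  # never perturbs the base profiles.
  rates <- stats::setNames(rep(0, length(.confounder_names)),
                           .confounder_names)
  for (nm in names(confounder_rates)) {
    if (!nm %in% .confounder_names) stop_invalid("unknown confounder: ", nm)
    rates[nm] <- as.numeric(confounder_rates[[nm]])
  }
  pat_profiles <- with_seed(derive_seed(seed, 3L), {
    lapply(pat_profiles, function(p) {
      conf <- .confounder_names[stats::runif(length(.confounder_names)) <
                                  rates]
      if (length(conf) == 0L) return(p)
      mutations <- p$mutations
      if ("gene_synonym_swap" %in% conf &&
          !any(names(.swap_map) %in% mutations)) {
        mutations <- c(mutations, "CHK2")
      }
      if ("expression_variant" %in% conf && length(mutations) == 0L) {
        mutations <- "BRCA1"
      }
      patient_profile(p$id, p$cancer_concept, p$metastatic, p$ecog,
                      p$ecog_rendering, p$lesions, mutations,
                      setdiff(p$therapy_mentions, mutations), conf)
    })
  })

  rendered_p <- lapply(seq_along(pat_profiles), function(i) {
    render_patient(pat_profiles[[i]], derive_seed(seed, 1000L + i), index)
  })
  rendered_q <- lapply(seq_along(prot_profiles), function(j) {
    render_protocol(prot_profiles[[j]], derive_seed(seed, 2000L + j), index)
  })
  patients <- lapply(seq_along(rendered_p), function(i) {
    parse_document(rendered_p[[i]]$text, "patient",
                   id = pat_profiles[[i]]$id)
  })
  protocols <- lapply(seq_along(rendered_q), function(j) {
    parse_document(rendered_q[[j]]$text, "protocol",
                   id = prot_profiles[[j]]$id)
  })

  gold <- do.call(rbind, lapply(pat_profiles, function(p) {
    do.call(rbind, lapply(prot_profiles, function(q) {
      data.frame(
        patient_id = p$id, protocol_id = q$id,
        pair_id = paste0("patient", p$id, "_protocol", q$id),
        label = gold_label(p, q, index, synonyms), stringsAsFactors = FALSE
      )
    }))
  }))

  annotations <- stats::setNames(lapply(rendered_p, `[[`, "annotations"),
                                 vapply(pat_profiles, `[[`, "", "id"))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list()
    for (i in seq_along(patients)) {
      f <- file.path(out_dir, sprintf("patient_%s.txt", patients[[i]]$id))
      writeLines(patients[[i]]$raw_text, f)
      manifest[[length(manifest) + 1L]] <-
        list(id = patients[[i]]$id, kind = "patient", path = basename(f))
    }
    for (j in seq_along(protocols)) {
      f <- file.path(out_dir, sprintf("protocol_%s.txt", protocols[[j]]$id))
      writeLines(protocols[[j]]$raw_text, f)
      manifest[[length(manifest) + 1L]] <-
        list(id = protocols[[j]]$id, kind = "protocol", path = basename(f))
    }
    utils::write.csv(gold[, c("patient_id", "protocol_id", "label")],
                     file.path(out_dir, "gold.csv"), row.names = FALSE)
    jsonlite::write_json(annotations,
                         file.path(out_dir, "annotations.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    paths <- out_dir
  }

  structure(
    list(patients = patients, protocols = protocols,
         patient_profiles = pat_profiles, protocol_profiles = prot_profiles,
         gold = gold, annotations = annotations, paths = paths),
    class = "tm_corpus"
  )
}
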