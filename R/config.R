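#' Default pipeline configuration
#'
#' Every lexicon, trigger list, threshold and template the pipeline relies on
#' is collected in one auditable configuration list. Any element can be
#' overridden through [load_config()] or by editing the returned list.
#'
#' Key elements:
#' \describe{
#'   \item{threshold}{Decision threshold on the matching score; a pair is
#'     declared a match only when `score > threshold` (strict). Default 0.5.}
#'   \item{negation_triggers}{Lowercase phrases that negate every tagged
#'     mention in their sentence (sentence-scope negation).}
#'   \item{good_health, poor_health}{Phrase lexicons for implicit ECOG
#'     performance status; good maps to the interval 0-1, poor to 2-4.}
#'   \item{site_map}{Anatomic-site surface strings normalized to
#'     `solid_organ`, `lymph_node` or `bone` for RECIST measurability.}
#'   \item{measurable_cm}{Minimum longest dimension in cm for a measurable
#'     lesion, per site category (solid organ 1.0, lymph node 1.5; bone is
#'     never measurable).}
#'   \item{size_comparator}{`">="` (default, RECIST 1.1 "or above") or `">"`
#'     for the strict reading of the size rule.}
#'   \item{generic_blocklist}{Concept codes too generic to identify a cancer
#'     type (e.g. "Malignant Neoplasm", "Solid Neoplasm").}
#'   \item{synonyms_enabled}{Whether gene tokens are canonicalized through the
#'     gene-synonym table before intersection. Default `FALSE`.}
#'   \item{indeterminate_as_no_match}{Evaluation switch: coerce indeterminate
#'     decisions (no requirement detected) to `no_match` instead of excluding
#'     them. Default `FALSE`.}
#' }
#'
#' @return A named list of configuration values.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$threshold
default_config <- function() {
  list(
    threshold = 0.5,
    criteria_enabled = c("cancer_type", "ecog", "measurable", "mutation"),
    negation_triggers = c(
      "not including", "except for", "no evidence of", "without",
      "denies", "negative for", "free of", "are excluded", "must not have"
    ),
    good_health = c(
      "active", "doing well", "in good health", "fully active",
      "asymptomatic", "no complaints"
    ),
    poor_health = c(
      "fatigued", "wheelchair bound", "limited activity", "bed bound",
      "bedridden", "confined to bed", "severely debilitated"
    ),
    therapy_pre_cues = c("anti"),
    therapy_post_cues = c("targeted"),
    site_map = c(
      liver = "solid_organ", lung = "solid_organ", pancreas = "solid_organ",
      kidney = "solid_organ", spleen = "solid_organ", brain = "solid_organ",
      breast = "solid_organ", prostate = "solid_organ", ovary = "solid_organ",
      "adrenal gland" = "solid_organ",
      "lymph node" = "lymph_node", "lymph nodes" = "lymph_node",
      "axillary lymph node" = "lymph_node",
      "mediastinal lymph node" = "lymph_node",
      "supraclavicular lymph node" = "lymph_node",
      "cervical lymph node" = "lymph_node",
      bone = "bone", vertebra = "bone", "l4 vertebra" = "bone",
      "t8 vertebra" = "bone", "iliac bone" = "bone", rib = "bone",
      femur = "bone", sternum = "bone"
    ),
    measurable_cm = c(solid_organ = 1.0, lymph_node = 1.5),
    size_comparator = ">=",
    # Codes of the fixture thesaurus concepts too generic to be informative.
    generic_blocklist = c("C3262", "C9305", "C9292", "C14174", "C3677"),
    synonyms_enabled = FALSE,
    indeterminate_as_no_match = FALSE,
    rectify_window = 40L
  )
}

#' Load a configuration file
#'
#' Reads a YAML or JSON configuration file and merges it over
#' [default_config()]: keys present in the file replace the defaults, all
#' other defaults are kept.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A full configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- default_config()
  for (k in names(user)) {
    v <- user[[k]]
    # site_map round-trips as a named list in YAML/JSON; restore it.
    if (k == "site_map" && is.list(v)) v <- unlist(v)
    cfg[[k]] <- v
  }
  stopifnot(cfg$threshold >= 0, cfg$threshold < 1)
  cfg
}
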