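#' Define a pseudoword study design
#'
#' A study design fixes the experimental conditions, the transcribed response
#' categories that the mixture model treats as outcomes, and the three
#' correspondence (rule) types whose weights are estimated. Two layouts are
#' supported: `english_style`, where a vowel grapheme has several plausible
#' vowel pronunciations and consonant errors / non-responses are excluded
#' while "other vowel" responses count as valid transcriptions; and
#' `german_style`, where the outcome is binary (short vs long vowel) and any
#' consonant or vowel error is excluded.
#'
#' @param language_mode `"english_style"` or `"german_style"`.
#' @param conditions Character vector of exactly 4 condition labels.
#' @param response_categories Character vector of modelled response category
#'   labels (exactly 2 for `german_style`).
#' @param rule_types Character vector of exactly 3 rule-type labels, in the
#'   order used for weight vectors (conventionally simple GPC first).
#' @param items_per_condition Named integer vector (names = conditions) giving
#'   the number of experimental items in each condition.
#' @param other_categories Valid but unmodelled response labels
#'   (e.g. `"other_vowel"`); empty for `german_style`.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(language_mode,
                         conditions,
                         response_categories,
                         rule_types,
                         items_per_condition,
                         other_categories = character()) {
  language_mode <- match.arg(language_mode, c("english_style", "german_style"))
  conditions <- as.character(conditions)
  response_categories <- as.character(response_categories)
  rule_types <- as.character(rule_types)
  if (length(conditions) != 4L) {
    stop("a study design must have exactly 4 conditions, got ",
         length(conditions), call. = FALSE)
  }
  if (length(rule_types) != 3L) {
    stop("a study design must have exactly 3 rule types, got ",
         length(rule_types), call. = FALSE)
  }
  if (language_mode == "german_style" && length(response_categories) != 2L) {
    stop("german_style designs model exactly 2 response categories",
         call. = FALSE)
  }
  if (anyDuplicated(conditions) || anyDuplicated(response_categories) ||
      anyDuplicated(rule_types)) {
    stop("conditions, response categories and rule types must be unique",
         call. = FALSE)
  }
  items_per_condition <- as.integer(items_per_condition[conditions])
  names(items_per_condition) <- conditions
  if (anyNA(items_per_condition) || any(items_per_condition < 1L)) {
    stop("items_per_condition must give a positive count for every condition",
         call. = FALSE)
  }
  structure(
    list(
      language_mode = language_mode,
      conditions = conditions,
      response_categories = response_categories,
      rule_types = rule_types,
      items_per_condition = items_per_condition,
      other_categories = as.character(other_categories)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", x$language_mode, "\n",
      "  conditions: ", paste(x$conditions, collapse = ", "), "\n",
      "  modelled categories: ", paste(x$response_categories, collapse = ", "),
      "\n  rule types: ", paste(x$rule_types, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# all labels a response_category column may contain for this design
valid_categories <- function(design) {
  unique(c(design$response_categories, design$other_categories))
}

#' Read a study design from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file with fields
#'   `language_mode`, `conditions`, `response_categories`, `rule_types`,
#'   `items_per_condition` and optionally `other_categories`.
#' @return A [study_design()] object.
#' @export
read_design <- function(path) {
  lst <- read_structured(path)
  study_design(
    language_mode = lst$language_mode,
    conditions = unlist(lst$conditions),
    response_categories = unlist(lst$response_categories),
    rule_types = unlist(lst$rule_types),
    items_per_condition = unlist(lst$items_per_condition),
    other_categories = as.character(unlist(lst$other_categories))
  )
}

# YAML/JSON loader dispatched on extension
read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension '", ext, "' (use yaml or json)",
         call. = FALSE)
  )
}

#' Preset English and German designs with fixture probability tables
#'
#' Returns the two 4-condition designs used throughout the examples and the
#' simulator, each paired with a corpus-probability table. The probability
#' values are synthetic fixtures chosen to be linguistically plausible (they
#' are not corpus-derived statistics): a simple GPC that prefers the default
#' vowel everywhere, an onset-context rule that switches the vowel in
#' w-onset conditions, and a body-context rule that switches it when the
#' critical body is present.
#'
#' The English design has conditions `hact` (onset and body both agree with
#' the simple GPC), `wact` (onset disagrees), `kalt` (body disagrees) and
#' `wald` (both disagree), with modelled vowel categories `ae`, `open_o`,
#' `long_o` and an unmodelled `other_vowel` label. The German design has
#' conditions `bamt`, `git`, `blagd`, `blaf` crossing the vowel-length
#' super-rule with body congruency, and binary categories `short`/`long`.
#'
#' @return A list with elements `english` and `german`, each a list of
#'   `design` (a [study_design()]) and `probs` (a [corpus_probs()] table).
#' @export
preset_designs <- function() {
  english_design <- study_design(
    language_mode = "english_style",
    conditions = c("hact", "wact", "kalt", "wald"),
    response_categories = c("ae", "open_o", "long_o"),
    rule_types = c("simpleGPC", "CS_O", "CS_B"),
    items_per_condition = c(hact = 18L, wact = 18L, kalt = 18L, wald = 18L),
    other_categories = "other_vowel"
  )
  german_design <- study_design(
    language_mode = "german_style",
    conditions = c("bamt", "git", "blagd", "blaf"),
    response_categories = c("short", "long"),
    rule_types = c("simpleGPC", "SR", "CS_B"),
    items_per_condition = c(bamt = 16L, git = 16L, blagd = 16L, blaf = 16L)
  )
  list(
    english = list(design = english_design,
                   probs = english_fixture_probs(english_design)),
    german = list(design = german_design,
                  probs = german_fixture_probs(german_design))
  )
}

# synthetic fixture table: simple GPC favours /ae/ everywhere; the onset rule
# switches to /open_o/ in w-onset conditions; the body rule switches to
# /long_o/ in alC-body conditions. Residual mass (rows sum < 1) is the
# probability of some other transcribed vowel.
english_fixture_probs <- function(design) {
  simple <- c(ae = 0.88, open_o = 0.04, long_o = 0.04)
  onset_switch <- c(ae = 0.12, open_o = 0.80, long_o = 0.04)
  body_switch <- c(ae = 0.15, open_o = 0.06, long_o = 0.75)
  rows <- list(
    hact = list(simpleGPC = simple, CS_O = simple, CS_B = simple),
    wact = list(simpleGPC = simple, CS_O = onset_switch, CS_B = simple),
    kalt = list(simpleGPC = simple, CS_O = simple, CS_B = body_switch),
    wald = list(simpleGPC = simple, CS_O = onset_switch, CS_B = body_switch)
  )
  corpus_probs_from_nested(rows, design)
}

# binary fixture: short is the default; the super-rule signals long when the
# body has a single consonant; the body rule follows the specific body.
german_fixture_probs <- function(design) {
  p <- function(short) c(short = short, long = 1 - short)
  rows <- list(
    bamt = list(simpleGPC = p(0.85), SR = p(0.90), CS_B = p(0.90)),
    git = list(simpleGPC = p(0.85), SR = p(0.15), CS_B = p(0.95)),
    blagd = list(simpleGPC = p(0.85), SR = p(0.90), CS_B = p(0.05)),
    blaf = list(simpleGPC = p(0.85), SR = p(0.15), CS_B = p(0.20))
  )
  corpus_probs_from_nested(rows, design)
}
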