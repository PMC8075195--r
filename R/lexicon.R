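#' Schedule-extraction lexicon
#'
#' Configurable term sets driving the schedule filter and classifier. The
#' defaults are a documented reconstruction: `schedule_keywords` anchor the
#' syntactic patterns; a keyword only matches when its vaccination context is
#' established (a `context_terms` member inside the keyword's noun phrase or
#' shortly after it, or a `context_verbs` member governing the clause), which
#' screens out decoy uses like "my work schedule". `alternative_markers` and
#' `recommended_markers` are the polarity cues consumed by
#' [classify_schedule()]; they must be disjoint. All terms are lower-case
#' lemmas; hyphenated entries (`spread-out`, `one-at-a-time`, `on-time`)
#' correspond to multiword expressions merged during normalization.
#'
#' @param schedule_keywords terms whose noun-phrase context is pattern-matched.
#' @param alternative_markers cues flipping the default label to alternative.
#' @param recommended_markers cues confirming the recommended default.
#' @param negation_cues negation tokens considered for scope attachment.
#' @param context_terms vaccination-context nouns that disambiguate keywords.
#' @param context_verbs vaccination verbs that establish context when they
#'   govern the clause.
#' @param context_constraints optional named list mapping a keyword to its own
#'   context-term vector, overriding `context_terms` for that keyword.
#' @return An object of class `schedule_lexicon`.
#' @export
schedule_lexicon <- function(
    schedule_keywords = c("schedule", "spacing"),
    alternative_markers = c("delayed", "selective", "alternative", "modified",
                            "spread-out", "one-at-a-time", "spacing", "spaced"),
    recommended_markers = c("regular", "recommended", "normal", "standard",
                            "on-time", "cdc", "full"),
    negation_cues = c("not", "never", "no", "without"),
    context_terms = c("vaccine", "vaccination", "vax", "shot", "immunization",
                      "jab", "mmr", "dtap", "booster", "cdc"),
    context_verbs = c("vaccinate", "immunize"),
    context_constraints = NULL) {
  overlap <- intersect(alternative_markers, recommended_markers)
  if (length(overlap) > 0) {
    stop("alternative and recommended marker sets must be disjoint; shared: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(
    schedule_keywords = tolower(schedule_keywords),
    alternative_markers = tolower(alternative_markers),
    recommended_markers = tolower(recommended_markers),
    negation_cues = tolower(negation_cues),
    context_terms = tolower(context_terms),
    context_verbs = tolower(context_verbs),
    context_constraints = context_constraints
  ), class = "schedule_lexicon")
}

#' @rdname schedule_lexicon
#' @export
default_schedule_lexicon <- function() schedule_lexicon()

#' Read a schedule lexicon from a YAML file
#'
#' The file may define any subset of the [schedule_lexicon()] arguments;
#' unspecified sets keep their defaults.
#'
#' @param path YAML file.
#' @return A `schedule_lexicon`.
#' @export
read_lexicon <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(schedule_lexicon))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown lexicon field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(schedule_lexicon, cfg)
}

#' AEFI reaction vocabulary
#'
#' Maps each canonical reaction to its synonym set (matched against tokens and
#' lemmas). Synonym sets must be disjoint across canonical reactions. The
#' generic entry `reaction` lets the pipeline catch explicit "no reaction"
#' statements that name no specific symptom.
#'
#' @param terms named list: canonical reaction -> character vector of synonyms.
#' @return An object of class `reaction_vocabulary`.
#' @export
reaction_vocabulary <- function(terms = list(
    fever = c("fever"),
    seizure = c("seizure", "convulsion"),
    regression = c("regression"),
    pain = c("pain", "soreness", "sore", "ache"),
    fussiness = c("fussiness", "fussy"),
    rash = c("rash", "hive"),
    swelling = c("swelling", "swollen"),
    lethargy = c("lethargy", "lethargic", "drowsiness", "drowsy"),
    vomiting = c("vomiting", "vomit"),
    reaction = c("reaction", "side-effect"))) {
  terms <- lapply(terms, tolower)
  all_terms <- unlist(terms, use.names = FALSE)
  if (anyDuplicated(all_terms)) {
    stop("reaction synonym sets must be disjoint; shared: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(terms = terms), class = "reaction_vocabulary")
}

#' @rdname reaction_vocabulary
#' @export
default_reaction_vocabulary <- function() reaction_vocabulary()

#' Kinship term table for experiencer resolution
#'
#' Splits possessed kinship heads into the author's own child vs. other
#' relations/acquaintances; used by [resolve_subject()].
#'
#' @param child_terms head nouns treated as the author's child under a
#'   first-person possessive.
#' @param acquaintance_terms head nouns treated as second-hand subjects.
#' @return A named list with the two term vectors.
#' @export
kinship_table <- function(
    child_terms = c("son", "daughter", "baby", "kid", "child", "toddler",
                    "twin", "infant", "newborn", "girl", "boy"),
    acquaintance_terms = c("nephew", "niece", "friend", "cousin", "sister",
                           "brother", "neighbor", "coworker", "mom", "dad",
                           "grandson", "granddaughter", "husband", "wife")) {
  list(child_terms = tolower(child_terms),
       acquaintance_terms = tolower(acquaintance_terms))
}
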