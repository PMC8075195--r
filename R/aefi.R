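#' Filter a comment for AEFI experience mentions
#'
#' Reuses the schedule-extraction machinery with a reaction vocabulary: a
#' sentence matches when it names a reaction term in an immunization context
#' (any vaccination-context lemma in the sentence). Who experienced the
#' reaction is resolved from the subject noun phrase, and negated attributions
#' ("no reaction", "didn't have any fever") are recorded rather than dropped,
#' so that explicit reports of uneventful vaccination count as positive
#' experiences downstream.
#'
#' @param comment a one-row data frame (or list) with `comment_id` and `text`.
#' @param vocabulary a [reaction_vocabulary()].
#' @param context_terms vaccination-context lemmas required in the sentence.
#' @param kinship a [kinship_table()] for subject resolution.
#' @return A tibble of matches: `comment_id`, `sentence_index`,
#'   `reaction_terms` (list-column of canonical reactions), `subject` (one of
#'   author/child/acquaintance/unknown), `attribution_negated`. Zero rows
#'   means the comment does not mention an AEFI experience.
#' @export
filter_aefi <- function(comment, vocabulary = default_reaction_vocabulary(),
                        context_terms = c("vaccine", "vaccination", "vax",
                                          "shot", "immunization", "jab",
                                          "mmr", "dtap", "booster",
                                          "vaccinate", "immunize"),
                        kinship = kinship_table()) {
  text <- if (is.list(comment) && !is.null(comment$text)) comment$text[1] else
    as.character(comment)[1]
  cid <- if (is.list(comment) && !is.null(comment$comment_id))
    comment$comment_id[1] else NA_character_
  synonyms <- unlist(vocabulary$terms, use.names = FALSE)
  canonical <- rep(names(vocabulary$terms),
                   vapply(vocabulary$terms, length, integer(1)))
  summaries <- summarize_sentences(text, keywords = synonyms)
  rows <- list()
  for (si in seq_along(summaries)) {
    s <- summaries[[si]]
    if (length(s$keyword_hits) == 0) next
    if (!any(s$lemmas %in% context_terms)) next  # no immunization context
    hit_idx <- vapply(s$keyword_hits, function(h) h$index, integer(1))
    reactions <- unique(canonical[match(
      vapply(s$keyword_hits, function(h) h$keyword, character(1)), synonyms)])
    negated <- vapply(s$keyword_hits, function(h) {
      h$det_no || negation_attached(s, h$index, max_np_distance = 4L)
    }, logical(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      comment_id = cid, sentence_index = si,
      reaction_terms = list(reactions),
      subject = resolve_subject(s, kinship = kinship),
      attribution_negated = all(negated)
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(comment_id = character(), sentence_index = integer(),
                          reaction_terms = list(), subject = character(),
                          attribution_negated = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Classify an AEFI experience from its matches
#'
#' A comment is a `negative_experience` when any match asserts a non-negated
#' reaction attribution; it is a `positive_experience` when every attribution
#' is negated (the author explicitly reports no adverse reaction). The rule is
#' monotone: adding a non-negated match can only move the label toward
#' negative, never away from it.
#'
#' @param matches a match tibble from [filter_aefi()].
#' @return `"negative_experience"`, `"positive_experience"`, or `NULL` when
#'   `matches` is empty.
#' @export
classify_experience <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0) return(NULL)
  if (any(!matches$attribution_negated)) "negative_experience"
  else "positive_experience"
}

#' Resolve the experiencing subject of an AEFI sentence
#'
#' First-person singular subjects resolve to `author`; a first-person
#' possessive over a child kinship head ("my son", "our baby") to `child`; a
#' possessive chain ("my friend's kid") or another kinship/social head ("my
#' nephew") to `acquaintance`; anything else to `unknown`.
#'
#' @param summary a `sentence_summary` from [summarize_sentences()].
#' @param match unused placeholder for API symmetry with the match object the
#'   summary was derived from; may be omitted.
#' @param kinship a [kinship_table()].
#' @return One of `"author"`, `"child"`, `"acquaintance"`, `"unknown"`.
#' @export
resolve_subject <- function(summary, match = NULL, kinship = kinship_table()) {
  span <- summary$subject_span
  if (is.null(span)) return("unknown")
  toks <- summary$tokens[span[1]:span[2]]
  lems <- summary$lemmas[span[1]:span[2]]
  if (any(toks == "i")) return("author")
  if (toks[1] %in% c("my", "our")) {
    if (any(grepl("'s$", toks))) return("acquaintance")
    headl <- lems[length(lems)]
    if (headl %in% kinship$child_terms) return("child")
    if (headl %in% kinship$acquaintance_terms) return("acquaintance")
    return("unknown")
  }
  if (any(toks == "we")) return("author")
  "unknown"
}

#' Run the AEFI extraction pipeline over a corpus
#'
#' Deterministic; operates on comments only. Comments with multiple reaction
#' mentions record all canonical reaction terms.
#'
#' @param corpus a [forum_corpus()].
#' @param vocabulary a [reaction_vocabulary()].
#' @param ... passed to [filter_aefi()].
#' @return A tibble with one row per AEFI-related comment: `comment_id`,
#'   `user_id`, `label` (negative/positive experience), `subject` (of the
#'   first match), `reactions` (list-column of canonical terms).
#' @export
run_aefi_pipeline <- function(corpus, vocabulary = default_reaction_vocabulary(),
                              ...) {
  cm <- corpus$comments
  out <- vector("list", nrow(cm))
  for (i in seq_len(nrow(cm))) {
    matches <- filter_aefi(list(comment_id = cm$comment_id[i],
                                text = cm$text[i]), vocabulary, ...)
    if (nrow(matches) == 0) next
    out[[i]] <- tibble::tibble(
      comment_id = cm$comment_id[i],
      user_id = cm$user_id[i],
      label = classify_experience(matches),
      subject = matches$subject[1],
      reactions = list(sort(unique(unlist(matches$reaction_terms))))
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble::tibble(comment_id = character(), user_id = character(),
                          label = character(), subject = character(),
                          reactions = list()))
  }
  dplyr::bind_rows(out)
}
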