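#' Filter a comment for vaccination-schedule statements
#'
#' Scans every sentence of a comment for schedule keywords occurring inside a
#' documented syntactic pattern with the vaccination context established.
#' Three patterns are matched, in order of specificity:
#' \describe{
#'   \item{`np_context`}{a context term sits inside the keyword's noun phrase
#'     (e.g. "the regular \emph{vaccination} schedule");}
#'   \item{`verb_context`}{a vaccination verb governs the clause (e.g. "we
#'     \emph{vaccinate} on the regular schedule");}
#'   \item{`pp_context`}{a context term follows the keyword within a short
#'     window, covering prepositional attachments and objects (e.g. "schedule
#'     of \emph{vaccinations}", "spacing out her \emph{shots}").}
#' }
#' Keywords without any established context (e.g. "my work schedule") yield no
#' match. A negation cue flips a match only when it attaches to a clause verb
#' in the same comma-delimited segment as the keyword (or is the keyword's own
#' "no" determiner); clause-external negations do not count.
#'
#' @param comment a one-row data frame (or list) with `comment_id` and `text`.
#' @param lexicon a [schedule_lexicon()].
#' @return A tibble of matches: `comment_id`, `sentence_index`, `keyword`,
#'   `pattern_id`, `alt_cues` / `rec_cues` (list-columns of matched polarity
#'   markers), `negated`. Zero rows means the comment is not schedule-related.
#' @export
filter_schedule <- function(comment, lexicon = default_schedule_lexicon()) {
  text <- if (is.list(comment) && !is.null(comment$text)) comment$text[1] else
    as.character(comment)[1]
  cid <- if (is.list(comment) && !is.null(comment$comment_id))
    comment$comment_id[1] else NA_character_
  summaries <- summarize_sentences(text, keywords = lexicon$schedule_keywords)
  rows <- list()
  for (si in seq_along(summaries)) {
    s <- summaries[[si]]
    for (h in s$keyword_hits) {
      ctx <- lexicon$context_constraints[[h$keyword]]
      if (is.null(ctx)) ctx <- lexicon$context_terms
      np_terms <- c(h$modifiers, h$compounds)
      pattern <- NULL
      if (any(np_terms %in% ctx)) {
        pattern <- "np_context"
      } else if (!is.na(s$main_verb_index) &&
                 s$lemmas[s$main_verb_index] %in% lexicon$context_verbs) {
        pattern <- "verb_context"
      } else {
        win <- seq.int(h$index + 1L, min(h$index + 5L, length(s$tokens)))
        win <- win[win > h$index]
        if (length(win) > 0 && any(s$lemmas[win] %in% ctx)) {
          pattern <- "pp_context"
        }
      }
      if (is.null(pattern)) next
      cue_pool <- unique(c(np_terms, h$keyword))
      alt <- intersect(cue_pool, lexicon$alternative_markers)
      rec <- intersect(cue_pool, lexicon$recommended_markers)
      negated <- h$det_no || negation_attached(s, h$index)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        comment_id = cid, sentence_index = si, keyword = h$keyword,
        pattern_id = pattern, alt_cues = list(alt), rec_cues = list(rec),
        negated = negated
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(comment_id = character(), sentence_index = integer(),
                          keyword = character(), pattern_id = character(),
                          alt_cues = list(), rec_cues = list(),
                          negated = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Classify a comment from its schedule matches
#'
#' Implements the default/flip rule: a match is `recommended` by default;
#' an alternative-marker cue makes it `alternative`; an attached negation
#' flips whatever the cues say, so a negated recommended-marker match becomes
#' `alternative` and a negated alternative-marker match (double flip) returns
#' to `recommended`. A comment with conflicting per-match labels resolves
#' alternative-over-recommended, since alternative cues are the specific
#' signal while recommended is only the default. The function is a pure,
#' permutation-invariant function of the match set.
#'
#' @param matches a match tibble from [filter_schedule()].
#' @return `"recommended"`, `"alternative"`, or `NULL` when `matches` is empty.
#' @export
classify_schedule <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0) return(NULL)
  per_match <- vapply(seq_len(nrow(matches)), function(i) {
    label <- if (length(matches$alt_cues[[i]]) > 0) "alternative" else "recommended"
    if (matches$negated[i]) {
      label <- if (label == "alternative") "recommended" else "alternative"
    }
    label
  }, character(1))
  if (any(per_match == "alternative")) "alternative" else "recommended"
}

#' Run the schedule filter + classifier over a corpus
#'
#' Operates on comments only (post bodies are ignored: they tend to be phrased
#' as questions rather than statements of behaviour). Deterministic: the same
#' corpus always yields the same labels.
#'
#' @param corpus a [forum_corpus()].
#' @param lexicon a [schedule_lexicon()].
#' @return A tibble with one row per schedule-related comment: `comment_id`,
#'   `user_id`, `label`, `pattern_id` and `keyword` of the first match.
#' @export
run_schedule_pipeline <- function(corpus, lexicon = default_schedule_lexicon()) {
  cm <- corpus$comments
  out <- vector("list", nrow(cm))
  for (i in seq_len(nrow(cm))) {
    matches <- filter_schedule(list(comment_id = cm$comment_id[i],
                                    text = cm$text[i]), lexicon)
    if (nrow(matches) == 0) next
    out[[i]] <- tibble::tibble(
      comment_id = cm$comment_id[i],
      user_id = cm$user_id[i],
      label = classify_schedule(matches),
      pattern_id = matches$pattern_id[1],
      keyword = matches$keyword[1]
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble::tibble(comment_id = character(), user_id = character(),
                          label = character(), pattern_id = character(),
                          keyword = character()))
  }
  dplyr::bind_rows(out)
}
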