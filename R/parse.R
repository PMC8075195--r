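# Deterministic shallow sentence annotation.
#
# The extraction pipelines need, per sentence: tokens, lemmas, the main verb,
# the subject noun phrase, negation cue positions, and for each keyword the
# adjectival and compound modifiers inside its noun phrase. A full dependency
# parse is unnecessary for this closed pattern family; a rule-based annotator
# keeps the pipeline deterministic and dependency-free. Head indices and
# relation labels are approximations sufficient for the patterns matched here.

.det_words <- c("the", "a", "an", "my", "our", "his", "her", "their", "this",
                "that", "your", "its", "any", "some", "every", "each")
.prep_words <- c("on", "in", "at", "of", "for", "with", "to", "after",
                 "before", "about", "from", "under", "over", "by", "between",
                 "during", "through")
.conj_words <- c("and", "or", "but", "so", "because", "while", "when", "if",
                 "though", "although")
.negation_words <- c("not", "never", "no", "without", "nothing")
.adverb_words <- c("always", "still", "just", "usually", "often", "really",
                   "finally", "already", "only", "also", "again", "lately",
                   "recently", "probably", "definitely")

# surface adjectives recognised inside noun phrases (markers + common)
.adjective_words <- c("delayed", "selective", "alternative", "modified",
                      "spread-out", "one-at-a-time", "spaced", "regular",
                      "recommended", "normal", "standard", "on-time", "full",
                      "new", "crazy", "strict", "busy", "usual", "high", "low",
                      "low-grade", "mild", "serious", "little", "big", "bad")

.lemma_table <- c(
  am = "be", is = "be", are = "be", was = "be", were = "be", be = "be",
  been = "be", being = "be",
  did = "do", does = "do", doing = "do", done = "do",
  had = "have", has = "have", having = "have",
  will = "will", would = "would", can = "can", could = "could",
  follows = "follow", followed = "follow", following = "follow",
  sticks = "stick", stuck = "stick", sticking = "stick",
  vaccinates = "vaccinate", vaccinated = "vaccinate",
  vaccinating = "vaccinate",
  immunizes = "immunize", immunized = "immunize", immunizing = "immunize",
  runs = "run", ran = "run", running = "run",
  gets = "get", got = "get", gotten = "get", getting = "get",
  goes = "go", went = "go", going = "go",
  children = "child", babies = "baby", rashes = "rash", hives = "hive",
  spacing = "spacing", always = "always",
  this = "this", his = "his", its = "its", was = "be"
)

.verb_lemmas <- c("be", "do", "have", "will", "would", "can", "could",
                  "follow", "stick", "vaccinate", "immunize", "run", "get",
                  "go", "react", "skip", "change")
.aux_lemmas <- c("be", "do", "have", "will", "would", "can", "could")

lemmatize <- function(tokens) {
  out <- unname(.lemma_table[tokens])
  miss <- is.na(out)
  raw <- tokens[miss]
  strip <- nchar(raw) > 3 & endsWith(raw, "s") &
    !endsWith(raw, "ss") & !endsWith(raw, "us") & !endsWith(raw, "is")
  raw[strip] <- substr(raw[strip], 1L, nchar(raw[strip]) - 1L)
  out[miss] <- raw
  out
}

# lower-case, expand contractions, merge multiword expressions
normalize_text <- function(text) {
  x <- tolower(text)
  x <- gsub("n't", " not", x, fixed = TRUE)
  x <- gsub("'m", " am", x, fixed = TRUE)
  x <- gsub("'re", " are", x, fixed = TRUE)
  x <- gsub("'ve", " have", x, fixed = TRUE)
  x <- gsub("'ll", " will", x, fixed = TRUE)
  x <- gsub("\\bspread out\\b", "spread-out", x)
  x <- gsub("\\bone at a time\\b", "one-at-a-time", x)
  x <- gsub("\\bon time\\b", "on-time", x)
  x <- gsub("\\blow grade\\b", "low-grade", x)
  x <- gsub("\\bside effects?\\b", "side-effect", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

split_sentences <- function(text) {
  parts <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
  parts[nzchar(trimws(parts))]
}

# tokenize one sentence; returns tokens plus a comma-clause segment id each
tokenize_sentence <- function(sentence) {
  segments <- unlist(strsplit(sentence, "[,;]"))
  tokens <- character(0)
  seg_id <- integer(0)
  for (s in seq_along(segments)) {
    toks <- unlist(strsplit(trimws(segments[s]), "\\s+"))
    toks <- gsub("[.!?:\"')]+$", "", toks)
    toks <- gsub("^[\"'(]+", "", toks)
    toks <- toks[nzchar(toks)]
    tokens <- c(tokens, toks)
    seg_id <- c(seg_id, rep(s, length(toks)))
  }
  list(tokens = tokens, segment = seg_id)
}

find_main_verb <- function(lemmas) {
  cand <- which(lemmas %in% .verb_lemmas)
  if (length(cand) == 0) return(NA_integer_)
  for (v in cand) {
    if (lemmas[v] %in% .aux_lemmas &&
        any(cand > v & cand <= v + 3L)) next
    return(v)
  }
  cand[1]
}

find_subject_span <- function(tokens, lemmas, segment, main_verb) {
  if (is.na(main_verb) || main_verb == 1L) return(NULL)
  j <- main_verb - 1L
  # skip adverbs, negations and auxiliaries between subject and main verb
  while (j >= 1L && (tokens[j] %in% .adverb_words ||
                     tokens[j] %in% .negation_words ||
                     lemmas[j] %in% .aux_lemmas)) j <- j - 1L
  if (j < 1L || segment[j] != segment[main_verb]) return(NULL)
  end <- j
  stoppers <- c(.prep_words, .conj_words)
  while (j >= 1L && segment[j] == segment[main_verb]) {
    tok <- tokens[j]
    if (tok %in% stoppers || lemmas[j] %in% .verb_lemmas ||
        tok %in% .negation_words) break
    if (tok %in% .det_words) { j <- j - 1L; break }
    j <- j - 1L
  }
  start <- j + 1L
  if (start > end) return(NULL)
  c(start, end)
}

# noun-phrase scan left of a keyword: adjectival + compound modifiers
scan_keyword_np <- function(tokens, lemmas, segment, i, max_len = 4L) {
  modifiers <- character(0)
  compounds <- character(0)
  det_no <- FALSE
  j <- i - 1L
  steps <- 0L
  while (j >= 1L && steps < max_len && segment[j] == segment[i]) {
    tok <- tokens[j]
    if (tok == "no") { det_no <- TRUE; break }
    if (tok %in% .det_words) break
    if (tok %in% c(.prep_words, .conj_words, .negation_words) ||
        lemmas[j] %in% .verb_lemmas) break
    if (tok %in% .adjective_words) modifiers <- c(tok, modifiers)
    else compounds <- c(lemmas[j], compounds)
    j <- j - 1L
    steps <- steps + 1L
  }
  list(modifiers = modifiers, compounds = compounds, det_no = det_no)
}

summarize_one <- function(sentence, keywords) {
  tk <- tokenize_sentence(sentence)
  tokens <- tk$tokens
  segment <- tk$segment
  n <- length(tokens)
  if (n == 0) return(NULL)
  lemmas <- lemmatize(tokens)
  verb_candidates <- which(lemmas %in% .verb_lemmas)
  main_verb <- find_main_verb(lemmas)
  negation_indices <- which(tokens %in% .negation_words)
  subject_span <- find_subject_span(tokens, lemmas, segment, main_verb)

  keyword_hits <- list()
  if (length(keywords) > 0) {
    hit_idx <- which(lemmas %in% keywords | tokens %in% keywords)
    keyword_hits <- lapply(hit_idx, function(i) {
      np <- scan_keyword_np(tokens, lemmas, segment, i)
      list(keyword = if (lemmas[i] %in% keywords) lemmas[i] else tokens[i],
           index = i, modifiers = np$modifiers, compounds = np$compounds,
           det_no = np$det_no)
    })
  }

  # approximate heads/relations for the structured summary contract
  head_index <- rep(if (is.na(main_verb)) 0L else main_verb, n)
  dep_relation <- rep("dep", n)
  if (!is.na(main_verb)) {
    head_index[main_verb] <- 0L
    dep_relation[main_verb] <- "root"
  }
  if (!is.null(subject_span)) {
    dep_relation[subject_span[1]:subject_span[2]] <- "nsubj"
  }
  dep_relation[negation_indices] <- "neg"
  for (h in keyword_hits) {
    np_idx <- which(tokens %in% c(h$modifiers) | lemmas %in% c(h$compounds))
    np_idx <- np_idx[np_idx < h$index & np_idx >= h$index - 4L]
    head_index[np_idx] <- h$index
    dep_relation[np_idx] <- ifelse(tokens[np_idx] %in% .adjective_words,
                                   "amod", "compound")
  }

  structure(list(
    tokens = tokens, lemmas = lemmas, segment = segment,
    head_index = head_index, dep_relation = dep_relation,
    subject_span = subject_span, main_verb_index = main_verb,
    verb_candidates = verb_candidates,
    negation_indices = negation_indices, keyword_hits = keyword_hits
  ), class = "sentence_summary")
}

#' Build structured summaries of the sentences in a comment
#'
#' Splits a comment into sentences and annotates each with tokens, lemmas,
#' approximate governor indices and relation labels, the subject span, the
#' main verb, negation cue positions, and — for each supplied keyword — the
#' adjectival and compound modifiers found in its noun phrase. The annotation
#' is rule-based and fully deterministic.
#'
#' @param text comment text (a single string).
#' @param keywords lower-case lemmas to locate and contextualize; typically the
#'   schedule keywords or the flattened reaction vocabulary.
#' @return A list of `sentence_summary` objects, one per detected sentence
#'   (empty for whitespace-only text). Unparseable fragments yield summaries
#'   with empty subject and verb slots rather than errors.
#' @examples
#' s <- summarize_sentences("I follow the regular vaccination schedule.",
#'                          keywords = "schedule")
#' s[[1]]$keyword_hits[[1]]$compounds  # "vaccination"
#' @export
summarize_sentences <- function(text, keywords = character()) {
  stopifnot(is.character(text), length(text) == 1)
  norm <- normalize_text(text)
  if (!nzchar(norm)) return(list())
  sentences <- split_sentences(norm)
  out <- lapply(sentences, summarize_one, keywords = tolower(keywords))
  out[!vapply(out, is.null, logical(1))]
}

# does a negation cue attach to the clause verb governing token position i?
# verb attachment: cue within 2 tokens of a verb candidate that does not
# follow the target. NP attachment (det "no") is handled by the caller.
negation_attached <- function(summary, i, max_np_distance = 0L) {
  negs <- summary$negation_indices
  negs <- negs[negs < i & summary$segment[negs] == summary$segment[i]]
  if (length(negs) == 0) return(FALSE)
  verbs <- summary$verb_candidates
  verbs <- verbs[verbs <= i]
  for (ng in negs) {
    if (length(verbs) > 0 && any(abs(verbs - ng) <= 2L)) return(TRUE)
    if (max_np_distance > 0L && (i - ng) <= max_np_distance) return(TRUE)
  }
  FALSE
}
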