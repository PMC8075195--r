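#' Construct a forum corpus
#'
#' A `forum_corpus` bundles three tables: `posts` (post_id, user_id,
#' timestamp, title, body), `comments` (comment_id, post_id, user_id,
#' timestamp, text) and `profiles` (user_id, self_reported_location, groups,
#' public). Timestamps are UTC `POSIXct`; `groups` is a list-column of
#' character vectors, empty for non-public profiles. Users without a public
#' profile page are kept with `public = FALSE` rather than dropped, mirroring
#' the partial profile coverage typical of scraped forums.
#'
#' @param posts data frame of posts.
#' @param comments data frame of comments.
#' @param profiles data frame of user profiles.
#' @param validate if `TRUE` (default), stop when [integrity_check()] reports
#'   violations.
#' @return An object of class `forum_corpus`.
#' @seealso [load_corpus()], [write_corpus()], [integrity_check()]
#' @export
forum_corpus <- function(posts = empty_posts(), comments = empty_comments(),
                         profiles = empty_profiles(), validate = TRUE) {
  posts <- coerce_posts(posts)
  comments <- coerce_comments(comments)
  profiles <- coerce_profiles(profiles)
  corpus <- structure(
    list(posts = posts, comments = comments, profiles = profiles),
    class = "forum_corpus"
  )
  if (validate) {
    violations <- integrity_check(corpus)
    if (length(violations) > 0) {
      stop("corpus integrity violations:\n", paste("-", violations, collapse = "\n"),
           call. = FALSE)
    }
  }
  corpus
}

empty_posts <- function() {
  tibble::tibble(post_id = character(), user_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 title = character(), body = character())
}

empty_comments <- function() {
  tibble::tibble(comment_id = character(), post_id = character(),
                 user_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 text = character())
}

empty_profiles <- function() {
  tibble::tibble(user_id = character(), self_reported_location = character(),
                 groups = list(), public = logical())
}

coerce_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(as.character(x), format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

coerce_posts <- function(posts) {
  posts <- tibble::as_tibble(posts)
  if (nrow(posts) == 0 && ncol(posts) == 0) return(empty_posts())
  require_cols(posts, c("post_id", "user_id", "timestamp", "title", "body"), "posts")
  dplyr::mutate(posts,
    post_id = as.character(.data$post_id),
    user_id = as.character(.data$user_id),
    timestamp = coerce_timestamp(.data$timestamp),
    title = as.character(.data$title),
    body = as.character(.data$body)
  )[, c("post_id", "user_id", "timestamp", "title", "body")]
}

coerce_comments <- function(comments) {
  comments <- tibble::as_tibble(comments)
  if (nrow(comments) == 0 && ncol(comments) == 0) return(empty_comments())
  require_cols(comments, c("comment_id", "post_id", "user_id", "timestamp", "text"),
               "comments")
  dplyr::mutate(comments,
    comment_id = as.character(.data$comment_id),
    post_id = as.character(.data$post_id),
    user_id = as.character(.data$user_id),
    timestamp = coerce_timestamp(.data$timestamp),
    text = as.character(.data$text)
  )[, c("comment_id", "post_id", "user_id", "timestamp", "text")]
}

coerce_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) == 0 && ncol(profiles) == 0) return(empty_profiles())
  require_cols(profiles, c("user_id", "self_reported_location", "groups", "public"),
               "profiles")
  groups <- profiles$groups
  if (!is.list(groups)) groups <- as.list(groups)
  groups <- lapply(groups, function(g) {
    g <- as.character(g)
    g[!is.na(g) & nzchar(g)]
  })
  tibble::tibble(
    user_id = as.character(profiles$user_id),
    self_reported_location = as.character(profiles$self_reported_location),
    groups = groups,
    public = as.logical(profiles$public)
  )
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat(sprintf("<forum_corpus> %d posts, %d comments, %d profiles\n",
              nrow(x$posts), nrow(x$comments), nrow(x$profiles)))
  invisible(x)
}

#' Check the referential and type invariants of a corpus
#'
#' Violations are returned as data, not raised: duplicate post / comment /
#' profile identifiers, comments referencing a nonexistent post, missing
#' timestamps, and non-public profiles carrying group memberships.
#'
#' @param corpus a [forum_corpus()].
#' @return Character vector of human-readable violation descriptions; empty
#'   when all invariants hold.
#' @export
integrity_check <- function(corpus) {
  v <- character()
  p <- corpus$posts; cm <- corpus$comments; pr <- corpus$profiles
  dup <- unique(p$post_id[duplicated(p$post_id)])
  if (length(dup) > 0)
    v <- c(v, sprintf("duplicated post_id: %s", paste(dup, collapse = ", ")))
  dup <- unique(cm$comment_id[duplicated(cm$comment_id)])
  if (length(dup) > 0)
    v <- c(v, sprintf("duplicated comment_id: %s", paste(dup, collapse = ", ")))
  dup <- unique(pr$user_id[duplicated(pr$user_id)])
  if (length(dup) > 0)
    v <- c(v, sprintf("duplicated profile user_id: %s", paste(dup, collapse = ", ")))
  orphan <- !(cm$post_id %in% p$post_id)
  if (any(orphan)) {
    v <- c(v, sprintf("comment %s references missing post %s",
                      cm$comment_id[orphan], cm$post_id[orphan]))
  }
  if (anyNA(p$timestamp))
    v <- c(v, sprintf("post %s has missing timestamp", p$post_id[is.na(p$timestamp)]))
  if (anyNA(cm$timestamp))
    v <- c(v, sprintf("comment %s has missing timestamp",
                      cm$comment_id[is.na(cm$timestamp)]))
  closed <- !pr$public & vapply(pr$groups, length, integer(1)) > 0
  if (any(closed)) {
    v <- c(v, sprintf("non-public profile %s has non-empty groups",
                      pr$user_id[closed]))
  }
  v
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", na = "null"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  lapply(seq_along(idx), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[idx[i]], simplifyVector = TRUE),
      error = function(e) {
        stop(sprintf("parse error in %s at line %d: %s",
                     basename(path), idx[i], conditionMessage(e)), call. = FALSE)
      }
    )
    rec
  })
}

jsonl_field <- function(records, field, default = NA_character_) {
  vapply(records, function(r) {
    val <- r[[field]]
    if (is.null(val) || length(val) == 0 || all(is.na(val))) default
    else as.character(val)[1]
  }, character(1))
}

#' Read a corpus from a directory of JSON-lines files
#'
#' Expects `posts.jsonl`, `comments.jsonl` and `profiles.jsonl` under `path`,
#' one UTF-8 JSON object per line with fields matching the corpus tables.
#' Malformed lines are reported with their line number; the assembled corpus
#' must pass [integrity_check()].
#'
#' @param path directory containing the three files.
#' @return A [forum_corpus()].
#' @export
load_corpus <- function(path) {
  posts_rec <- read_jsonl(file.path(path, "posts.jsonl"))
  comments_rec <- read_jsonl(file.path(path, "comments.jsonl"))
  profiles_rec <- read_jsonl(file.path(path, "profiles.jsonl"))

  posts <- if (length(posts_rec) == 0) empty_posts() else tibble::tibble(
    post_id = jsonl_field(posts_rec, "post_id"),
    user_id = jsonl_field(posts_rec, "user_id"),
    timestamp = coerce_timestamp(jsonl_field(posts_rec, "timestamp")),
    title = jsonl_field(posts_rec, "title"),
    body = jsonl_field(posts_rec, "body")
  )
  comments <- if (length(comments_rec) == 0) empty_comments() else tibble::tibble(
    comment_id = jsonl_field(comments_rec, "comment_id"),
    post_id = jsonl_field(comments_rec, "post_id"),
    user_id = jsonl_field(comments_rec, "user_id"),
    timestamp = coerce_timestamp(jsonl_field(comments_rec, "timestamp")),
    text = jsonl_field(comments_rec, "text")
  )
  profiles <- if (length(profiles_rec) == 0) empty_profiles() else tibble::tibble(
    user_id = jsonl_field(profiles_rec, "user_id"),
    self_reported_location = jsonl_field(profiles_rec, "self_reported_location"),
    groups = lapply(profiles_rec, function(r) as.character(unlist(r[["groups"]]))),
    public = vapply(profiles_rec, function(r) isTRUE(as.logical(r[["public"]])),
                    logical(1))
  )
  forum_corpus(posts, comments, profiles, validate = TRUE)
}

#' Write a corpus as JSON-lines files
#'
#' Inverse of [load_corpus()]: writes `posts.jsonl`, `comments.jsonl` and
#' `profiles.jsonl` under `path` (created if needed). Text round-trips
#' byte-identically (UTF-8); `load_corpus(write_corpus(x, p))` is the identity
#' on valid corpora.
#'
#' @param corpus a valid [forum_corpus()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  violations <- integrity_check(corpus)
  if (length(violations) > 0) {
    stop("refusing to write corpus with integrity violations:\n",
         paste("-", violations, collapse = "\n"), call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  posts <- corpus$posts
  write_jsonl(lapply(seq_len(nrow(posts)), function(i) list(
    post_id = posts$post_id[i], user_id = posts$user_id[i],
    timestamp = format_timestamp(posts$timestamp[i]),
    title = posts$title[i], body = posts$body[i]
  )), file.path(path, "posts.jsonl"))
  cm <- corpus$comments
  write_jsonl(lapply(seq_len(nrow(cm)), function(i) list(
    comment_id = cm$comment_id[i], post_id = cm$post_id[i],
    user_id = cm$user_id[i], timestamp = format_timestamp(cm$timestamp[i]),
    text = cm$text[i]
  )), file.path(path, "comments.jsonl"))
  pr <- corpus$profiles
  write_jsonl(lapply(seq_len(nrow(pr)), function(i) list(
    user_id = pr$user_id[i],
    self_reported_location = pr$self_reported_location[i],
    groups = I(pr$groups[[i]]),
    public = pr$public[i]
  )), file.path(path, "profiles.jsonl"))
  invisible(path)
}
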