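#' Aggregate one user's schedule-comment labels
#'
#' Unanimous labels propagate directly; discordant labels resolve by majority;
#' an exact tie resolves to the label of the chronologically latest comment.
#' The rule is injectable: `"any_alternative"` instead labels the user ASU as
#' soon as any comment is alternative.
#'
#' @param labels character vector of `"recommended"` / `"alternative"` comment
#'   labels (at least one).
#' @param timestamps `POSIXct` vector aligned with `labels`; required by the
#'   tie-break of the default rule.
#' @param rule conflict-resolution rule.
#' @return A list with `value` (`"RSU"` or `"ASU"`), `n_schedule_comments`,
#'   and `conflict_resolved` (TRUE for any non-unanimous input).
#' @export
aggregate_schedule_labels <- function(labels, timestamps = NULL,
                                      rule = c("majority_latest",
                                               "any_alternative")) {
  rule <- match.arg(rule)
  if (length(labels) == 0) stop("no schedule labels to aggregate", call. = FALSE)
  stopifnot(all(labels %in% c("recommended", "alternative")))
  conflict <- length(unique(labels)) > 1
  n_alt <- sum(labels == "alternative")
  n_rec <- sum(labels == "recommended")
  winner <- if (rule == "any_alternative") {
    if (n_alt > 0) "alternative" else "recommended"
  } else if (n_alt > n_rec) {
    "alternative"
  } else if (n_rec > n_alt) {
    "recommended"
  } else {
    if (is.null(timestamps)) stop("tie requires timestamps", call. = FALSE)
    labels[which.max(timestamps)]
  }
  list(value = if (winner == "alternative") "ASU" else "RSU",
       n_schedule_comments = length(labels),
       conflict_resolved = conflict)
}

#' Aggregate one user's AEFI experience labels
#'
#' A user reports negative experiences as soon as any of their comments is a
#' negative experience; all other labeled users report positive experiences.
#' Order-invariant.
#'
#' @param labels character vector of `"negative_experience"` /
#'   `"positive_experience"` comment labels (at least one).
#' @return `"reporting_negative"` or `"reporting_positive"`.
#' @export
aggregate_experience_labels <- function(labels) {
  if (length(labels) == 0) stop("no experience labels to aggregate", call. = FALSE)
  stopifnot(all(labels %in% c("negative_experience", "positive_experience")))
  if (any(labels == "negative_experience")) "reporting_negative"
  else "reporting_positive"
}

#' Label all users from comment-level schedule labels
#'
#' @param schedule_labels tibble from [run_schedule_pipeline()] (needs
#'   `comment_id`, `user_id`, `label`).
#' @param comments the corpus `comments` table, used for tie-break timestamps.
#' @param rule see [aggregate_schedule_labels()].
#' @return Tibble: `user_id`, `value` (RSU/ASU), `n_schedule_comments`,
#'   `conflict_resolved`.
#' @export
user_schedule_labels <- function(schedule_labels, comments,
                                 rule = "majority_latest") {
  if (nrow(schedule_labels) == 0) {
    return(tibble::tibble(user_id = character(), value = character(),
                          n_schedule_comments = integer(),
                          conflict_resolved = logical()))
  }
  joined <- dplyr::left_join(
    schedule_labels,
    comments[, c("comment_id", "timestamp")],
    by = "comment_id"
  )
  joined |>
    dplyr::group_by(.data$user_id) |>
    dplyr::group_modify(function(d, key) {
      agg <- aggregate_schedule_labels(d$label, d$timestamp, rule = rule)
      tibble::tibble(value = agg$value,
                     n_schedule_comments = agg$n_schedule_comments,
                     conflict_resolved = agg$conflict_resolved)
    }) |>
    dplyr::ungroup()
}

#' Label all users from comment-level AEFI labels
#'
#' @param aefi_labels tibble from [run_aefi_pipeline()] (needs `user_id`,
#'   `label`).
#' @return Tibble: `user_id`, `value` (reporting_negative/reporting_positive).
#' @export
user_experience_labels <- function(aefi_labels) {
  if (nrow(aefi_labels) == 0) {
    return(tibble::tibble(user_id = character(), value = character()))
  }
  aefi_labels |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(value = aggregate_experience_labels(.data$label),
                     .groups = "drop")
}

#' Activity statistics for one user
#'
#' Counts authored posts and comments, schedule-related comments when labels
#' are supplied, the activity period tau (whole days between first and last
#' comment), whether all activity fell on a single calendar day (such users
#' are excluded from tau summaries), and the number of comments received under
#' each authored post.
#'
#' @param corpus a [forum_corpus()].
#' @param user_id the user.
#' @param schedule_labels optional tibble from [run_schedule_pipeline()].
#' @return A list: `user_id`, `n_posts`, `n_comments`, `n_schedule_comments`,
#'   `tau`, `single_day`, `comments_under_posts` (integer vector, one entry
#'   per authored post).
#' @export
compute_activity <- function(corpus, user_id, schedule_labels = NULL) {
  cm <- corpus$comments[corpus$comments$user_id == user_id, ]
  if (nrow(cm) == 0) stop(sprintf("user %s has no comments", user_id),
                          call. = FALSE)
  posts <- corpus$posts[corpus$posts$user_id == user_id, ]
  n_cs <- if (is.null(schedule_labels)) NA_integer_ else
    sum(schedule_labels$user_id == user_id)
  dates <- as.Date(cm$timestamp, tz = "UTC")
  tau <- as.integer(round(as.numeric(difftime(max(cm$timestamp),
                                              min(cm$timestamp),
                                              units = "days"))))
  received <- table(factor(corpus$comments$post_id, levels = posts$post_id))
  list(user_id = user_id,
       n_posts = nrow(posts),
       n_comments = nrow(cm),
       n_schedule_comments = n_cs,
       tau = tau,
       single_day = length(unique(dates)) == 1,
       comments_under_posts = as.integer(received))
}

#' Group activity table for RSUs and ASUs
#'
#' Summarises, per user group: the number of users, authored posts, comments
#' and schedule-related comments (with per-user means), the median activity
#' period tau over users active on more than one day, and the median number
#' of comments received under the group's posts (I_p, computed per authored
#' post).
#'
#' @param corpus a [forum_corpus()].
#' @param user_labels tibble from [user_schedule_labels()].
#' @param schedule_labels tibble from [run_schedule_pipeline()].
#' @return A tibble with one row per group (RSU, ASU).
#' @export
activity_table <- function(corpus, user_labels, schedule_labels) {
  cm <- corpus$comments
  posts <- corpus$posts
  groups <- split(user_labels$user_id, user_labels$value)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    g_cm <- cm[cm$user_id %in% ids, ]
    g_posts <- posts[posts$user_id %in% ids, ]
    n_cs <- sum(schedule_labels$user_id %in% ids)
    per_user <- split(g_cm$timestamp, g_cm$user_id)
    taus <- vapply(per_user, function(ts) {
      if (length(unique(as.Date(ts, tz = "UTC"))) == 1) return(NA_real_)
      as.numeric(difftime(max(ts), min(ts), units = "days"))
    }, numeric(1))
    received <- as.integer(table(factor(cm$post_id, levels = g_posts$post_id)))
    tibble::tibble(
      group = g, n_users = length(ids),
      n_posts = nrow(g_posts), posts_per_user = nrow(g_posts) / length(ids),
      n_comments = nrow(g_cm), comments_per_user = nrow(g_cm) / length(ids),
      n_schedule_comments = n_cs,
      schedule_comments_per_user = n_cs / length(ids),
      median_tau = median(taus, na.rm = TRUE),
      median_comments_under_posts = if (length(received) > 0)
        median(received) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

wilson_ci <- function(k, n, conf.level = 0.95) {
  # Wilson score interval via base R's prop.test (correct = FALSE)
  ci <- suppressWarnings(
    stats::prop.test(k, n, conf.level = conf.level, correct = FALSE)$conf.int)
  c(ci[1], ci[2])
}

#' Prolificacy-class curve of recommended-comment probability
#'
#' Divides schedule-related comments into classes C_(a,b] by the number of
#' schedule-related comments their author wrote, and estimates within each
#' class the probability (with a Wilson 95% interval) that a comment is
#' labeled recommended. Empty classes are omitted; the classes partition the
#' labeled comments, so class sizes sum to the total.
#'
#' @param schedule_labels tibble with `comment_id`, `user_id`, `label`.
#' @param bounds strictly increasing class bounds; class i is
#'   `(bounds[i], bounds[i+1]]`. Defaults to powers of two.
#' @param conf.level confidence level for the Wilson interval.
#' @return A tibble: `a`, `b`, `n`, `k` (recommended comments), `p_hat`,
#'   `ci_low`, `ci_high`.
#' @export
prolificacy_curve <- function(schedule_labels, bounds = c(0, 1, 2, 4, 8, Inf),
                              conf.level = 0.95) {
  if (any(diff(bounds) <= 0)) stop("bounds must be strictly increasing",
                                   call. = FALSE)
  counts <- table(schedule_labels$user_id)
  per_comment_count <- as.integer(counts[schedule_labels$user_id])
  cls <- cut(per_comment_count, breaks = bounds, right = TRUE)
  rows <- lapply(seq_len(length(bounds) - 1L), function(i) {
    in_class <- which(as.integer(cls) == i)
    n <- length(in_class)
    if (n == 0) return(NULL)
    k <- sum(schedule_labels$label[in_class] == "recommended")
    ci <- wilson_ci(k, n, conf.level)
    tibble::tibble(a = bounds[i], b = bounds[i + 1L], n = n, k = k,
                   p_hat = k / n, ci_low = ci[1], ci_high = ci[2])
  })
  dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
}
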