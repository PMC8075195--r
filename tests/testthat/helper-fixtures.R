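# Small hand-built corpora used across tests; everything generated in code.

ts <- function(x) as.POSIXct(x, tz = "UTC")

make_corpus <- function(comment_texts = character(),
                        comment_users = rep("u1", length(comment_texts)),
                        validate = TRUE) {
  posts <- tibble::tibble(
    post_id = c("p1", "p2"),
    user_id = c("u1", "u2"),
    timestamp = ts(c("2013-01-01 10:00:00", "2013-02-01 10:00:00")),
    title = c("Shots question", "Schedule question"),
    body = c("Looking for advice.", "What did you do?")
  )
  n <- length(comment_texts)
  comments <- tibble::tibble(
    comment_id = sprintf("c%d", seq_len(n)),
    post_id = rep(c("p1", "p2"), length.out = max(n, 1))[seq_len(n)],
    user_id = comment_users,
    timestamp = ts("2013-03-01 10:00:00") + 86400 * seq_len(n),
    text = comment_texts
  )
  profiles <- tibble::tibble(
    user_id = unique(c("u1", "u2", comment_users)),
    self_reported_location = NA_character_,
    groups = replicate(length(unique(c("u1", "u2", comment_users))),
                       character(0), simplify = FALSE),
    public = FALSE
  )
  forum_corpus(posts, comments, profiles, validate = validate)
}

# independent enumeration oracle for the two-sided Fisher p-value:
# direct binomial-coefficient arithmetic over all tables with fixed margins
fisher_enumeration_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) return(1)
  as <- max(0, k - n2):min(k, m)
  probs <- exp(lchoose(m, as) + lchoose(n2, k - as) - lchoose(m + n2, k))
  p_obs <- probs[as == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
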