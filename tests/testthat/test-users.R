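test_that("schedule label aggregation: unanimity, majority, tie-to-latest", {
  t1 <- ts("2013-01-01 10:00:00"); t2 <- ts("2013-06-01 10:00:00")
  agg <- aggregate_schedule_labels(c("recommended", "recommended"), c(t1, t2))
  expect_identical(agg$value, "RSU")
  expect_false(agg$conflict_resolved)
  expect_equal(agg$n_schedule_comments, 2)

  agg <- aggregate_schedule_labels(c("recommended", "alternative", "alternative"),
                                   c(t1, t1, t2))
  expect_identical(agg$value, "ASU")
  expect_true(agg$conflict_resolved)

  agg <- aggregate_schedule_labels(c("recommended", "alternative"), c(t1, t2))
  expect_identical(agg$value, "ASU")   # latest wins the exact tie
  agg <- aggregate_schedule_labels(c("alternative", "recommended"), c(t1, t2))
  expect_identical(agg$value, "RSU")

  expect_error(aggregate_schedule_labels(character(0)), "no schedule labels")
  # injectable rule
  agg <- aggregate_schedule_labels(c("recommended", "recommended", "alternative"),
                                   rule = "any_alternative")
  expect_identical(agg$value, "ASU")
})

test_that("experience aggregation: any negative makes the user reporting_negative", {
  expect_identical(
    aggregate_experience_labels(c("positive_experience", "positive_experience",
                                  "negative_experience")),
    "reporting_negative")
  expect_identical(aggregate_experience_labels("positive_experience"),
                   "reporting_positive")
  expect_identical(aggregate_experience_labels("negative_experience"),
                   "reporting_negative")
  # order invariance
  labs <- c("negative_experience", rep("positive_experience", 4))
  for (i in 1:5) {
    expect_identical(aggregate_experience_labels(sample(labs)),
                     "reporting_negative")
  }
  expect_error(aggregate_experience_labels(character(0)), "no experience")
})

test_that("activity statistics count posts/comments and compute tau in days", {
  corpus <- make_corpus(c("one", "two", "three"),
                        comment_users = c("u1", "u1", "u1"))
  corpus$comments$timestamp <- ts("2013-01-01 12:00:00") + c(0, 86400 * 450, 3600)
  act <- compute_activity(corpus, "u1")
  expect_equal(act$n_comments, 3)
  expect_equal(act$n_posts, 1)
  expect_equal(act$tau, 450)
  expect_false(act$single_day)
  expect_equal(act$comments_under_posts,
               sum(corpus$comments$post_id == "p1"))

  one_day <- make_corpus("only one")
  act <- compute_activity(one_day, "u1")
  expect_equal(act$tau, 0)
  expect_true(act$single_day)
  expect_error(compute_activity(one_day, "ghost"), "no comments")
})

test_that("user-level labeling joins timestamps for the tie-break", {
  corpus <- make_corpus(c("a", "b", "c"), comment_users = c("u1", "u1", "u2"))
  sched <- tibble::tibble(
    comment_id = c("c1", "c2", "c3"),
    user_id = c("u1", "u1", "u2"),
    label = c("recommended", "alternative", "alternative"))
  ul <- user_schedule_labels(sched, corpus$comments)
  expect_identical(ul$value[ul$user_id == "u1"], "ASU")  # c2 is later
  expect_identical(ul$value[ul$user_id == "u2"], "ASU")
  expect_true(ul$conflict_resolved[ul$user_id == "u1"])
})

test_that("prolificacy classes partition comments and reproduce the overall mean", {
  # construct: prolific users lean alternative, so p_hat decreases by class
  labels <- dplyr::bind_rows(
    tibble::tibble(user_id = sprintf("s%02d", 1:20),
                   label = rep(c("recommended", "alternative"), c(16, 4))),
    tibble::tibble(user_id = rep(sprintf("m%02d", 1:10), each = 3),
                   label = rep(rep(c("recommended", "alternative"), c(4, 6)),
                               each = 3)),
    tibble::tibble(user_id = rep(sprintf("b%02d", 1:4), each = 10),
                   label = rep(rep(c("recommended", "alternative"), c(1, 3)),
                               each = 10))
  )
  labels$comment_id <- sprintf("c%03d", seq_len(nrow(labels)))
  curve <- prolificacy_curve(labels)
  expect_equal(sum(curve$n), nrow(labels))              # partition property
  expect_true(all(curve$ci_low <= curve$p_hat + 1e-12 &
                    curve$p_hat <= curve$ci_high + 1e-12))
  expect_true(all(diff(curve$p_hat) < 0))               # monotone by construction
  # overall recommended fraction = weighted mean of class p_hat
  expect_equal(sum(curve$p_hat * curve$n) / sum(curve$n),
               mean(labels$label == "recommended"))
  # empty classes omitted, overlapping bounds rejected
  # only (0,1], (2,3] and (3,100] are populated; empty classes are omitted
  expect_equal(nrow(prolificacy_curve(labels, bounds = c(0, 1, 2, 3, 100, Inf))),
               3)
  expect_error(prolificacy_curve(labels, bounds = c(0, 2, 1)), "increasing")
})

test_that("one comment in a class where all are recommended gives p_hat 1", {
  labels <- tibble::tibble(comment_id = "c1", user_id = "u1",
                           label = "recommended")
  curve <- prolificacy_curve(labels)
  expect_equal(curve$p_hat, 1)
  expect_equal(curve$n, 1)
})

test_that("activity_table summarises groups consistently", {
  sim <- generate_corpus(synthetic_config(n_users = 150, seed = 5))
  sched <- run_schedule_pipeline(sim$corpus)
  ul <- user_schedule_labels(sched, sim$corpus$comments)
  tab <- activity_table(sim$corpus, ul, sched)
  expect_setequal(tab$group, unique(ul$value))
  expect_equal(sum(tab$n_users), nrow(ul))
  expect_equal(sum(tab$n_schedule_comments), nrow(sched))
  expect_true(all(tab$schedule_comments_per_user >= 1))
})
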