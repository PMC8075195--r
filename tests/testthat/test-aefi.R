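aefi_cases <- list(
  # text, n_matches, label, subject, negated, reaction
  list("My nephew always runs a high fever after his shots.",
       1, "negative_experience", "acquaintance", FALSE, "fever"),
  list("I have a fever today, skipping work.", 0, NA, NA, NA, NA),
  list("No reaction at all after her 2-month shots.",
       1, "positive_experience", "unknown", TRUE, "reaction"),
  list("My daughter had a seizure after her shots.",
       1, "negative_experience", "child", FALSE, "seizure"),
  list("I ran a fever after my flu shot.",
       1, "negative_experience", "author", FALSE, "fever"),
  list("My son had no fever after the vaccines.",
       1, "positive_experience", "child", TRUE, "fever"),
  list("My friend's kid had a rash after the MMR vaccine.",
       1, "negative_experience", "acquaintance", FALSE, "rash"),
  list("He got a rash from the new detergent.", 0, NA, NA, NA, NA),
  list("My toddler had developmental regression after the MMR vaccine.",
       1, "negative_experience", "child", FALSE, "regression")
)

test_that("the AEFI filter requires an immunization context and tracks subjects", {
  for (case in aefi_cases) {
    m <- filter_aefi(list(comment_id = "x", text = case[[1]]))
    expect_equal(nrow(m), case[[2]], info = case[[1]])
    if (case[[2]] > 0) {
      expect_identical(classify_experience(m), case[[3]], info = case[[1]])
      expect_identical(m$subject[1], case[[4]], info = case[[1]])
      expect_identical(m$attribution_negated[1], case[[5]], info = case[[1]])
      expect_true(case[[6]] %in% m$reaction_terms[[1]], info = case[[1]])
    } else {
      expect_null(classify_experience(m))
    }
  }
})

test_that("classify_experience is monotone toward negative", {
  neg <- filter_aefi(list(comment_id = "x",
                          text = "My daughter had a seizure after her shots."))
  pos <- filter_aefi(list(comment_id = "x",
                          text = "My son had no fever after the vaccines."))
  expect_identical(classify_experience(pos), "positive_experience")
  expect_identical(classify_experience(dplyr::bind_rows(pos, neg)),
                   "negative_experience")
  expect_identical(classify_experience(dplyr::bind_rows(neg, pos)),
                   "negative_experience")
})

test_that("a comment labeled by both pipelines is retrievable by intersection", {
  corpus <- make_corpus(c(
    paste("We do a delayed vaccination schedule.",
          "My daughter had a seizure after her shots."),
    "I follow the regular vaccination schedule."
  ), comment_users = c("u1", "u2"))
  sched <- run_schedule_pipeline(corpus)
  aefi <- run_aefi_pipeline(corpus)
  both <- intersect(sched$comment_id, aefi$comment_id)
  expect_identical(both, "c1")
  expect_identical(sched$label[sched$comment_id == "c1"], "alternative")
  expect_identical(aefi$label[aefi$comment_id == "c1"], "negative_experience")
})

test_that("multiple reactions in one comment are all recorded", {
  corpus <- make_corpus(paste(
    "My son had a fever after the shots.",
    "He also got a rash after the vaccines."))
  out <- run_aefi_pipeline(corpus)
  expect_identical(out$reactions[[1]], c("fever", "rash"))
})

test_that("the AEFI pipeline is deterministic and empty when nothing matches", {
  corpus <- make_corpus(c("Thanks for sharing.", "Every kid is different."))
  expect_equal(nrow(run_aefi_pipeline(corpus)), 0)
  corpus2 <- make_corpus("My baby got a lot of fussiness after the shots.")
  expect_identical(run_aefi_pipeline(corpus2), run_aefi_pipeline(corpus2))
})
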