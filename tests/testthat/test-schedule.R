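# comment text -> expected (n_matches, label, negated) over the documented
# pattern family, including decoys and clause-external negation
schedule_cases <- list(
  list("I follow the regular vaccination schedule", 1, "recommended", FALSE),
  list("My work schedule is crazy this week", 0, NA, NA),
  list("The bus schedule changed again.", 0, NA, NA),
  list("We are not vaccinating on the recommended schedule", 1, "alternative", TRUE),
  list("We do a delayed vaccination schedule.", 1, "alternative", FALSE),
  list("We are spacing out her shots.", 1, "alternative", FALSE),
  list("My kids are on the CDC schedule.", 1, "recommended", FALSE),
  list("We go with a one at a time schedule for her shots.", 1, "alternative", FALSE),
  list("My kids are on a spread out vaccination schedule.", 1, "alternative", FALSE),
  list("We are not doing a delayed schedule for his shots.", 1, "recommended", TRUE),
  list("Not sure it matters, but we follow the regular vaccination schedule.",
       1, "recommended", FALSE),
  list("We do not follow the CDC schedule.", 1, "alternative", TRUE),
  list("We stick to the regular schedule of vaccinations.", 1, "recommended", FALSE)
)

test_that("the filter matches schedule statements and rejects decoys", {
  for (case in schedule_cases) {
    m <- filter_schedule(list(comment_id = "x", text = case[[1]]))
    expect_equal(nrow(m), case[[2]], info = case[[1]])
    if (case[[2]] > 0) {
      expect_identical(classify_schedule(m), case[[3]], info = case[[1]])
      expect_identical(m$negated[1], case[[4]], info = case[[1]])
    } else {
      expect_null(classify_schedule(m))
    }
  }
})

test_that("matches with no polarity cues and no negation default to recommended", {
  m <- filter_schedule(list(comment_id = "x",
                            text = "We follow the vaccination schedule."))
  expect_equal(nrow(m), 1)
  expect_length(m$alt_cues[[1]], 0)
  expect_length(m$rec_cues[[1]], 0)
  expect_false(m$negated[1])
  expect_identical(classify_schedule(m), "recommended")
})

test_that("classify_schedule is permutation-invariant and alt-dominant", {
  a <- filter_schedule(list(comment_id = "x",
                            text = "I follow the regular vaccination schedule."))
  b <- filter_schedule(list(comment_id = "x",
                            text = "We do a delayed vaccination schedule."))
  both <- dplyr::bind_rows(a, b)
  expect_identical(classify_schedule(both), "alternative")
  expect_identical(classify_schedule(both[2:1, ]), "alternative")
})

test_that("the lexicon is overridable and validates marker disjointness", {
  lex <- schedule_lexicon(alternative_markers = c("staggered"),
                          recommended_markers = c("regular"))
  m <- filter_schedule(list(comment_id = "x",
                            text = "We use a staggered vaccination schedule."),
                       lex)
  expect_identical(classify_schedule(m), "alternative")
  expect_error(schedule_lexicon(alternative_markers = "regular"),
               "disjoint")
})

test_that("the pipeline labels comments only, deterministically", {
  corpus <- make_corpus(c(
    "I follow the regular vaccination schedule.",
    "Thanks for sharing your story.",
    "We do a delayed vaccination schedule."
  ), comment_users = c("u1", "u1", "u2"))
  out1 <- run_schedule_pipeline(corpus)
  out2 <- run_schedule_pipeline(corpus)
  expect_identical(out1, out2)
  expect_setequal(out1$comment_id, c("c1", "c3"))
  expect_identical(out1$label[out1$comment_id == "c1"], "recommended")
  expect_identical(out1$label[out1$comment_id == "c3"], "alternative")
  # post titles/bodies contain keywords but are never labeled
  expect_false(any(grepl("^p", out1$comment_id)))

  empty <- run_schedule_pipeline(make_corpus("Nothing relevant here."))
  expect_equal(nrow(empty), 0)
})
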