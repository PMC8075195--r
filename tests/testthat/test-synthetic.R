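test_that("the same seed reproduces the corpus and ground truth exactly", {
  cfg <- synthetic_config(n_users = 120, seed = 7)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus$comments, b$corpus$comments)
  expect_identical(a$corpus$posts, b$corpus$posts)
  expect_identical(a$corpus$profiles, b$corpus$profiles)
  expect_identical(a$ground_truth$comments, b$ground_truth$comments)
  c <- generate_corpus(synthetic_config(n_users = 120, seed = 8))
  expect_false(identical(a$corpus$comments$text, c$corpus$comments$text))
})

test_that("degenerate mixtures and invalid configs behave as documented", {
  sim <- generate_corpus(synthetic_config(n_users = 60, asu_fraction = 0,
                                          seed = 3))
  expect_true(all(sim$ground_truth$users$schedule_label == "RSU"))
  sim <- generate_corpus(synthetic_config(n_users = 60, asu_fraction = 1,
                                          seed = 3))
  expect_true(all(sim$ground_truth$users$schedule_label == "ASU"))
  err <- tryCatch(synthetic_config(asu_fraction = 1.4, homophily = -0.1),
                  error = identity)
  expect_match(conditionMessage(err), "asu_fraction")
  expect_match(conditionMessage(err), "homophily")
})

test_that("the ASU share lands within 3 binomial SE of the configured rate", {
  p <- 0.595; n <- 1500
  sim <- generate_corpus(synthetic_config(n_users = n, asu_fraction = p,
                                          seed = 21))
  share <- mean(sim$ground_truth$users$schedule_label == "ASU")
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("per-user comment counts follow the configured heavy tail", {
  n <- 5000; alpha <- 2.5
  sim <- generate_corpus(synthetic_config(
    n_users = n, activity_exponent = alpha, seed = 13,
    schedule_statement_rate = 0, aefi_rate = 0, url_rate = 0, decoy_rate = 0))
  counts <- as.integer(table(factor(sim$corpus$comments$user_id,
                                    levels = sim$ground_truth$users$user_id)))
  for (t in c(1, 2, 4, 8, 16)) {
    p <- activity_survival(t, alpha)
    expect_lt(abs(mean(counts > t) - p),
              3 * sqrt(p * (1 - p) / n) + 1e-9,
              label = sprintf("survival at %d", t))
  }
})

test_that("every clean template class realizes its intended label", {
  lex <- default_schedule_lexicon()
  check <- function(class, expected, slots = list()) {
    for (i in 1:25) {
      txt <- realize_sentence(class, slots)
      m <- filter_schedule(list(comment_id = "x", text = txt), lex)
      lab <- classify_schedule(m)
      if (is.null(expected)) {
        expect_null(lab, info = txt)
      } else {
        expect_identical(lab, expected, info = txt)
      }
    }
  }
  set.seed(2)
  check("schedule_recommended", "recommended")
  check("schedule_recommended_negated", "alternative")
  check("schedule_alternative", "alternative")
  check("schedule_alternative_negated_hard", "recommended")
  check("schedule_clause_external_negation_hard", "recommended")
  check("schedule_decoy", NULL)

  check_aefi <- function(class, expected, subjects) {
    for (subj in subjects) for (i in 1:15) {
      txt <- realize_sentence(class, list(subject = subj))
      m <- filter_aefi(list(comment_id = "x", text = txt))
      lab <- classify_experience(m)
      if (is.null(expected)) expect_null(lab, info = txt)
      else {
        expect_identical(lab, expected, info = txt)
        if (subj %in% c("author", "child", "acquaintance")) {
          expect_identical(m$subject[1], subj, info = txt)
        }
      }
    }
  }
  check_aefi("aefi_negative", "negative_experience",
             c("author", "child", "acquaintance"))
  check_aefi("aefi_positive", "positive_experience",
             c("author", "child", "acquaintance", "none"))
  check_aefi("aefi_decoy", NULL, list(NULL))
  expect_error(realize_sentence("no_such_class"), "unknown template class")
})

test_that("h = 1 produces zero cross-leaning interaction edges", {
  sim <- generate_corpus(synthetic_config(
    n_users = 300, homophily = 1, seed = 19,
    schedule_statement_rate = 0, aefi_rate = 0, url_rate = 0, decoy_rate = 0))
  gt <- sim$ground_truth$users
  labels <- tibble::tibble(user_id = gt$user_id, value = gt$schedule_label)
  g <- build_graph(sim$corpus, labels)
  lean <- setNames(labels$value, labels$user_id)
  expect_true(all(lean[g$edges$source] == lean[g$edges$target]))
})
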