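test_that("odds ratio follows the cross-product rule with a Woolf interval", {
  r <- odds_ratio_ci(contingency_table(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1)
  expect_true(r$ci_low < 1 && r$ci_high > 1)

  r <- odds_ratio_ci(contingency_table(2, 8, 8, 2))
  expect_equal(r$odds_ratio, (2 * 2) / (8 * 8))  # 1/16 by hand
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)

  # one zero cell: continuity correction applied and flagged
  r <- odds_ratio_ci(contingency_table(0, 10, 5, 5))
  expect_true(r$corrected)
  expect_equal(r$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  # a zero row/column leaves the OR undefined
  expect_error(odds_ratio_ci(contingency_table(0, 0, 5, 5)), "undefined")
  expect_error(odds_ratio_ci(contingency_table(0, 5, 0, 5)), "undefined")
})

test_that("swapping the table rows inverts the OR and reflects the interval", {
  set.seed(31)
  for (i in 1:20) {
    cells <- rpois(4, 12) + 1
    r1 <- odds_ratio_ci(cells, fisher = FALSE)
    r2 <- odds_ratio_ci(cells[c(3, 4, 1, 2)], fisher = FALSE)
    expect_equal(r2$odds_ratio, 1 / r1$odds_ratio)
    expect_equal(r2$ci_low, 1 / r1$ci_high)
    expect_equal(r2$ci_high, 1 / r1$ci_low)
  }
})

test_that("fisher_exact matches both enumeration and the reference routine", {
  expect_equal(fisher_exact(c(10, 10, 10, 10)), 1)
  expect_equal(fisher_exact(c(1, 9, 11, 3)),
               fisher_enumeration_oracle(1, 9, 11, 3))
  set.seed(17)
  for (i in 1:40) {
    cells <- rpois(4, 6)
    p <- fisher_exact(cells)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, fisher_enumeration_oracle(cells[1], cells[2],
                                              cells[3], cells[4]))
    expect_equal(p, stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("group screening retains constructed signals and skips empty groups", {
  labels <- tibble::tibble(user_id = sprintf("u%03d", 1:200),
                           value = rep(c("ASU", "RSU"), each = 100))
  groups <- replicate(200, character(0), simplify = FALSE)
  # group joined only by ASUs, plus a uniformly joined group
  for (i in 1:40) groups[[i]] <- "ASU Only Group"
  for (i in seq(1, 200, by = 4)) groups[[i]] <- c(groups[[i]], "Everyone")
  profiles <- tibble::tibble(user_id = labels$user_id,
                             self_reported_location = NA_character_,
                             groups = groups, public = TRUE)
  res <- screen_groups(labels, profiles)
  sig <- res[res$group == "ASU Only Group", ]
  expect_true(sig$retained)
  expect_gt(sig$odds_ratio, 1)
  expect_false(res$retained[res$group == "Everyone"])
  expect_false("Ghost Group" %in% res$group)
})

test_that("URL domains are normalized, deduplicated per comment, and split by group", {
  comments <- tibble::tibble(
    comment_id = c("c1", "c2", "c3"),
    post_id = "p1", user_id = c("u1", "u2", "u3"),
    timestamp = ts("2013-01-01 00:00:00"),
    text = c(
      "See https://www.cdc.gov/vaccines and https://www.cdc.gov/flu too",
      "Compare www.nvic.org/page and https://pediatrics.aappublications.org/content",
      "no links here"))
  out <- extract_domains(comments)
  expect_equal(out$n_comments[out$domain == "cdc.gov"], 1)  # once per comment
  expect_setequal(out$domain,
                  c("cdc.gov", "nvic.org", "pediatrics.aappublications.org"))
  labels <- tibble::tibble(user_id = c("u1", "u2"), value = c("RSU", "ASU"))
  out <- extract_domains(comments, labels)
  expect_equal(out$n_comments_rsu[out$domain == "cdc.gov"], 1)
  expect_equal(out$n_comments_asu[out$domain == "nvic.org"], 1)
  # registrable mode collapses subdomains
  out <- extract_domains(comments, mode = "registrable")
  expect_true("aappublications.org" %in% out$domain)
})

test_that("users are geolocated from self-reports first, local groups second", {
  gaz <- state_gazetteer()
  expect_equal(nrow(gaz), 51)
  profile <- list(user_id = "u1", self_reported_location = "Austin, TX",
                  groups = list(character(0)))
  g <- geolocate_user(profile, gaz)
  expect_identical(g$state, "Texas")
  expect_identical(g$source, "self_report")

  profile <- list(user_id = "u2", self_reported_location = NA_character_,
                  groups = list("Texas Moms"))
  g <- geolocate_user(profile, gaz)
  expect_identical(g$state, "Texas")
  expect_identical(g$source, "local_group")

  profile <- list(user_id = "u3", self_reported_location = "Springfield, OH",
                  groups = list("Texas Moms"))
  g <- geolocate_user(profile, gaz)
  expect_identical(g$state, "Ohio")   # self-report wins
  expect_identical(g$source, "both")

  profile <- list(user_id = "u4", self_reported_location = NA_character_,
                  groups = list(character(0)))
  g <- geolocate_user(profile, gaz)
  expect_true(is.na(g$state))
})

test_that("log-log population correlation is exact for proportional counts", {
  tab <- state_population_table()
  expect_equal(nrow(tab), 51)
  counts <- setNames(tab$population * 0.001, tab$state)
  r <- population_correlation(counts)
  expect_equal(r$r, 1)
  expect_equal(r$n_states, 51)
  # permuted counts decorrelate
  set.seed(3)
  perm <- setNames(sample(counts), names(counts))
  expect_lt(abs(population_correlation(perm)$r), 0.5)
  expect_error(population_correlation(counts[1:2]), "at least 3")
})

test_that("evaluation metrics follow the two-stage design", {
  ann <- tibble::tibble(comment_id = sprintf("c%d", 1:6),
                        label = c("alternative", "recommended", "unrelated",
                                  "alternative", "recommended", "alternative"))
  # perfect predictions on the related comments
  pred <- tibble::tibble(comment_id = sprintf("c%d", c(1, 2, 4, 5, 6)),
                         label = c("alternative", "recommended", "alternative",
                                   "recommended", "alternative"))
  m <- evaluation_metrics(pred, ann)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  # 3 retrieved, 2 relevant -> filter precision 2/3
  pred <- tibble::tibble(comment_id = c("c1", "c2", "c3"),
                         label = c("alternative", "recommended", "alternative"))
  m <- evaluation_metrics(pred, ann)
  expect_equal(m$precision, 2 / 3)
  # degenerate predictor: all recommended
  pred <- tibble::tibble(comment_id = sprintf("c%d", c(1, 2, 4, 5)),
                         label = "recommended")
  m <- evaluation_metrics(pred, ann)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_equal(sum(m$counts[c("tp", "fp", "tn", "fn")]),
               m$counts[["relevant"]])
  expect_error(evaluation_metrics(pred, ann[0, ]), "empty annotation")
})

test_that("Cohen's kappa matches its definition on hand-computed fixtures", {
  expect_equal(cohen_kappa(c("a", "b", "c", "a"), c("a", "b", "c", "a"))$kappa, 1)
  k <- cohen_kappa(rep("x", 10), rep(c("x", "y"), 5))
  expect_equal(k$kappa, 0)
  # 3-label fixture: p_o = 4/6; p_e = (3/6)(2/6)+(2/6)(2/6)+(1/6)(2/6) = 12/36
  a <- c("r", "r", "r", "a", "a", "u")
  b <- c("r", "r", "a", "a", "u", "u")
  k <- cohen_kappa(a, b)
  expect_equal(k$observed_agreement, 4 / 6)
  expect_equal(k$expected_agreement, 1 / 3)
  expect_equal(k$kappa, (4 / 6 - 1 / 3) / (1 - 1 / 3))
  expect_error(cohen_kappa(rep("x", 3), rep("x", 3)), "undefined")
})
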