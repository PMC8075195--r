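# Synthetic forum-corpus generator with exact ground truth.
#
# Sentences are realized from a controlled template bank (paraphrase slots,
# not free generation) so that the intended label of every sentence is exact
# by construction; the generator tests rule logic, not open-domain NLP.

#' Synthetic corpus configuration
#'
#' Parameters of the generating process. Defaults emulate the marginal
#' statistics reported for a large US parenting-forum study: about 59.5% of
#' schedule-labeled users on an alternative schedule, AEFI comments negative
#' for ~85% of ASU and ~75% of RSU authors, a heavy-tailed per-user comment
#' count, and state assignment proportional to the 2010 Census populations.
#'
#' @param n_users number of users (>= 2).
#' @param asu_fraction probability a user leans toward an alternative
#'   schedule.
#' @param schedule_statement_rate probability a comment carries a schedule
#'   statement (of the author's leaning).
#' @param negation_rate probability a schedule statement is phrased via
#'   negation (label preserved).
#' @param decoy_rate probability a comment without a schedule statement
#'   carries a decoy keyword sentence (e.g. "my work schedule").
#' @param hard_fraction probability a schedule statement uses a "hard"
#'   template (double negation, clause-external negation); flagged in the
#'   ground truth so easy and hard strata can be scored separately.
#' @param aefi_rate probability a comment carries an AEFI statement.
#' @param aefi_negative_given_asu,aefi_negative_given_rsu probability that an
#'   AEFI statement reports a negative experience, by author leaning.
#' @param secondhand_rate probability the AEFI subject is an acquaintance.
#' @param activity_exponent power-law exponent alpha of the per-user comment
#'   count (P(N = n) ~ n^-alpha, n >= 1).
#' @param homophily h in \[0, 1\]: a commenter picks a post by an author of
#'   their own leaning with probability h, otherwise any post uniformly (so
#'   cross-leaning contact at h = 0 reflects the population mixture).
#' @param n_groups number of thematic interest groups (max 20 named groups;
#'   beyond that, neutral numbered groups are added).
#' @param group_association_strength log-odds shift of joining a leaning-
#'   aligned group (positive favours the aligned leaning).
#' @param url_rate probability a comment embeds a URL.
#' @param post_rate mean number of authored posts per user (Poisson).
#' @param profile_public_rate probability a user's profile page is public.
#' @param location_report_rate probability a public profile self-reports a
#'   location.
#' @param state_assignment `"census"` for 2010-Census-proportional state
#'   weights, or a named numeric vector of weights over states.
#' @param seed integer RNG seed; all stochastic choices draw from one global
#'   stream keyed by it, in documented order.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_users = 2000,
                             asu_fraction = 0.595,
                             schedule_statement_rate = 0.35,
                             negation_rate = 0.15,
                             decoy_rate = 0.08,
                             hard_fraction = 0.05,
                             aefi_rate = 0.12,
                             aefi_negative_given_asu = 0.854,
                             aefi_negative_given_rsu = 0.748,
                             secondhand_rate = 0.10,
                             activity_exponent = 2.5,
                             homophily = 0.5,
                             n_groups = 20,
                             group_association_strength = 0.8,
                             url_rate = 0.05,
                             post_rate = 0.4,
                             profile_public_rate = 0.54,
                             location_report_rate = 0.62,
                             state_assignment = "census",
                             seed = 1L) {
  cfg <- list(n_users = n_users, asu_fraction = asu_fraction,
              schedule_statement_rate = schedule_statement_rate,
              negation_rate = negation_rate, decoy_rate = decoy_rate,
              hard_fraction = hard_fraction, aefi_rate = aefi_rate,
              aefi_negative_given_asu = aefi_negative_given_asu,
              aefi_negative_given_rsu = aefi_negative_given_rsu,
              secondhand_rate = secondhand_rate,
              activity_exponent = activity_exponent, homophily = homophily,
              n_groups = n_groups,
              group_association_strength = group_association_strength,
              url_rate = url_rate, post_rate = post_rate,
              profile_public_rate = profile_public_rate,
              location_report_rate = location_report_rate,
              state_assignment = state_assignment, seed = as.integer(seed))
  probs <- c("asu_fraction", "schedule_statement_rate", "negation_rate",
             "decoy_rate", "hard_fraction", "aefi_rate",
             "aefi_negative_given_asu", "aefi_negative_given_rsu",
             "secondhand_rate", "homophily", "url_rate",
             "profile_public_rate", "location_report_rate")
  bad <- character(0)
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      bad <- c(bad, p)
  }
  if (!is.numeric(n_users) || n_users < 2) bad <- c(bad, "n_users")
  if (!is.numeric(activity_exponent) || activity_exponent <= 1)
    bad <- c(bad, "activity_exponent")
  if (!is.numeric(n_groups) || n_groups < 0) bad <- c(bad, "n_groups")
  if (!is.numeric(post_rate) || post_rate <= 0) bad <- c(bad, "post_rate")
  if (length(bad) > 0) {
    stop("invalid synthetic_config field(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Read a synthetic configuration from YAML
#'
#' @param path YAML file whose keys are [synthetic_config()] arguments.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(synthetic_config, cfg)
}

# ---- template bank ---------------------------------------------------------

.recommended_markers_bank <- c("regular", "recommended", "normal")
.alternative_markers_bank <- c("delayed", "selective", "alternative", "modified")

.filler_bank <- c(
  "Thanks for sharing your experience.",
  "Our pediatrician is wonderful.",
  "Hang in there, mama.",
  "Every kid is different.",
  "Sending hugs your way.",
  "That sounds really stressful.",
  "We went through something similar last year.",
  "Hope everyone sleeps well tonight.",
  "This group has been such a help.",
  "Congrats on the new baby!"
)

.decoy_bank <- c(
  "My work schedule is crazy this week.",
  "The bus schedule changed again.",
  "My sleep schedule is a mess lately.",
  "Our feeding schedule finally settled down."
)

.reaction_phrases <- list(
  fever = "a high fever", seizure = "a seizure", rash = "a rash",
  swelling = "some swelling", fussiness = "a lot of fussiness",
  lethargy = "lethargy", vomiting = "vomiting", pain = "a lot of pain",
  regression = "developmental regression"
)

.child_subjects <- c("My son", "My daughter", "My baby", "My toddler")
.acquaintance_subjects <- c("My nephew", "My niece", "My friend's kid",
                            "My sister's baby", "My neighbor's son")

.url_bank_common <- c(
  "https://www.cdc.gov/vaccines/schedules/index.html",
  "https://www.ncbi.nlm.nih.gov/pmc/articles/",
  "https://www.fda.gov/vaccines-blood-biologics",
  "https://community.parentingforum.com/groups"
)
.url_bank_rsu <- c(
  "https://pediatrics.aappublications.org/content/early",
  "https://sciencebasedmedicine.org/vaccines",
  "https://www.chop.edu/centers-programs/vaccine-education-center"
)
.url_bank_asu <- c(
  "https://www.nvic.org/vaccines-and-diseases",
  "https://www.askdrsears.com/topics/health-concerns/vaccines"
)

pick <- function(x) x[sample.int(length(x), 1)]

#' Realize one templated sentence
#'
#' Draws a sentence from the documented template bank for the requested class,
#' filling paraphrase slots from the current RNG stream. By template
#' construction the returned text carries the intended ground-truth label
#' under correct rule application.
#'
#' Template classes: `schedule_recommended`, `schedule_recommended_negated`,
#' `schedule_alternative`, `schedule_alternative_negated_hard` (double flip,
#' true label recommended), `schedule_clause_external_negation_hard` (true
#' label recommended), `schedule_decoy`, `aefi_negative`, `aefi_positive`,
#' `aefi_decoy`, `filler`.
#'
#' @param template_class one of the classes above.
#' @param slots optional named list fixing slots: `subject` (one of author /
#'   child / acquaintance for AEFI classes), `reaction` (a canonical reaction
#'   name), `marker` (a polarity marker).
#' @return A single sentence (character).
#' @export
realize_sentence <- function(template_class, slots = list()) {
  marker <- slots$marker
  switch(template_class,
    schedule_recommended = {
      m <- marker %||% pick(.recommended_markers_bank)
      pick(c(
        sprintf("%s follow the %s vaccination schedule.", pick(c("I", "We")), m),
        sprintf("We are sticking to the %s shot schedule.", m),
        sprintf("We vaccinate on the %s schedule.", m),
        "My kids are on the CDC schedule.",
        sprintf("We stick to the %s schedule of vaccinations.", m)
      ))
    },
    schedule_recommended_negated = {
      m <- marker %||% pick(.recommended_markers_bank)
      pick(c(
        sprintf("I am not following the %s vaccination schedule.", m),
        sprintf("We are not vaccinating on the %s schedule.", m),
        "We do not follow the CDC schedule."
      ))
    },
    schedule_alternative = {
      m <- marker %||% pick(.alternative_markers_bank)
      pick(c(
        sprintf("We do a %s vaccination schedule.", m),
        sprintf("We follow a %s shot schedule.", m),
        "We are spacing out her shots.",
        sprintf("We vaccinate on a %s schedule.", m),
        "My kids are on a spread out vaccination schedule.",
        "We go with a one at a time schedule for her shots."
      ))
    },
    schedule_alternative_negated_hard = {
      m <- marker %||% pick(.alternative_markers_bank)
      sprintf("We are not doing a %s schedule for his shots.", m)
    },
    schedule_clause_external_negation_hard = {
      m <- marker %||% pick(.recommended_markers_bank)
      sprintf("Not sure it matters, but we follow the %s vaccination schedule.",
              m)
    },
    schedule_decoy = pick(.decoy_bank),
    aefi_negative = {
      subject <- slots$subject %||% "child"
      reaction <- slots$reaction %||% pick(names(.reaction_phrases))
      phrase <- .reaction_phrases[[reaction]]
      if (is.null(phrase)) stop("unknown reaction: ", reaction, call. = FALSE)
      subj <- switch(subject,
        author = "I",
        child = pick(.child_subjects),
        acquaintance = pick(.acquaintance_subjects),
        stop("unknown subject: ", subject, call. = FALSE))
      if (subject == "acquaintance" && reaction == "fever" &&
          runif(1) < 0.5) {
        sprintf("%s always runs a high fever after his shots.", subj)
      } else {
        pick(c(
          sprintf("%s %s %s after the shots.", subj, pick(c("had", "got")),
                  phrase),
          sprintf("%s had %s after the MMR vaccine.", subj, phrase)
        ))
      }
    },
    aefi_positive = {
      subject <- slots$subject %||% "child"
      reaction <- slots$reaction %||% "reaction"
      bare <- if (reaction == "reaction") "reaction" else reaction
      subj <- switch(subject,
        author = "I",
        child = pick(.child_subjects),
        acquaintance = pick(.acquaintance_subjects),
        none = NA_character_,
        stop("unknown subject: ", subject, call. = FALSE))
      if (is.na(subj)) {
        "No reaction at all after her 2-month shots."
      } else {
        pick(c(
          sprintf("%s had no %s after the vaccines.", subj, bare),
          sprintf("%s did not have any reaction to the shots.", subj)
        ))
      }
    },
    aefi_decoy = pick(c(
      "I have a fever today, skipping work.",
      "He got a rash from the new detergent."
    )),
    filler = pick(.filler_bank),
    stop("unknown template class: ", template_class, call. = FALSE)
  )
}

# discrete power law on {1, 2, ...} as the floor of a Pareto(1, alpha - 1)
# variate, so P(N > n) = (n + 1)^(1 - alpha)
rplaw <- function(n, alpha, cap = 500L) {
  u <- runif(n)
  pmin(cap, floor(u^(-1 / (alpha - 1))))
}

#' Survival function of the generating activity distribution
#'
#' `P(N > n) = (n + 1)^(1 - alpha)` for the per-user comment count (the floor
#' of a unit-scale Pareto variate with tail exponent `alpha - 1`), exposed so
#' tests can run distributional sanity checks against the generator.
#'
#' @param n non-negative integers.
#' @param alpha the configured `activity_exponent`.
#' @return `P(N > n)`.
#' @export
activity_survival <- function(n, alpha) (floor(pmax(0, n)) + 1)^(1 - alpha)

state_weights <- function(state_assignment) {
  if (identical(state_assignment, "census")) {
    tab <- state_population_table()
    return(setNames(tab$population / sum(tab$population), tab$state))
  }
  w <- unlist(state_assignment)
  w / sum(w)
}

#' Generate a synthetic forum corpus with ground truth
#'
#' Deterministic given the configured seed. Users receive a latent schedule
#' leaning (ASU with probability `asu_fraction`); per-user comment counts are
#' heavy-tailed; each comment attaches to a post through the homophily
#' process (same-leaning author with probability h, any author otherwise) and
#' may carry a schedule statement matching the author's leaning, an AEFI
#' statement (negative with a leaning-dependent probability), a decoy keyword
#' sentence, and an embedded URL. Public profiles carry interest-group
#' memberships tilted by leaning and, sometimes, a self-reported location or
#' a local state group.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `corpus` (a [forum_corpus()]) and
#'   `ground_truth`: `comments` (tibble `comment_id`, `schedule_label`,
#'   `hard`, `aefi_label`, `subject`, `reaction`), `users` (tibble `user_id`,
#'   `schedule_label`, `state`), and the `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_users
  user_id <- sprintf("u%05d", seq_len(n))
  is_asu <- runif(n) < config$asu_fraction
  user_label <- ifelse(is_asu, "ASU", "RSU")

  sw <- state_weights(config$state_assignment)
  user_state <- sample(names(sw), n, replace = TRUE, prob = sw)

  origin <- as.POSIXct("2012-01-01 00:00:00", tz = "UTC")
  span <- 2000 * 86400

  # posts -------------------------------------------------------------------
  n_posts <- rpois(n, config$post_rate)
  # guarantee at least one post per present leaning so attachment never fails
  for (lean in unique(user_label)) {
    idx <- which(user_label == lean)
    if (sum(n_posts[idx]) == 0) n_posts[idx[1]] <- 1L
  }
  post_author_idx <- rep(seq_len(n), n_posts)
  n_post_total <- length(post_author_idx)
  posts <- tibble::tibble(
    post_id = sprintf("p%06d", seq_len(n_post_total)),
    user_id = user_id[post_author_idx],
    timestamp = origin + round(runif(n_post_total, 0, span * 0.5)),
    title = "Question about vaccines",
    body = "What has your experience been? Looking for advice."
  )
  post_leaning <- user_label[post_author_idx]

  # comments ----------------------------------------------------------------
  n_comments <- rplaw(n, config$activity_exponent)
  author_idx <- rep(seq_len(n), n_comments)
  n_cm <- length(author_idx)
  cm_author <- user_id[author_idx]
  cm_leaning <- user_label[author_idx]

  same_lean_posts <- split(seq_len(n_post_total), post_leaning)
  use_homophily <- runif(n_cm) < config$homophily
  target_post <- integer(n_cm)
  all_posts <- seq_len(n_post_total)
  for (i in seq_len(n_cm)) {
    pool <- if (use_homophily[i]) same_lean_posts[[cm_leaning[i]]] else all_posts
    target_post[i] <- pool[sample.int(length(pool), 1)]
  }

  has_schedule <- runif(n_cm) < config$schedule_statement_rate
  is_negated <- runif(n_cm) < config$negation_rate
  is_hard <- runif(n_cm) < config$hard_fraction
  has_decoy <- !has_schedule & runif(n_cm) < config$decoy_rate
  has_aefi <- runif(n_cm) < config$aefi_rate
  p_neg <- ifelse(cm_leaning == "ASU", config$aefi_negative_given_asu,
                  config$aefi_negative_given_rsu)
  aefi_negative <- runif(n_cm) < p_neg
  subj_draw <- runif(n_cm)
  has_url <- runif(n_cm) < config$url_rate

  texts <- character(n_cm)
  gt_schedule <- rep("none", n_cm)
  gt_hard <- logical(n_cm)
  gt_aefi <- rep("none", n_cm)
  gt_subject <- rep("none", n_cm)
  gt_reaction <- rep(NA_character_, n_cm)
  reaction_names <- names(.reaction_phrases)

  for (i in seq_len(n_cm)) {
    parts <- realize_sentence("filler")
    if (has_schedule[i]) {
      lean <- cm_leaning[i]
      if (is_hard[i]) {
        gt_hard[i] <- TRUE
        cls <- if (lean == "RSU") {
          pick(c("schedule_alternative_negated_hard",
                 "schedule_clause_external_negation_hard"))
        } else {
          # no hard template realizes an alternative truth; fall back to a
          # negated phrasing, which is the harder clean variant
          "schedule_recommended_negated"
        }
        gt_schedule[i] <- if (lean == "RSU") "recommended" else "alternative"
        parts <- c(parts, realize_sentence(cls))
      } else if (lean == "ASU") {
        gt_schedule[i] <- "alternative"
        cls <- if (is_negated[i]) "schedule_recommended_negated"
        else "schedule_alternative"
        parts <- c(parts, realize_sentence(cls))
      } else {
        gt_schedule[i] <- "recommended"
        parts <- c(parts, realize_sentence("schedule_recommended"))
      }
    } else if (has_decoy[i]) {
      parts <- c(parts, realize_sentence("schedule_decoy"))
    }
    if (has_aefi[i]) {
      subject <- if (subj_draw[i] < config$secondhand_rate) "acquaintance"
      else if (subj_draw[i] < config$secondhand_rate +
                 (1 - config$secondhand_rate) * 0.6) "child"
      else "author"
      if (aefi_negative[i]) {
        reaction <- pick(reaction_names)
        gt_aefi[i] <- "negative"
        gt_subject[i] <- subject
        gt_reaction[i] <- reaction
        parts <- c(parts, realize_sentence("aefi_negative",
                                           list(subject = subject,
                                                reaction = reaction)))
      } else {
        gt_aefi[i] <- "positive"
        gt_subject[i] <- subject
        gt_reaction[i] <- NA_character_
        parts <- c(parts, realize_sentence("aefi_positive",
                                           list(subject = subject)))
      }
    }
    if (has_url[i]) {
      pool <- if (runif(1) < 0.6) .url_bank_common
      else if (cm_leaning[i] == "RSU") .url_bank_rsu else .url_bank_asu
      parts <- c(parts, sprintf("More info here: %s", pick(pool)))
    }
    texts[i] <- paste(parts, collapse = " ")
  }

  comments <- tibble::tibble(
    comment_id = sprintf("c%07d", seq_len(n_cm)),
    post_id = posts$post_id[target_post],
    user_id = cm_author,
    timestamp = origin + round(runif(n_cm, 0, span)),
    text = texts
  )

  # profiles ----------------------------------------------------------------
  public <- runif(n) < config$profile_public_rate
  group_bank <- thematic_group_bank(config$n_groups)
  s <- config$group_association_strength
  base_logit <- stats::qlogis(0.10)
  groups <- vector("list", n)
  location <- rep(NA_character_, n)
  gaz <- state_gazetteer()
  abb <- setNames(gaz$abb, gaz$state)
  for (i in seq_len(n)) {
    if (!public[i]) { groups[[i]] <- character(0); next }
    align <- group_bank$alignment
    shift <- ifelse(align == user_label[i], s, ifelse(align == "neutral", 0, -s))
    p_join <- stats::plogis(base_logit + shift)
    member <- runif(length(p_join)) < p_join
    g <- group_bank$name[member]
    if (runif(1) < 0.25) g <- c(g, sprintf("%s Moms", user_state[i]))
    groups[[i]] <- g
    if (runif(1) < config$location_report_rate) {
      location[i] <- if (runif(1) < 0.5) user_state[i]
      else sprintf("Springfield, %s", abb[[user_state[i]]])
    }
  }
  profiles <- tibble::tibble(
    user_id = user_id,
    self_reported_location = location,
    groups = groups,
    public = public
  )

  corpus <- forum_corpus(posts, comments, profiles, validate = TRUE)
  ground_truth <- list(
    comments = tibble::tibble(
      comment_id = comments$comment_id,
      user_id = cm_author,
      schedule_label = gt_schedule,
      hard = gt_hard,
      aefi_label = gt_aefi,
      subject = gt_subject,
      reaction = gt_reaction
    ),
    users = tibble::tibble(
      user_id = user_id,
      schedule_label = user_label,
      state = user_state
    ),
    config = config
  )
  list(corpus = corpus, ground_truth = ground_truth)
}

thematic_group_bank <- function(n_groups) {
  named <- tibble::tibble(
    name = c("None/Select/Delayed Vaccinations", "Crunchy Mamas",
             "Organic Mamas", "Attachment Parenting", "Homeschooling",
             "Formula-feeding Families", "Pumping Moms", "Working Moms",
             "Connect with Pampers",
             "First-Time Moms", "Sleep Training Support", "Toddler Meals",
             "Due Date Club", "Potty Training", "Budget Families",
             "Craft Corner", "Book Club Moms", "Meal Planning",
             "Single Parents", "Twins and Multiples"),
    alignment = c(rep("ASU", 5), rep("RSU", 4), rep("neutral", 11))
  )
  if (n_groups <= nrow(named)) return(named[seq_len(n_groups), ])
  extra <- tibble::tibble(
    name = sprintf("Community Group %02d", seq_len(n_groups - nrow(named))),
    alignment = "neutral"
  )
  dplyr::bind_rows(named, extra)
}
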