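#' Build a 2x2 contingency table
#'
#' Cell layout: `a` = group1 & feature present, `b` = group1 & feature absent,
#' `c` = group2 & feature present, `d` = group2 & feature absent.
#'
#' @param a,b,c,d non-negative counts.
#' @param groups,feature optional labels carried along for reporting.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, groups = c("group1", "group2"),
                              feature = "feature") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || anyNA(counts)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d,
                 groups = groups, feature = feature),
            class = "contingency_table")
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c); the interval is the log-OR normal approximation
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` (Woolf). A single zero
#' cell triggers the Haldane-Anscombe 0.5 continuity correction on all cells
#' and is flagged; a zero row or column leaves the OR undefined and errors.
#'
#' @param table a [contingency_table()] or a length-4 vector `(a, b, c, d)`.
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @param fisher if `TRUE` (default) also compute the two-sided
#'   [fisher_exact()] p-value on the uncorrected counts.
#' @return A list of class `or_result`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `alpha`, `corrected`, `p_fisher`.
#' @export
odds_ratio_ci <- function(table, alpha = 0.05, fisher = TRUE) {
  cells <- as_cells(table)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("odds ratio undefined: a zero row or column", call. = FALSE)
  }
  corrected <- any(cells == 0)
  use <- if (corrected) cells + 0.5 else cells
  or <- (use[1] * use[4]) / (use[2] * use[3])
  se <- sqrt(sum(1 / use))
  z <- qnorm(1 - alpha / 2)
  structure(list(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    alpha = alpha,
    corrected = corrected,
    p_fisher = if (fisher) fisher_exact(cells) else NA_real_
  ), class = "or_result")
}

as_cells <- function(table) {
  if (inherits(table, "contingency_table")) {
    c(table$a, table$b, table$c, table$d)
  } else {
    stopifnot(length(table) == 4)
    as.numeric(table)
  }
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value sums the hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed the observed table's
#' (probability-mass definition of two-sidedness, with the customary
#' `1 + 1e-7` relative tolerance for ties).
#'
#' @param table a [contingency_table()] or length-4 vector `(a, b, c, d)`.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  cells <- as_cells(table)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p0 <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

#' Screen interest groups for association with schedule adherence
#'
#' For every group appearing in the profiles of labeled users, builds the
#' member/non-member x ASU/RSU table (oriented so OR > 1 means the group is
#' favoured by ASUs), computes the Woolf interval and Fisher p-value, and
#' retains groups whose confidence interval excludes 1. Denominators are the
#' labeled users with an available profile, since membership is only known
#' for them. No multiple-testing correction is applied by default, matching
#' the per-group confidence-level criterion; `adjust = "BH"` instead retains
#' groups with Benjamini-Hochberg-adjusted Fisher p below `alpha`.
#'
#' @param user_labels tibble from [user_schedule_labels()].
#' @param profiles the corpus `profiles` table.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble sorted by decreasing OR: `group`, the four counts,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_fisher`, `retained`.
#' @export
screen_groups <- function(user_labels, profiles, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  prof <- profiles[profiles$user_id %in% user_labels$user_id, ]
  labels <- setNames(user_labels$value, user_labels$user_id)
  n_members <- vapply(prof$groups, length, integer(1))
  membership <- tibble::tibble(
    user_id = rep(prof$user_id, n_members),
    group = unlist(prof$groups, use.names = FALSE)
  )
  user_leaning <- labels[prof$user_id]
  n_asu <- sum(user_leaning == "ASU")
  n_rsu <- sum(user_leaning == "RSU")
  if (nrow(membership) == 0 || n_asu == 0 || n_rsu == 0) {
    return(tibble::tibble(group = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), odds_ratio = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          p_fisher = numeric(), retained = logical()))
  }
  membership$leaning <- labels[membership$user_id]
  per_group <- membership |>
    dplyr::distinct(.data$user_id, .data$group, .keep_all = TRUE) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(a = sum(.data$leaning == "ASU"),
                     c = sum(.data$leaning == "RSU"), .groups = "drop")
  per_group <- per_group[per_group$a + per_group$c > 0, ]
  res <- lapply(seq_len(nrow(per_group)), function(i) {
    a <- per_group$a[i]; c <- per_group$c[i]
    b <- n_asu - a; d <- n_rsu - c
    or <- odds_ratio_ci(c(a, b, c, d), alpha = alpha)
    tibble::tibble(group = per_group$group[i], a = a, b = b, c = c, d = d,
                   odds_ratio = or$odds_ratio, ci_low = or$ci_low,
                   ci_high = or$ci_high, p_fisher = or$p_fisher)
  })
  out <- dplyr::bind_rows(res)
  out$retained <- if (adjust == "BH") {
    stats::p.adjust(out$p_fisher, method = "BH") < alpha
  } else {
    out$ci_low > 1 | out$ci_high < 1
  }
  dplyr::arrange(out, dplyr::desc(.data$odds_ratio))
}

#' Count URL domains cited in comments, split by author group
#'
#' URLs are located by pattern scan; each is reduced to its host, lower-cased,
#' with a leading `www.` stripped (the default `"host"` mode, which keeps
#' informative subdomains like `pediatrics.aappublications.org`). The
#' `"registrable"` mode further collapses to the registrable domain using a
#' compact second-level-suffix heuristic. A comment contributes at most once
#' per domain regardless of how many URLs of that domain it embeds.
#'
#' @param comments the corpus `comments` table.
#' @param user_labels optional tibble from [user_schedule_labels()]; when
#'   supplied, counts are split into RSU/ASU comment counts.
#' @param mode `"host"` (default) or `"registrable"`.
#' @return A tibble sorted by total count: `domain`, `n_comments` and, when
#'   labels are given, `n_comments_rsu` / `n_comments_asu`.
#' @export
extract_domains <- function(comments, user_labels = NULL,
                            mode = c("host", "registrable")) {
  mode <- match.arg(mode)
  rx <- "(?i)\\b(?:https?://|www\\.)[^[:space:]\"'<>)]+"
  hits <- regmatches(comments$text, gregexpr(rx, comments$text, perl = TRUE))
  per_comment <- lapply(hits, function(urls) {
    if (length(urls) == 0) return(character(0))
    unique(url_domain(urls, mode))
  })
  n_dom <- vapply(per_comment, length, integer(1))
  if (sum(n_dom) == 0) {
    return(tibble::tibble(domain = character(), n_comments = integer()))
  }
  long <- tibble::tibble(
    comment_id = rep(comments$comment_id, n_dom),
    user_id = rep(comments$user_id, n_dom),
    domain = unlist(per_comment, use.names = FALSE)
  )
  if (is.null(user_labels)) {
    out <- long |>
      dplyr::count(.data$domain, name = "n_comments")
  } else {
    labels <- setNames(user_labels$value, user_labels$user_id)
    long$leaning <- labels[long$user_id]
    out <- long |>
      dplyr::group_by(.data$domain) |>
      dplyr::summarise(
        n_comments = dplyr::n(),
        n_comments_rsu = sum(.data$leaning == "RSU", na.rm = TRUE),
        n_comments_asu = sum(.data$leaning == "ASU", na.rm = TRUE),
        .groups = "drop")
  }
  dplyr::arrange(out, dplyr::desc(.data$n_comments), .data$domain)
}

url_domain <- function(urls, mode = "host") {
  host <- sub("^(?i)https?://", "", urls, perl = TRUE)
  host <- sub("[/?#].*$", "", host)
  host <- sub(":[0-9]+$", "", host)
  host <- tolower(sub("^www\\.", "", host))
  host <- gsub("[.,;]+$", "", host)
  if (mode == "host") return(host)
  second_level <- c("co", "com", "net", "org", "gov", "edu", "ac")
  vapply(strsplit(host, ".", fixed = TRUE), function(parts) {
    np <- length(parts)
    if (np <= 2) return(paste(parts, collapse = "."))
    take <- if (nchar(parts[np]) == 2 && parts[np - 1] %in% second_level) 3 else 2
    paste(parts[(np - take + 1):np], collapse = ".")
  }, character(1))
}

#' Gazetteer of the 51 US states
#'
#' The 50 states plus the District of Columbia, with their two-letter
#' abbreviations, built from base R's `state.name` / `state.abb`.
#'
#' @return A 51-row tibble: `state`, `abb`.
#' @export
state_gazetteer <- function() {
  tibble::tibble(
    state = c(datasets::state.name, "District of Columbia"),
    abb = c(datasets::state.abb, "DC")
  )
}

#' Assign a US state to one user profile
#'
#' The self-reported location is resolved first (full state name anywhere in
#' the string, else a trailing two-letter abbreviation); the user's local
#' groups (group names containing a state name, e.g. "Texas Moms") serve as a
#' fallback. When both signals exist the self-report wins and `source` records
#' `"both"`.
#'
#' @param profile a one-row profile (list or data frame row) with
#'   `self_reported_location` and `groups`.
#' @param gazetteer a [state_gazetteer()].
#' @return A list: `user_id`, `state` (or `NA`), `source` (one of
#'   self_report / local_group / both, or `NA`).
#' @export
geolocate_user <- function(profile, gazetteer = state_gazetteer()) {
  loc <- profile$self_reported_location[[1]]
  groups <- unlist(profile$groups)
  from_loc <- NA_character_
  if (!is.null(loc) && !is.na(loc) && nzchar(loc)) {
    hit <- which(vapply(gazetteer$state, function(s)
      grepl(paste0("\\b", s, "\\b"), loc, ignore.case = TRUE), logical(1)))
    if (length(hit) > 0) {
      from_loc <- gazetteer$state[hit[1]]
    } else {
      abb <- regmatches(loc, regexpr("[A-Za-z]{2}\\.?$", loc))
      if (length(abb) > 0) {
        abb <- toupper(sub("\\.", "", abb))
        idx <- match(abb, gazetteer$abb)
        if (!is.na(idx)) from_loc <- gazetteer$state[idx]
      }
    }
  }
  from_group <- NA_character_
  if (length(groups) > 0) {
    for (s in gazetteer$state) {
      if (any(grepl(paste0("\\b", s, "\\b"), groups, ignore.case = TRUE))) {
        from_group <- s
        break
      }
    }
  }
  state <- if (!is.na(from_loc)) from_loc else from_group
  source <- if (!is.na(from_loc) && !is.na(from_group)) "both"
  else if (!is.na(from_loc)) "self_report"
  else if (!is.na(from_group)) "local_group"
  else NA_character_
  list(user_id = profile$user_id[[1]], state = state, source = source)
}

#' Assign states to all profiles
#'
#' @param profiles the corpus `profiles` table.
#' @param gazetteer a [state_gazetteer()].
#' @return Tibble: `user_id`, `state`, `source`.
#' @export
geolocate_users <- function(profiles, gazetteer = state_gazetteer()) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    g <- geolocate_user(profiles[i, ], gazetteer)
    tibble::tibble(user_id = g$user_id, state = g$state %||% NA_character_,
                   source = g$source %||% NA_character_)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' 2010 Census state population table
#'
#' The packaged 51-row table of US state resident populations (2010 Census),
#' used as the reference for [population_correlation()].
#'
#' @return Tibble: `state`, `abb`, `population`.
#' @export
state_population_table <- function() {
  path <- system.file("extdata", "state_population_2010.csv",
                      package = "vaxforum", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Pearson correlation of log user counts against log state populations
#'
#' States with zero mapped users are excluded (and reported) before taking
#' logs.
#'
#' @param state_counts named numeric vector (names are state names) of mapped
#'   users per state.
#' @param state_populations named numeric vector of state populations;
#'   defaults to the packaged 2010 Census table.
#' @return A list: `r`, `n_states`, `excluded` (states dropped for zero
#'   counts or missing population).
#' @export
population_correlation <- function(state_counts,
                                   state_populations = NULL) {
  if (is.null(state_populations)) {
    tab <- state_population_table()
    state_populations <- setNames(tab$population, tab$state)
  }
  common <- intersect(names(state_counts), names(state_populations))
  counts <- state_counts[common]
  pops <- state_populations[common]
  keep <- counts > 0 & pops > 0
  excluded <- c(setdiff(names(state_counts), common), common[!keep])
  counts <- counts[keep]; pops <- pops[keep]
  if (length(counts) < 3) stop("need at least 3 states with users", call. = FALSE)
  list(r = cor(log(counts), log(pops)), n_states = length(counts),
       excluded = excluded)
}

#' Filter precision and classifier sensitivity/specificity
#'
#' Evaluates the two-stage design against manual annotations: filter precision
#' is the fraction of retrieved comments annotated as task-relevant (label not
#' `unrelated`); classifier sensitivity and specificity are computed on the
#' retrieved, relevant comments with the stated positive class (`alternative`
#' for the schedule task, `negative_experience` for the AEFI task).
#'
#' @param predicted tibble `comment_id`, `label` — the pipeline's retrieved
#'   comments and labels.
#' @param annotations tibble `comment_id`, `label` — the human labels, one of
#'   the task's two class labels or `"unrelated"`; must cover all evaluated
#'   comments.
#' @param positive the positive class label.
#' @return A list of class `eval_metrics`: `precision`, `sensitivity`,
#'   `specificity`, `counts` (retrieved, relevant, tp, fp, tn, fn).
#' @export
evaluation_metrics <- function(predicted, annotations,
                               positive = "alternative") {
  if (nrow(annotations) == 0) stop("empty annotation set", call. = FALSE)
  ann <- setNames(annotations$label, annotations$comment_id)
  if (!all(predicted$comment_id %in% names(ann))) {
    stop("annotations must cover all evaluated comments", call. = FALSE)
  }
  truth <- ann[predicted$comment_id]
  retrieved <- nrow(predicted)
  relevant <- sum(truth != "unrelated")
  precision <- if (retrieved > 0) relevant / retrieved else NA_real_
  eval_idx <- truth != "unrelated"
  pred <- predicted$label[eval_idx]
  tr <- truth[eval_idx]
  tp <- sum(pred == positive & tr == positive)
  fp <- sum(pred == positive & tr != positive)
  fn <- sum(pred != positive & tr == positive)
  tn <- sum(pred != positive & tr != positive)
  structure(list(
    precision = precision,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    counts = c(retrieved = retrieved, relevant = relevant,
               tp = tp, fp = fp, tn = tn, fn = fn)
  ), class = "eval_metrics")
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with expected
#' agreement from the two annotators' marginal label frequencies.
#'
#' @param labels_a,labels_b equal-length label vectors over the same comments.
#' @return A list of class `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  levels_all <- sort(unique(c(labels_a, labels_b)))
  fa <- table(factor(labels_a, levels = levels_all)) / length(labels_a)
  fb <- table(factor(labels_b, levels = levels_all)) / length(labels_b)
  p_o <- mean(labels_a == labels_b)
  p_e <- sum(fa * fb)
  if (p_e >= 1) stop("kappa undefined: expected agreement is 1", call. = FALSE)
  structure(list(kappa = (p_o - p_e) / (1 - p_e),
                 observed_agreement = p_o,
                 expected_agreement = p_e),
            class = "kappa_result")
}
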