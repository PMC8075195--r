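#' Pipeline run configuration
#'
#' Either `synthetic` (a [synthetic_config()]) or `input_dir` (a directory
#' readable by [load_corpus()]) must be supplied. Stages run in dependency
#' order; later stages require the labels produced by earlier ones.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param synthetic optional [synthetic_config()]; enables the `simulate`
#'   stage.
#' @param input_dir optional corpus directory; used when `synthetic` is NULL.
#' @param lexicon a [schedule_lexicon()].
#' @param vocabulary a [reaction_vocabulary()].
#' @param stages subset of
#'   `c("simulate", "schedule", "aefi", "users", "associations", "network")`.
#' @param seed optional integer overriding the synthetic config's seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       synthetic = NULL,
                       input_dir = NULL,
                       lexicon = default_schedule_lexicon(),
                       vocabulary = default_reaction_vocabulary(),
                       stages = c("simulate", "schedule", "aefi", "users",
                                  "associations", "network"),
                       seed = NULL) {
  if (is.null(synthetic) && is.null(input_dir)) {
    stop("run_config needs either a synthetic config or an input corpus",
         call. = FALSE)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed) && !is.null(synthetic)) synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 input_dir = input_dir, lexicon = lexicon,
                 vocabulary = vocabulary, stages = stages),
            class = "run_config")
}

write_stage_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
    }
  }
  write.csv(df, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Chains simulate -> schedule extraction -> AEFI extraction -> user labeling
#' -> association screening -> interaction network, writing each stage's
#' artifact under `config$out_dir` and a `manifest.json` recording the
#' configuration hash, per-stage record counts and package version. Outputs
#' are pure functions of (inputs, config, seed): re-running an identical
#' config reproduces byte-identical files.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("vaxforum")),
    stages = list()
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if ("simulate" %in% config$stages && !is.null(config$synthetic)) {
    sim <- run_stage("simulate", generate_corpus(config$synthetic))
    corpus <- sim$corpus
    write_corpus(corpus, out)
    gt <- sim$ground_truth$comments
    write_jsonl(lapply(seq_len(nrow(gt)), function(i) list(
      comment_id = gt$comment_id[i], schedule_label = gt$schedule_label[i],
      hard = gt$hard[i], aefi_label = gt$aefi_label[i],
      subject = gt$subject[i], reaction = gt$reaction[i]
    )), file.path(out, "ground_truth.jsonl"))
    manifest$stages$simulate <- list(posts = nrow(corpus$posts),
                                     comments = nrow(corpus$comments),
                                     profiles = nrow(corpus$profiles))
  } else {
    corpus <- run_stage("load", load_corpus(config$input_dir))
    manifest$stages$load <- list(posts = nrow(corpus$posts),
                                 comments = nrow(corpus$comments),
                                 profiles = nrow(corpus$profiles))
  }

  schedule_labels <- NULL
  if ("schedule" %in% config$stages) {
    schedule_labels <- run_stage("schedule",
                                 run_schedule_pipeline(corpus, config$lexicon))
    write_jsonl(lapply(seq_len(nrow(schedule_labels)), function(i) list(
      comment_id = schedule_labels$comment_id[i],
      label = schedule_labels$label[i],
      pattern_id = schedule_labels$pattern_id[i],
      keyword = schedule_labels$keyword[i]
    )), file.path(out, "schedule_labels.jsonl"))
    manifest$stages$schedule <- list(labeled_comments = nrow(schedule_labels))
  }

  aefi_labels <- NULL
  if ("aefi" %in% config$stages) {
    aefi_labels <- run_stage("aefi",
                             run_aefi_pipeline(corpus, config$vocabulary))
    write_jsonl(lapply(seq_len(nrow(aefi_labels)), function(i) list(
      comment_id = aefi_labels$comment_id[i],
      label = aefi_labels$label[i],
      subject = aefi_labels$subject[i],
      reactions = I(aefi_labels$reactions[[i]])
    )), file.path(out, "aefi_labels.jsonl"))
    manifest$stages$aefi <- list(labeled_comments = nrow(aefi_labels))
  }

  user_labels <- NULL
  if ("users" %in% config$stages) {
    if (is.null(schedule_labels)) {
      stop("stage 'users' requires stage 'schedule'", call. = FALSE)
    }
    user_labels <- run_stage("users",
                             user_schedule_labels(schedule_labels,
                                                  corpus$comments))
    exp_labels <- if (!is.null(aefi_labels)) user_experience_labels(aefi_labels)
    else tibble::tibble(user_id = character(), value = character())
    merged <- dplyr::left_join(
      user_labels,
      dplyr::rename(exp_labels, experience_label = "value"),
      by = "user_id")
    act <- lapply(merged$user_id, function(u)
      compute_activity(corpus, u, schedule_labels))
    merged$n_posts <- vapply(act, function(a) a$n_posts, integer(1))
    merged$n_comments <- vapply(act, function(a) a$n_comments, integer(1))
    merged$tau <- vapply(act, function(a) a$tau, integer(1))
    write_stage_csv(merged, file.path(out, "user_labels.csv"))
    manifest$stages$users <- list(labeled_users = nrow(user_labels))
  }

  if ("associations" %in% config$stages) {
    if (is.null(user_labels)) {
      stop("stage 'associations' requires stage 'users'", call. = FALSE)
    }
    run_stage("associations", {
      gor <- screen_groups(user_labels, corpus$profiles)
      write_stage_csv(gor, file.path(out, "group_or.csv"))
      dom <- extract_domains(corpus$comments, user_labels)
      write_stage_csv(dom, file.path(out, "domain_counts.csv"))
      geo <- geolocate_users(corpus$profiles)
      labeled_geo <- geo[geo$user_id %in% user_labels$user_id & !is.na(geo$state), ]
      state_counts <- labeled_geo |>
        dplyr::count(.data$state, name = "n_users") |>
        dplyr::arrange(.data$state)
      write_stage_csv(state_counts, file.path(out, "state_counts.csv"))
      manifest$stages$associations <- list(
        groups_screened = nrow(gor),
        groups_retained = sum(gor$retained),
        domains = nrow(dom),
        states_mapped = nrow(state_counts))
    })
  }

  if ("network" %in% config$stages) {
    if (is.null(user_labels)) {
      stop("stage 'network' requires stage 'users'", call. = FALSE)
    }
    run_stage("network", {
      graph <- build_graph(corpus, user_labels)
      write_stage_csv(graph$edges, file.path(out, "edge_list.csv"))
      ls <- leaning_summary(graph)
      write_stage_csv(ls, file.path(out, "leaning_summary.csv"))
      for (grp in intersect(c("RSU", "ASU"), user_labels$value)) {
        jd <- tryCatch(joint_distribution(graph, grp), error = function(e) NULL)
        if (!is.null(jd)) {
          write_stage_csv(as.data.frame(jd$mass),
                          file.path(out, sprintf("joint_leaning_%s.csv",
                                                 tolower(grp))))
        }
      }
      manifest$stages$network <- list(nodes = nrow(graph$nodes),
                                       edges = nrow(graph$edges),
                                       total_weight = sum(graph$edges$weight))
    })
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
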