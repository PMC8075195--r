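#' Build the directed weighted commenter-to-author interaction graph
#'
#' Nodes are the schedule-labeled users; there is an edge i -> j with weight
#' w_ij when labeled user i wrote w_ij comments under posts authored by
#' labeled user j. Commenting on one's own post is not an inter-user
#' interaction, so self-loops are excluded. The sum of edge weights equals the
#' number of qualifying comment events.
#'
#' @param corpus a [forum_corpus()].
#' @param user_labels tibble from [user_schedule_labels()] (`user_id`,
#'   `value`).
#' @return An object of class `interaction_graph`: `graph` (an
#'   \pkg{igraph} directed graph with vertex attribute `leaning`, +1 for RSU
#'   and -1 for ASU), `edges` (tibble `source`, `target`, `weight`) and
#'   `nodes` (tibble `user_id`, `leaning`).
#' @export
build_graph <- function(corpus, user_labels) {
  if (nrow(user_labels) < 2) stop("need labels for at least 2 users", call. = FALSE)
  leaning <- setNames(ifelse(user_labels$value == "RSU", 1, -1),
                      user_labels$user_id)
  authors <- setNames(corpus$posts$user_id, corpus$posts$post_id)
  cm <- corpus$comments
  target <- authors[cm$post_id]
  keep <- cm$user_id %in% names(leaning) & target %in% names(leaning) &
    cm$user_id != target & !is.na(target)
  edges <- tibble::tibble(source = cm$user_id[keep],
                          target = unname(target[keep])) |>
    dplyr::count(.data$source, .data$target, name = "weight") |>
    dplyr::arrange(.data$source, .data$target)
  nodes <- tibble::tibble(user_id = user_labels$user_id,
                          leaning = unname(leaning[user_labels$user_id]))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(graph = g, edges = edges, nodes = nodes),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges, total weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Weighted mean leaning of a user's neighbors
#'
#' In-neighbors of u are the users who comment on u's posts (sources of edges
#' into u); out-neighbors are the authors u comments on. The mean is weighted
#' by edge weight and is invariant to uniform rescaling of all weights.
#'
#' @param graph an [build_graph()] result.
#' @param user a user id present in the graph.
#' @param direction `"in"` or `"out"`.
#' @return A value in \[-1, 1\], or `NA` when the user has no edges in that
#'   direction (undefined).
#' @export
neighbor_leaning <- function(graph, user, direction = c("in", "out")) {
  direction <- match.arg(direction)
  if (!user %in% graph$nodes$user_id) {
    stop(sprintf("unknown user: %s", user), call. = FALSE)
  }
  leaning <- setNames(graph$nodes$leaning, graph$nodes$user_id)
  e <- graph$edges
  if (direction == "in") {
    e <- e[e$target == user, ]
    neigh <- e$source
  } else {
    e <- e[e$source == user, ]
    neigh <- e$target
  }
  if (nrow(e) == 0) return(NA_real_)
  sum(leaning[neigh] * e$weight) / sum(e$weight)
}

#' Neighbor-leaning summary for every node
#'
#' @param graph an [build_graph()] result.
#' @return Tibble: `user_id`, `leaning`, `in_avg`, `out_avg` (NA when
#'   undefined).
#' @export
leaning_summary <- function(graph) {
  leaning <- setNames(graph$nodes$leaning, graph$nodes$user_id)
  e <- graph$edges
  in_avg <- e |>
    dplyr::mutate(src_leaning = leaning[.data$source]) |>
    dplyr::group_by(user_id = .data$target) |>
    dplyr::summarise(in_avg = sum(.data$src_leaning * .data$weight) /
                       sum(.data$weight), .groups = "drop")
  out_avg <- e |>
    dplyr::mutate(tgt_leaning = leaning[.data$target]) |>
    dplyr::group_by(user_id = .data$source) |>
    dplyr::summarise(out_avg = sum(.data$tgt_leaning * .data$weight) /
                       sum(.data$weight), .groups = "drop")
  graph$nodes |>
    dplyr::left_join(in_avg, by = "user_id") |>
    dplyr::left_join(out_avg, by = "user_id")
}

#' Joint distribution of in/out neighbor leanings for one group
#'
#' Normalized 2D histogram of (in_avg, out_avg) over the group's users having
#' both averages defined; users with an undefined side cannot be placed and
#' are excluded (their number is returned). An echo chamber concentrates mass
#' in the (+1, +1) corner for RSUs and the (-1, -1) corner for ASUs.
#'
#' @param graph an [build_graph()] result.
#' @param group `"RSU"` or `"ASU"`.
#' @param bins number of bins per axis (default 21, odd so that 0 is a bin
#'   center).
#' @return A list of class `joint_leaning_distribution`: `group`, `breaks`
#'   (bin edges over \[-1, 1\]), `mass` (bins x bins matrix summing to 1,
#'   rows = in_avg, columns = out_avg), `n` (users placed), `n_excluded`.
#' @export
joint_distribution <- function(graph, group = c("RSU", "ASU"), bins = 21) {
  group <- match.arg(group)
  if (bins < 2) stop("need at least 2 bins per axis", call. = FALSE)
  want <- if (group == "RSU") 1 else -1
  ls <- leaning_summary(graph)
  ls <- ls[ls$leaning == want, ]
  ok <- !is.na(ls$in_avg) & !is.na(ls$out_avg)
  n_excluded <- sum(!ok)
  ls <- ls[ok, ]
  if (nrow(ls) == 0) {
    stop(sprintf("no %s user has both neighbor averages defined", group),
         call. = FALSE)
  }
  breaks <- seq(-1, 1, length.out = bins + 1)
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks, all.inside = TRUE),
                                  1L), bins)
  mass <- matrix(0, nrow = bins, ncol = bins)
  bi <- bin_of(ls$in_avg)
  bo <- bin_of(ls$out_avg)
  for (i in seq_along(bi)) mass[bi[i], bo[i]] <- mass[bi[i], bo[i]] + 1
  mass <- mass / sum(mass)
  structure(list(group = group, breaks = breaks, mass = mass,
                 n = nrow(ls), n_excluded = n_excluded),
            class = "joint_leaning_distribution")
}

#' Mass in the own-group corner of a joint leaning distribution
#'
#' Convenience accessor for the echo-chamber diagnostic: the probability mass
#' in the bin containing (-1, -1) for ASUs or (+1, +1) for RSUs.
#'
#' @param jd a [joint_distribution()] result.
#' @return A single probability.
#' @export
corner_mass <- function(jd) {
  bins <- nrow(jd$mass)
  if (jd$group == "ASU") jd$mass[1, 1] else jd$mass[bins, bins]
}
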