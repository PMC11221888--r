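#' Top-scoring fraction of edges for one perturbed sample
#'
#' Returns the ceiling(fraction * WG) edges with the largest differential
#' scores. Ties at the cutoff value are all included, which makes the result
#' deterministic and independent of storage order (the set can therefore be
#' slightly larger than the nominal count).
#'
#' @param result a `niee_result` from [score_sample()].
#' @param fraction real in (0, 1\]; the default 0.01 keeps the top 1%.
#' @return tibble `gene1`, `gene2`, `delta`, in lexicographic edge order.
#' @export
top_fraction_edges <- function(result, fraction = 0.01) {
  stopifnot(inherits(result, "niee_result"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop_niee("`fraction` must be a single number in (0, 1]")
  }
  if (nrow(result) == 0) stop_niee("result has no edges")
  k <- ceiling(fraction * nrow(result))
  cutoff <- sort(result$delta, decreasing = TRUE)[k]
  out <- as_tibble(result)[result$delta >= cutoff,
                           c("gene1", "gene2", "delta")]
  class(out) <- class(tibble())
  arrange(out, .data$gene1, .data$gene2)
}

#' Screen the key local network by occurrence frequency
#'
#' Pools the per-sample top-fraction edge sets and keeps the edges that occur
#' in at least `min_frequency` of them. The surviving edge set — the key
#' local network — is the method's candidate dynamic network biomarker.
#'
#' @param top_sets list of per-sample edge sets, as returned by
#'   [top_fraction_edges()] (or character vectors of `"a--b"` keys).
#' @param min_frequency minimum number of sets an edge must appear in;
#'   defaults to half the number of sets, rounded up.
#' @param top_fraction optional; recorded in the result's parameters.
#' @return a `key_local_network`: tibble `gene1`, `gene2`, `frequency` in
#'   lexicographic edge order, with a `params` attribute.
#' @export
select_key_network <- function(top_sets, min_frequency = NULL,
                               top_fraction = NA_real_) {
  if (!is.list(top_sets) || length(top_sets) == 0) {
    stop_niee("`top_sets` must be a nonempty list of edge sets")
  }
  n_sets <- length(top_sets)
  if (is.null(min_frequency)) min_frequency <- ceiling(n_sets / 2)
  if (min_frequency < 1 || min_frequency != round(min_frequency)) {
    stop_niee("`min_frequency` must be a positive integer")
  }
  if (min_frequency > n_sets) {
    stop_niee(sprintf(
      "`min_frequency` (%d) exceeds the number of edge sets (%d)",
      min_frequency, n_sets
    ))
  }
  keys_per_set <- lapply(top_sets, function(s) unique(as_edge_keys(s)))
  counts <- table(unlist(keys_per_set, use.names = FALSE))
  keep <- names(counts)[counts >= min_frequency]
  pairs <- split_edge_key(sort(keep))
  out <- tibble(
    gene1 = pairs$gene1, gene2 = pairs$gene2,
    frequency = as.integer(counts[sort(keep)])
  )
  out <- arrange(out, .data$gene1, .data$gene2)
  structure(
    out,
    params = list(top_fraction = top_fraction,
                  min_frequency = as.integer(min_frequency),
                  n_sets = n_sets),
    class = c("key_local_network", class(tibble()))
  )
}

#' @export
print.key_local_network <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<key_local_network> %d edges (min frequency %d of %d sample sets)\n",
    nrow(x), p$min_frequency, p$n_sets
  ))
  NextMethod()
}

# per-result summary score used by both trajectory builders
result_score <- function(result, key, reduction) {
  if (is.null(key)) {
    local_score(result, edge_key(result$gene1, result$gene2),
                reduction = reduction)
  } else {
    local_score(result, key, reduction = reduction)
  }
}

check_same_universe <- function(results) {
  keys <- lapply(results, function(r) edge_key(r$gene1, r$gene2))
  if (length(unique(lapply(keys, sort))) != 1) {
    stop_niee("results do not share the same edge universe")
  }
  invisible(results)
}

#' Score trajectory over an ordered series of perturbed samples
#'
#' Computes the per-sample summary score — the key-local score over
#' `key` when one is given, otherwise the global score over all edges — in
#' the order the results are supplied (time points, stages, ...).
#'
#' @param results list of `niee_result` objects in label order.
#' @param key a `key_local_network` (or any edge subset accepted by
#'   [local_score()]); `NULL` scores over all edges.
#' @param reduction `"mean"` (default) or `"sum"` aggregation of edge scores.
#' @return a `niee_trajectory`: tibble `label`, `score`.
#' @export
niee_trajectory <- function(results, key = NULL, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  stopifnot(is.list(results), length(results) >= 1)
  lapply(results, function(r) stopifnot(inherits(r, "niee_result")))
  check_same_universe(results)
  labels <- vapply(results, function(r) attr(r, "sample"), character(1))
  if (anyDuplicated(labels)) {
    stop_niee(sprintf("duplicate sample labels in trajectory: %s",
                      paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  scores <- vapply(results, result_score, numeric(1),
                   key = key, reduction = reduction)
  new_trajectory(tibble(label = labels, score = scores))
}

new_trajectory <- function(tbl) {
  structure(tbl, class = c("niee_trajectory", class(tibble())))
}

#' Per-group mean score trajectory
#'
#' Averages per-sample summary scores within groups (e.g. tumor stages), in
#' an explicitly supplied group order.
#'
#' @param results list of `niee_result` objects.
#' @param groups named character vector mapping sample label to group label,
#'   or a data frame with columns `sample` and `group`.
#' @param group_order character vector fixing the output order; defaults to
#'   order of first appearance in `groups`.
#' @inheritParams niee_trajectory
#' @return a `niee_trajectory`: tibble `label` (group), `score` (group mean),
#'   `n_samples`.
#' @export
grouped_trajectory <- function(results, groups, group_order = NULL,
                               key = NULL, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  labels <- vapply(results, function(r) attr(r, "sample"), character(1))
  unassigned <- setdiff(labels, names(groups))
  if (length(unassigned)) {
    stop_niee(sprintf("samples without a group assignment: %s",
                      paste(unassigned, collapse = ", ")))
  }
  check_same_universe(results)
  scores <- vapply(results, result_score, numeric(1),
                   key = key, reduction = reduction)
  grp <- unname(groups[labels])
  if (is.null(group_order)) group_order <- unique(unname(groups))
  unknown <- setdiff(grp, group_order)
  if (length(unknown)) {
    stop_niee(sprintf("groups missing from `group_order`: %s",
                      paste(unique(unknown), collapse = ", ")))
  }
  agg <- tibble(group = grp, score = scores) |>
    group_by(.data$group) |>
    summarise(score = mean(.data$score), n_samples = dplyr::n(),
              .groups = "drop")
  agg <- agg[match(intersect(group_order, agg$group), agg$group), ]
  new_trajectory(tibble(label = agg$group, score = agg$score,
                        n_samples = agg$n_samples))
}

#' Flag early-warning signals on a score trajectory
#'
#' A sharply increasing score denotes an approaching tipping point. This
#' detector is a running-baseline convention (the underlying method states no
#' quantitative criterion): position t is flagged when its score exceeds the
#' mean of all earlier scores by more than k running standard deviations,
#' provided at least `min_history` earlier points exist. Flags are causal —
#' they only use scores at or before each position.
#'
#' @param traj a `niee_trajectory`.
#' @param k number of running standard deviations (default 2).
#' @param min_history minimum number of earlier points before flagging is
#'   allowed (default 3).
#' @return the trajectory with a logical `flag` column and attribute
#'   `first_signal` (label of the first flagged position, or `NA`).
#' @export
detect_signals <- function(traj, k = 2, min_history = 3) {
  stopifnot(inherits(traj, "niee_trajectory"))
  if (k <= 0) stop_niee("`k` must be positive")
  if (min_history < 1 || min_history != round(min_history)) {
    stop_niee("`min_history` must be a positive integer")
  }
  n <- nrow(traj)
  if (n < min_history + 1) {
    stop_niee(sprintf(
      "trajectory has %d points; need at least min_history + 1 = %d",
      n, min_history + 1
    ))
  }
  v <- traj$score
  flag <- logical(n)
  for (t in seq_len(n)) {
    if (t <= min_history) next
    hist <- v[seq_len(t - 1)]
    s <- stats::sd(hist)
    flag[t] <- v[t] > mean(hist) + k * s
  }
  out <- new_trajectory(tibble(!!!as_tibble(traj), flag = flag))
  attr(out, "first_signal") <-
    if (any(flag)) traj$label[which(flag)[1]] else NA_character_
  out
}

#' @export
print.niee_trajectory <- function(x, ...) {
  fs <- attr(x, "first_signal")
  cat(sprintf("<niee_trajectory> %d points%s\n", nrow(x),
              if (!is.null(fs)) sprintf(", first signal: %s", fs) else ""))
  NextMethod()
}

#' @exportS3Method ggplot2::autoplot
autoplot.niee_trajectory <- function(object, ...) {
  df <- as_tibble(object)
  class(df) <- class(tibble())
  df$position <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$position, labels = df$label) +
    ggplot2::labs(x = "sample", y = "differential score")
  if ("flag" %in% names(df) && any(df$flag)) {
    p <- p + ggplot2::geom_point(
      data = df[df$flag, ], color = "red", size = 3, shape = 17
    )
  }
  p
}

#' Landscape matrix of key-network edge scores over samples
#'
#' The edges-by-samples matrix of differential scores for the key local
#' network, the table behind 3D landscape plots: rows are key edges
#' (lexicographic), columns sample labels (input order).
#'
#' @param results list of `niee_result` objects in label order.
#' @param key a `key_local_network` (or edge subset).
#' @return numeric matrix (possibly 0-row, with a warning, when `key` is
#'   empty) with edge keys as rownames and sample labels as colnames.
#' @export
landscape_matrix <- function(results, key) {
  stopifnot(is.list(results), length(results) >= 1)
  check_same_universe(results)
  labels <- vapply(results, function(r) attr(r, "sample"), character(1))
  keys <- sort(as_edge_keys(key))
  if (length(keys) == 0) {
    rlang::warn("key network is empty; returning a 0-row landscape matrix")
    return(matrix(numeric(0), nrow = 0, ncol = length(labels),
                  dimnames = list(NULL, labels)))
  }
  cols <- vapply(results, function(r) {
    all_keys <- edge_key(r$gene1, r$gene2)
    unknown <- setdiff(keys, all_keys)
    if (length(unknown)) {
      stop_niee(sprintf("key edges absent from scored network: %s",
                        paste(utils::head(unknown, 5), collapse = ", ")))
    }
    r$delta[match(keys, all_keys)]
  }, numeric(length(keys)))
  m <- matrix(cols, nrow = length(keys),
              dimnames = list(keys, labels))
  m
}

#' Plot a landscape matrix as a heat map
#'
#' @param landscape matrix from [landscape_matrix()].
#' @return a ggplot object (tile heat map, edges on the y axis).
#' @export
plot_landscape <- function(landscape) {
  df <- as.data.frame.table(landscape, responseName = "delta",
                            stringsAsFactors = FALSE)
  names(df)[1:2] <- c("edge", "sample")
  df$sample <- factor(df$sample, levels = colnames(landscape))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$edge,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "sample", y = "edge", fill = "score")
}

#' Graph induced by the key edges alone
#'
#' The key local network's edges typically assemble spontaneously into small
#' connected sub-networks; isolated edges are legitimate and kept. No pruning
#' is applied.
#'
#' @param key a nonempty `key_local_network`.
#' @return a [background_network()] containing exactly the key edges
#'   (confidence `NA`).
#' @export
self_forming_subgraph <- function(key) {
  if (nrow(key) == 0) stop_niee("key network is empty")
  background_network(tibble(
    gene1 = key$gene1, gene2 = key$gene2, confidence = NA_real_
  ))
}

#' Write tabular results
#'
#' `write_key_network()` writes `gene1`, `gene2`, `frequency`;
#' `write_trajectory()` writes `label`, `score` (and `flag` if present);
#' `write_landscape()` writes the landscape matrix with an `edge` key column.
#'
#' @param key,traj,landscape the object to write.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_key_network <- function(key, path) {
  readr::write_tsv(as_tibble(key), path)
  invisible(path)
}

#' @rdname write_key_network
#' @export
write_trajectory <- function(traj, path) {
  df <- as_tibble(traj)
  class(df) <- class(tibble())
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_key_network
#' @export
write_landscape <- function(landscape, path) {
  df <- data.frame(edge = rownames(landscape), landscape,
                   check.names = FALSE, stringsAsFactors = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}
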