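#' Pearson correlation with a zero-variance convention
#'
#' Standard Pearson correlation over paired samples. When either vector is
#' constant the correlation is formally 0/0; a constant gene carries no
#' co-fluctuation signal, so the value is defined as 0. This keeps the
#' neighbor-weight normalization well defined for constant genes.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return a number in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop_niee("pcc: vectors must have equal length")
  if (length(x) < 3) stop_niee("pcc: need at least 3 paired samples")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Correlation-derived neighbor weight distribution of a node
#'
#' For a gene with M first-order neighbors, the weight of each neighbor is
#' its absolute Pearson correlation with the gene, normalized to sum to 1.
#' If every correlation is exactly 0 (no co-fluctuation information at all)
#' the uniform distribution 1/M is returned — the maximum-uncertainty state,
#' continuous with near-zero-correlation inputs.
#'
#' @param gene gene identifier (a row of `expr`).
#' @param neighbors character vector of neighbor identifiers, length M >= 2.
#' @param expr genes-by-samples numeric matrix with >= 3 samples.
#' @return named numeric vector of length M, entries >= 0, summing to 1.
#' @export
neighbor_weights <- function(gene, neighbors, expr) {
  if (length(neighbors) < 2) {
    stop_niee("neighbor_weights: need at least 2 neighbors (M >= 2)")
  }
  if (ncol(expr) < 3) stop_niee("neighbor_weights: need at least 3 samples")
  absent <- setdiff(c(gene, neighbors), rownames(expr))
  if (length(absent)) {
    stop_niee(sprintf("genes absent from expression matrix: %s",
                      paste(absent, collapse = ", ")))
  }
  x <- expr[gene, ]
  a <- vapply(neighbors, function(nb) abs(pcc(x, expr[nb, ])), numeric(1))
  s <- sum(a)
  if (s == 0) {
    w <- rep(1 / length(a), length(a))
    names(w) <- neighbors
    w
  } else {
    a / s
  }
}

#' Normalized Shannon entropy of a weight distribution
#'
#' Entropy of the M neighbor weights divided by log(M), so the value lies in
#' \[0, 1\]: 1 for the uniform distribution, 0 for a one-hot distribution
#' (with the 0 log 0 := 0 convention). The normalization cancels the choice
#' of logarithm base.
#'
#' @param weights nonnegative numeric vector of length M >= 2 summing to 1
#'   (tolerance 1e-9).
#' @param base logarithm base (irrelevant to the result; exposed to make the
#'   base-independence testable).
#' @return a number in \[0, 1\].
#' @export
node_entropy <- function(weights, base = exp(1)) {
  m <- length(weights)
  if (m < 2) stop_niee("node_entropy: need M >= 2 weights")
  if (any(weights < 0)) stop_niee("node_entropy: weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_niee("node_entropy: weights must sum to 1 (tolerance 1e-9)")
  }
  p <- weights[weights > 0]
  -sum(p * log(p, base = base)) / log(m, base = base)
}

#' Sample standard deviation of a gene across samples
#'
#' @param gene gene identifier (a row of `expr`).
#' @param expr genes-by-samples numeric matrix with >= 2 samples.
#' @return nonnegative number (divisor s - 1).
#' @export
node_sd <- function(gene, expr) {
  if (!gene %in% rownames(expr)) {
    stop_niee(sprintf("gene '%s' absent from expression matrix", gene))
  }
  if (ncol(expr) < 2) stop_niee("node_sd: need at least 2 samples")
  stats::sd(expr[gene, ])
}

#' Edge context: endpoints, degrees and neighbor sets of one edge
#'
#' Collects everything a single edge's entropy needs: the two member genes,
#' their degrees in the analysis graph (the node weights alpha and beta), and
#' their first-order neighbor lists (of lengths M1 and M2). Degrees and
#' neighbor sets always come from the same pruned, expression-aligned graph,
#' so the reference and perturbed computations share them.
#'
#' @param net a [background_network()].
#' @param gene1,gene2 the edge's member genes; the edge must exist in `net`.
#' @return an object of class `edge_context`.
#' @export
edge_context <- function(net, gene1, gene2) {
  stopifnot(inherits(net, "background_network"))
  key <- edge_key(gene1, gene2)
  if (!key %in% edge_key(net$edges$gene1, net$edges$gene2)) {
    stop_niee(sprintf("edge %s is not in the network", key))
  }
  n1 <- network_neighbors(net, gene1)
  n2 <- network_neighbors(net, gene2)
  structure(
    list(
      gene1 = gene1, gene2 = gene2,
      alpha = as.integer(net$degree[[gene1]]),
      beta = as.integer(net$degree[[gene2]]),
      neighbors1 = n1, neighbors2 = n2,
      M1 = length(n1), M2 = length(n2)
    ),
    class = "edge_context"
  )
}

# degree-weighted convex combination shared by edge entropy and edge SD
edge_combine <- function(ctx, v1, v2) {
  (ctx$alpha * v1 + ctx$beta * v2) / (ctx$alpha + ctx$beta)
}

#' Local edge entropy
#'
#' The entropy of an edge is the degree-weighted convex combination of its
#' two member genes' normalized neighbor-weight entropies:
#' alpha/(alpha+beta) * H(g1) + beta/(alpha+beta) * H(g2). Evaluated on the
#' reference cohort it gives the reference edge entropy; on the cohort with
#' the perturbed sample appended it gives the perturbed edge entropy.
#'
#' @param ctx an [edge_context()].
#' @param expr genes-by-samples matrix covering both genes and all their
#'   neighbors, >= 3 samples.
#' @return a number in \[0, 1\].
#' @export
edge_entropy <- function(ctx, expr) {
  stopifnot(inherits(ctx, "edge_context"))
  h1 <- node_entropy(neighbor_weights(ctx$gene1, ctx$neighbors1, expr))
  h2 <- node_entropy(neighbor_weights(ctx$gene2, ctx$neighbors2, expr))
  edge_combine(ctx, h1, h2)
}

#' Local edge standard deviation
#'
#' Degree-weighted convex combination of the two member genes' sample
#' standard deviations, mirroring [edge_entropy()].
#'
#' @inheritParams edge_entropy
#' @return nonnegative number.
#' @export
edge_sd <- function(ctx, expr) {
  stopifnot(inherits(ctx, "edge_context"))
  edge_combine(ctx, node_sd(ctx$gene1, expr), node_sd(ctx$gene2, expr))
}

#' Differential score of one edge for one perturbed sample
#'
#' Evaluates the edge entropy and edge SD on the reference cohort and on the
#' (s+1)-sample set with the perturbed sample appended, and returns their
#' product of absolute differences:
#' delta = |SD(s+1) - SD(s)| * |H(s+1) - H(s)|.
#'
#' @param ctx an [edge_context()].
#' @param reference genes-by-samples matrix, >= 3 samples.
#' @param perturbed named numeric vector covering the reference genes.
#' @return one-row tibble: `gene1`, `gene2`, `h_ref`, `sd_ref`, `h_pert`,
#'   `sd_pert`, `delta`.
#' @export
differential_edge_score <- function(ctx, reference, perturbed) {
  check_reference_size(ncol(reference))
  full <- build_sample_set(reference, perturbed)
  h_ref <- edge_entropy(ctx, reference)
  sd_ref <- edge_sd(ctx, reference)
  h_pert <- edge_entropy(ctx, full)
  sd_pert <- edge_sd(ctx, full)
  tibble(
    gene1 = ctx$gene1, gene2 = ctx$gene2,
    h_ref = h_ref, sd_ref = sd_ref,
    h_pert = h_pert, sd_pert = sd_pert,
    delta = abs(sd_pert - sd_ref) * abs(h_pert - h_ref)
  )
}

# vectorized per-edge Pearson correlations and per-node entropy/SD on one
# sample set; nodes' neighbor weights reuse the per-edge correlations because
# every (gene, neighbor) pair is an edge of the analysis graph
node_stats <- function(net, expr) {
  x <- expr[net$nodes, , drop = FALSE]
  n <- ncol(x)
  xc <- x - rowMeans(x)
  ss <- sqrt(rowSums(xc^2))
  i <- match(net$edges$gene1, net$nodes)
  j <- match(net$edges$gene2, net$nodes)
  num <- rowSums(xc[i, , drop = FALSE] * xc[j, , drop = FALSE])
  den <- ss[i] * ss[j]
  r <- ifelse(den > 0, num / den, 0)
  r <- pmax(-1, pmin(1, r))
  # incidence: edge indices touching each node (each edge appears once per end)
  ends <- factor(c(net$edges$gene1, net$edges$gene2), levels = net$nodes)
  incident <- split(rep(seq_len(nrow(net$edges)), 2L), ends)
  absr <- abs(r)
  entropy <- vapply(incident, function(idx) {
    a <- absr[idx]
    m <- length(a)
    s <- sum(a)
    w <- if (s == 0) rep(1 / m, m) else a / s
    w <- w[w > 0]
    -sum(w * log(w)) / log(m)
  }, numeric(1))
  list(entropy = entropy, sd = ss / sqrt(n - 1))
}

#' Score one perturbed sample over every edge of the network
#'
#' Computes, for every edge of the aligned analysis graph, the reference and
#' perturbed edge entropies and standard deviations and their differential
#' score, plus the global score (the mean differential score over all edges).
#' The expression matrix must cover every network node; use
#' [align_to_network()] first. Edges are reported in lexicographic order so
#' aggregation is bit-reproducible.
#'
#' @param net a [background_network()] whose every node has degree >= 2
#'   (see [prune_leaves()]).
#' @param reference genes-by-samples matrix, >= 3 samples.
#' @param perturbed named numeric vector covering the network nodes.
#' @param label sample label recorded in the result.
#' @return a `niee_result`: a tibble with one row per edge (`gene1`, `gene2`,
#'   `h_ref`, `sd_ref`, `h_pert`, `sd_pert`, `delta`) and attributes `sample`,
#'   `global_score`, `n_edges`.
#' @export
score_sample <- function(net, reference, perturbed, label = "perturbed") {
  stopifnot(inherits(net, "background_network"), is.matrix(reference))
  if (n_edges(net) == 0) stop_niee("network has no edges to score")
  if (any(net$degree < 2)) {
    stop_niee("network has degree-1 nodes; apply prune_leaves() first")
  }
  missing_g <- setdiff(net$nodes, rownames(reference))
  if (length(missing_g)) {
    stop_niee(sprintf("reference matrix lacks network genes: %s",
                      paste(utils::head(missing_g, 5), collapse = ", ")))
  }
  check_reference_size(ncol(reference))
  ref <- reference[net$nodes, , drop = FALSE]
  full <- build_sample_set(ref, perturbed[net$nodes], label = label)
  st_ref <- node_stats(net, ref)
  st_pert <- node_stats(net, full)
  g1 <- net$edges$gene1
  g2 <- net$edges$gene2
  a <- net$degree[g1]
  b <- net$degree[g2]
  wa <- a / (a + b)
  wb <- b / (a + b)
  h_ref <- wa * st_ref$entropy[g1] + wb * st_ref$entropy[g2]
  sd_ref <- wa * st_ref$sd[g1] + wb * st_ref$sd[g2]
  h_pert <- wa * st_pert$entropy[g1] + wb * st_pert$entropy[g2]
  sd_pert <- wa * st_pert$sd[g1] + wb * st_pert$sd[g2]
  records <- tibble(
    gene1 = g1, gene2 = g2,
    h_ref = unname(h_ref), sd_ref = unname(sd_ref),
    h_pert = unname(h_pert), sd_pert = unname(sd_pert),
    delta = unname(abs(sd_pert - sd_ref) * abs(h_pert - h_ref))
  )
  new_niee_result(records, sample = label)
}

new_niee_result <- function(records, sample) {
  structure(
    records,
    sample = sample,
    global_score = mean(records$delta),
    n_edges = nrow(records),
    class = c("niee_result", class(tibble()))
  )
}

#' @export
print.niee_result <- function(x, ...) {
  cat(sprintf("<niee_result> sample '%s': %d edges, global score %.6g\n",
              attr(x, "sample"), attr(x, "n_edges"), attr(x, "global_score")))
  NextMethod()
}

#' Global differential score of a scored sample
#'
#' @param result a `niee_result` from [score_sample()].
#' @return the mean differential score over all edges.
#' @export
global_score <- function(result) {
  stopifnot(inherits(result, "niee_result"))
  attr(result, "global_score")
}

#' Local (key-network) differential score
#'
#' Aggregates the differential scores of an edge subset, by default the mean
#' over the WL subset edges; `reduction = "sum"` gives the summed variant,
#' which differs only by the constant factor WL and induces the same ranking
#' of samples for a fixed key network.
#'
#' @param result a `niee_result`.
#' @param edges the subset: a `key_local_network`, any data frame with
#'   `gene1`/`gene2` columns, or a character vector of `"a--b"` keys.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return nonnegative number.
#' @export
local_score <- function(result, edges, reduction = c("mean", "sum")) {
  stopifnot(inherits(result, "niee_result"))
  reduction <- match.arg(reduction)
  keys <- as_edge_keys(edges)
  if (length(keys) == 0) stop_niee("local_score: empty edge subset")
  all_keys <- edge_key(result$gene1, result$gene2)
  unknown <- setdiff(keys, all_keys)
  if (length(unknown)) {
    stop_niee(sprintf("edges not present in the scored network: %s",
                      paste(utils::head(unknown, 5), collapse = ", ")))
  }
  d <- result$delta[match(keys, all_keys)]
  if (reduction == "mean") mean(d) else sum(d)
}

#' @exportS3Method generics::tidy
tidy.niee_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  attr(out, "sample") <- NULL
  attr(out, "global_score") <- NULL
  attr(out, "n_edges") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.niee_result <- function(x, ...) {
  tibble(
    sample = attr(x, "sample"),
    n_edges = attr(x, "n_edges"),
    global_score = attr(x, "global_score")
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.niee_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::labs(
      x = "differential edge score",
      y = "edges",
      title = sprintf("Sample '%s' (global score %.4g)",
                      attr(object, "sample"), attr(object, "global_score"))
    )
}

#' Write / read a scored sample
#'
#' The edge table goes to `path` as TSV; the sample label, global score and
#' edge count go to a one-line JSON sidecar at `paste0(path, ".json")`.
#'
#' @param result a `niee_result`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_niee_result <- function(result, path) {
  stopifnot(inherits(result, "niee_result"))
  readr::write_tsv(tidy(result), path)
  jsonlite::write_json(
    list(
      sample = attr(result, "sample"),
      global_score = attr(result, "global_score"),
      n_edges = attr(result, "n_edges")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_niee_result
#' @export
read_niee_result <- function(path) {
  records <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = "ccddddd")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  out <- new_niee_result(records, sample = meta$sample)
  stopifnot(abs(attr(out, "global_score") - meta$global_score) < 1e-8)
  out
}
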