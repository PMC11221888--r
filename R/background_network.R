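#' Construct a background network from an edge table
#'
#' Builds the undirected gene-interaction graph that all entropy computations
#' consume. Edges are stored canonically (lexicographically smaller gene
#' first) and sorted, so downstream summation order is reproducible.
#'
#' @param edges a data frame with columns `gene1`, `gene2` and optionally
#'   `confidence` (real in \[0,1\], `NA` allowed for synthetic subgraphs).
#' @param nodes optional character vector of node identifiers; must be a
#'   superset of the genes appearing in `edges`. Nodes without edges are kept
#'   (with degree 0) until [prune_isolated()] removes them.
#' @return an object of class `background_network`: a list with elements
#'   `edges` (tibble `gene1`, `gene2`, `confidence`), `nodes` (sorted
#'   character), `degree` (named integer) and `graph` (the underlying
#'   [igraph::igraph] object).
#' @export
background_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("gene1", "gene2") %in% names(edges))) {
    stop_niee("edge table must have columns 'gene1' and 'gene2'")
  }
  if (!"confidence" %in% names(edges)) edges$confidence <- NA_real_
  edges$gene1 <- as.character(edges$gene1)
  edges$gene2 <- as.character(edges$gene2)
  if (any(edges$gene1 == edges$gene2)) {
    stop_niee("self-loops are not allowed in a background network")
  }
  g1 <- pmin(edges$gene1, edges$gene2)
  g2 <- pmax(edges$gene1, edges$gene2)
  edges <- tibble(gene1 = g1, gene2 = g2, confidence = edges$confidence)
  if (anyDuplicated(edge_key(edges$gene1, edges$gene2))) {
    stop_niee("duplicate edges in edge table; collapse before constructing")
  }
  edges <- arrange(edges, .data$gene1, .data$gene2)
  edge_genes <- unique(c(edges$gene1, edges$gene2))
  if (is.null(nodes)) {
    nodes <- edge_genes
  } else {
    nodes <- as.character(nodes)
    if (!all(edge_genes %in% nodes)) {
      stop_niee("`nodes` must contain every gene appearing in `edges`")
    }
  }
  nodes <- sort(unique(nodes))
  graph <- igraph::graph_from_data_frame(
    edges[, c("gene1", "gene2")],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  degree <- igraph::degree(graph)
  structure(
    list(edges = edges, nodes = nodes, degree = degree[nodes], graph = graph),
    class = "background_network"
  )
}

#' @export
print.background_network <- function(x, ...) {
  cat(sprintf(
    "<background_network> %d nodes, %d edges (degree range %s)\n",
    length(x$nodes), nrow(x$edges),
    if (length(x$nodes)) paste(range(x$degree), collapse = "-") else "NA"
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.background_network <- function(x, ...) x$edges

n_edges <- function(net) nrow(net$edges)

#' Read a confidence-scored edge list (StringDB protein-links dialect)
#'
#' Parses a delimited edge list with at least three columns (two interactor
#' identifiers and a combined confidence score), filters edges at a confidence
#' threshold, collapses duplicate pairs (either orientation) keeping the
#' maximum score, and drops self-loops. The StringDB protein-links file
#' (space-delimited, header `protein1 protein2 combined_score`, integer scores
#' 0-1000) is accepted natively; set `score_scale = "unit"` for files already
#' on the \[0,1\] scale.
#'
#' @param path path to a whitespace-, tab- or comma-delimited file, with or
#'   without a header row.
#' @param threshold minimum normalized confidence in \[0,1\] for an edge to be
#'   retained (default 0.85, the usual high-confidence StringDB cutoff).
#' @param score_scale `"thousand"` (StringDB integers, divided by 1000) or
#'   `"unit"` (already in \[0,1\]).
#' @return a [background_network()].
#' @export
read_string_network <- function(path, threshold = 0.85,
                                score_scale = c("thousand", "unit")) {
  score_scale <- match.arg(score_scale)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop_niee("`threshold` must be a single number in [0, 1]")
  }
  lines <- readr::read_lines(path)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) stop_niee("empty network: file has no rows")
  toks <- strsplit(trimws(lines[lines_keep]), "[,\t ]+")
  # header detection: third field of the first row is not numeric
  first <- toks[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) {
    toks <- toks[-1]
    lines_keep <- lines_keep[-1]
  }
  if (length(toks) == 0) stop_niee("empty network: file has no data rows")
  bad <- which(vapply(toks, length, integer(1)) < 3)
  if (length(bad)) {
    stop_niee(sprintf(
      "malformed row at line %d: fewer than 3 fields", lines_keep[bad[1]]
    ))
  }
  g1 <- vapply(toks, `[[`, character(1), 1L)
  g2 <- vapply(toks, `[[`, character(1), 2L)
  score <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
  if (anyNA(score)) {
    stop_niee(sprintf(
      "malformed row at line %d: non-numeric score",
      lines_keep[which(is.na(score))[1]]
    ))
  }
  conf <- if (score_scale == "thousand") score / 1000 else score
  if (any(conf < 0) || any(conf > 1)) {
    stop_niee(paste0(
      "scores outside [0, 1] after normalization; ",
      "check `score_scale` (StringDB files need \"thousand\")"
    ))
  }
  keep <- g1 != g2
  g1 <- g1[keep]; g2 <- g2[keep]; conf <- conf[keep]
  key <- edge_key(g1, g2)
  # duplicate orientations collapse to the maximum score
  conf_max <- tapply(conf, key, max)
  keys <- names(conf_max)
  pairs <- split_edge_key(keys)
  edges <- tibble(
    gene1 = pairs$gene1, gene2 = pairs$gene2,
    confidence = as.numeric(conf_max)
  )
  edges <- filter(edges, .data$confidence >= !!threshold)
  if (nrow(edges) == 0) {
    stop_niee("empty network: no edges at or above the confidence threshold")
  }
  background_network(edges)
}

#' Remove isolated (degree-0) nodes
#'
#' @param net a [background_network()].
#' @return the network without degree-0 nodes; edges unchanged.
#' @export
prune_isolated <- function(net) {
  stopifnot(inherits(net, "background_network"))
  keep <- net$nodes[net$degree > 0]
  if (length(keep) == length(net$nodes)) return(net)
  background_network(net$edges, nodes = keep)
}

#' Remove edges attached to leaf (degree-1) nodes
#'
#' Leaf nodes have a single first-order neighbor and contribute minimal
#' information to edge entropies, so their edges are eliminated. With
#' `iterative = TRUE` (the default) the pass repeats until no degree-1 node
#' remains, guaranteeing every surviving node has at least two neighbors —
#' which keeps the entropy normalization 1/log(M) well defined. Nodes left
#' with degree 0 by a pass are dropped.
#'
#' @param net a [background_network()].
#' @param iterative repeat peeling to a fixed point (default `TRUE`).
#' @return the pruned network (possibly empty: 0 nodes, 0 edges).
#' @export
prune_leaves <- function(net, iterative = TRUE) {
  stopifnot(inherits(net, "background_network"))
  repeat {
    leaves <- net$nodes[net$degree == 1]
    if (length(leaves) == 0) break
    keep <- !(net$edges$gene1 %in% leaves | net$edges$gene2 %in% leaves)
    edges <- net$edges[keep, , drop = FALSE]
    net <- background_network(edges)
    if (!iterative) {
      net <- prune_isolated(net)
      break
    }
  }
  prune_isolated(net)
}

#' First-order neighbors of a gene
#'
#' @param net a [background_network()].
#' @param gene a node identifier present in the network.
#' @return character vector of neighbors in lexicographic order; its length
#'   equals the gene's degree (the M of the node-entropy normalization).
#' @export
network_neighbors <- function(net, gene) {
  stopifnot(inherits(net, "background_network"))
  if (!gene %in% net$nodes) {
    stop_niee(sprintf("gene '%s' is not a node of the network", gene))
  }
  nbr <- igraph::neighbors(net$graph, gene)
  sort(igraph::V(net$graph)$name[nbr])
}

#' Node degrees as a tibble
#'
#' @param net a [background_network()].
#' @return tibble with columns `gene`, `degree`, sorted by gene.
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "background_network"))
  tibble(gene = net$nodes, degree = as.integer(net$degree))
}

#' Write a background network as a three-column TSV
#'
#' @param net a [background_network()].
#' @param path output file (`gene1`, `gene2`, `confidence`).
#' @export
write_background_network <- function(net, path) {
  stopifnot(inherits(net, "background_network"))
  readr::write_tsv(net$edges, path)
  invisible(path)
}
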