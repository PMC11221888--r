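#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
NULL

# validation failures get a condition class so the CLI can map them to exit code 1
stop_niee <- function(msg, class = "niee_error") {
  rlang::abort(msg, class = c(class, "niee_error"))
}

# canonical undirected edge identity: lexicographically smaller gene first
edge_key <- function(gene1, gene2) {
  paste(pmin(gene1, gene2), pmax(gene1, gene2), sep = "--")
}

split_edge_key <- function(key) {
  parts <- strsplit(key, "--", fixed = TRUE)
  tibble(
    gene1 = vapply(parts, `[[`, character(1), 1L),
    gene2 = vapply(parts, `[[`, character(1), 2L)
  )
}

# accepts a two-column data frame (gene1, gene2), a key_local_network, or a
# character vector of "a--b" keys; returns canonical keys
as_edge_keys <- function(edges) {
  if (is.character(edges)) {
    parts <- split_edge_key(edges)
    return(edge_key(parts$gene1, parts$gene2))
  }
  if (is.data.frame(edges)) {
    if (!all(c("gene1", "gene2") %in% names(edges))) {
      stop_niee("edge table must have columns 'gene1' and 'gene2'")
    }
    return(edge_key(edges$gene1, edges$gene2))
  }
  stop_niee("edges must be a character vector of keys or a gene1/gene2 table")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
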