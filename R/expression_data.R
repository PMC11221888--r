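#' Read a genes-by-samples expression matrix
#'
#' Expects a delimited table whose first column holds gene identifiers and
#' whose header row holds sample labels; tab- and comma-delimited files are
#' auto-detected. Values are assumed pre-processed (normalized, on whatever
#' scale the source dataset uses); no transformation is applied.
#'
#' @param path path to the table.
#' @param missing_policy what to do with missing / non-numeric cells:
#'   `"error"` (default), `"drop_gene"` (remove affected rows) or
#'   `"impute_row_mean"` (replace with the gene's mean over observed samples).
#' @param transpose set `TRUE` only if the file is samples-by-genes; the
#'   orientation is never guessed.
#' @return numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression <- function(path,
                            missing_policy = c("error", "drop_gene",
                                               "impute_row_mean"),
                            transpose = FALSE) {
  missing_policy <- match.arg(missing_policy)
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) stop_niee("empty expression table")
  delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop_niee("empty expression table: need >= 1 gene row and >= 1 sample column")
  }
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop_niee(sprintf("duplicate gene identifiers: %s",
                      paste(dup, collapse = ", ")))
  }
  mat <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  )
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(genes, names(df)[-1]))
  if (anyDuplicated(colnames(mat))) {
    stop_niee("duplicate sample labels in header")
  }
  if (anyNA(mat)) {
    offenders <- rownames(mat)[apply(is.na(mat), 1, any)]
    mat <- switch(missing_policy,
      error = stop_niee(sprintf(
        "missing or non-numeric values in genes: %s",
        paste(offenders, collapse = ", ")
      )),
      drop_gene = mat[setdiff(rownames(mat), offenders), , drop = FALSE],
      impute_row_mean = {
        for (g in offenders) {
          row <- mat[g, ]
          if (all(is.na(row))) {
            stop_niee(sprintf("gene %s has no observed values to impute from", g))
          }
          row[is.na(row)] <- mean(row, na.rm = TRUE)
          mat[g, ] <- row
        }
        mat
      }
    )
    if (nrow(mat) == 0) stop_niee("no genes left after dropping missing rows")
  }
  if (transpose) mat <- t(mat)
  mat
}

#' Write an expression matrix as a TSV (genes in rows)
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Reconcile an expression matrix with a background network
#'
#' Restricts both inputs to their common genes: the network becomes the
#' induced subgraph on the intersection and is then re-pruned (isolated nodes
#' and leaf edges, with the same settings used to build it) so that every
#' retained node still has at least two neighbors; the expression matrix is
#' restricted to the surviving network nodes. Idempotent.
#'
#' @param expr genes-by-samples numeric matrix.
#' @param net a [background_network()].
#' @param iterative leaf pruning mode passed to [prune_leaves()].
#' @return list with elements `expression` and `network`.
#' @export
align_to_network <- function(expr, net, iterative = TRUE) {
  stopifnot(inherits(net, "background_network"), is.matrix(expr))
  common <- intersect(rownames(expr), net$nodes)
  if (length(common) == 0) {
    stop_niee("empty intersection between expression genes and network nodes")
  }
  keep <- net$edges$gene1 %in% common & net$edges$gene2 %in% common
  sub <- background_network(net$edges[keep, , drop = FALSE], nodes = common)
  sub <- prune_leaves(prune_isolated(sub), iterative = iterative)
  if (n_edges(sub) == 0) {
    stop_niee("empty network after aligning to the expression matrix")
  }
  list(
    expression = expr[sub$nodes, , drop = FALSE],
    network = sub
  )
}

# shared cohort-size guard (Pearson correlation needs >= 3 points; small
# cohorts give unstable correlations)
check_reference_size <- function(s) {
  if (s < 3) {
    stop_niee(sprintf(
      "reference cohort has %d samples; at least 3 are required", s
    ))
  }
  if (s < 8) {
    rlang::warn(sprintf(
      "reference cohort has only %d samples; correlations will be noisy", s
    ), .frequency = "once", .frequency_id = "niee_small_cohort")
  }
  invisible(s)
}

#' Append a perturbed sample to a reference cohort
#'
#' Builds the (s+1)-sample set on which the perturbed edge entropy and
#' standard deviation are evaluated: the s reference columns in their
#' original order, then the perturbed sample as the last column. Reference
#' values are never modified.
#'
#' @param reference genes-by-samples numeric matrix.
#' @param perturbed named numeric vector covering exactly the reference genes.
#' @param label column name for the appended sample.
#' @return numeric matrix with `ncol(reference) + 1` columns.
#' @export
build_sample_set <- function(reference, perturbed, label = "perturbed") {
  stopifnot(is.matrix(reference))
  if (is.null(names(perturbed))) {
    stop_niee("`perturbed` must be a named vector keyed by gene")
  }
  missing_g <- setdiff(rownames(reference), names(perturbed))
  extra_g <- setdiff(names(perturbed), rownames(reference))
  if (length(missing_g) || length(extra_g)) {
    stop_niee(sprintf(
      "gene mismatch between reference and perturbed sample (missing: %s; extra: %s)",
      paste(missing_g, collapse = ", "), paste(extra_g, collapse = ", ")
    ))
  }
  out <- cbind(reference, perturbed[rownames(reference)])
  colnames(out) <- c(colnames(reference), label)
  out
}
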