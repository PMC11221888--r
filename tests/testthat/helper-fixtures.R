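# small programmatic fixtures shared across test files

make_net <- function(pairs, confidence = NA_real_) {
  background_network(tibble::tibble(
    gene1 = vapply(pairs, `[[`, character(1), 1L),
    gene2 = vapply(pairs, `[[`, character(1), 2L),
    confidence = confidence
  ))
}

triangle_net <- function() {
  make_net(list(c("A", "B"), c("A", "C"), c("B", "C")), confidence = 0.9)
}

# random pruned instance (every node degree >= 2) with a matching expression
# cohort and one perturbed sample; used by oracle-equivalence and symmetry
# property tests
random_instance <- function(seed, n_genes = 20, p = 0.18, n_samples = 8) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n_genes, p)
      igraph::V(g)$name <- sprintf("g%02d", seq_len(n_genes))
      el <- igraph::as_edgelist(g)
      if (nrow(el) < 3) next
      net <- prune_leaves(prune_isolated(background_network(
        tibble::tibble(gene1 = el[, 1], gene2 = el[, 2], confidence = 0.9)
      )))
      if (nrow(net$edges) >= 3) break
    }
    ref <- matrix(stats::rnorm(length(net$nodes) * n_samples, mean = 10),
                  nrow = length(net$nodes),
                  dimnames = list(net$nodes,
                                  sprintf("ref_%02d", seq_len(n_samples))))
    pert <- stats::setNames(stats::rnorm(length(net$nodes), mean = 10, sd = 2),
                            net$nodes)
    list(net = net, reference = ref, perturbed = pert)
  })
}

# a fake scored result with chosen deltas, for screening/trajectory tests
fake_result <- function(deltas, label = "s", genes = NULL) {
  n <- length(deltas)
  if (is.null(genes)) {
    genes <- cbind(sprintf("a%03d", seq_len(n)), sprintf("b%03d", seq_len(n)))
  }
  niee:::new_niee_result(
    tibble::tibble(
      gene1 = genes[, 1], gene2 = genes[, 2],
      h_ref = 0.5, sd_ref = 1, h_pert = 0.5, sd_pert = 1,
      delta = as.numeric(deltas)
    ),
    sample = label
  )
}

write_edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
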