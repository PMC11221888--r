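# Deliberately naive, loop-based transcription of the scoring definitions,
# kept independent of the package internals: neighbor sets are rebuilt from
# the raw edge table, correlations use stats::cor directly, and entropies use
# base-2 logarithms (the production code uses natural logs; the 1/log M
# normalization must cancel the base).

oracle_node_entropy <- function(gene, neighbors, X) {
  pccs <- numeric(length(neighbors))
  for (i in seq_along(neighbors)) {
    x <- X[gene, ]
    y <- X[neighbors[i], ]
    pccs[i] <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else
      stats::cor(x, y)
  }
  a <- abs(pccs)
  m <- length(a)
  w <- if (sum(a) == 0) rep(1 / m, m) else a / sum(a)
  h <- 0
  for (p in w) if (p > 0) h <- h - p * log2(p)
  h / log2(m)
}

oracle_score_sample <- function(edges_df, reference, perturbed) {
  nodes <- sort(unique(c(edges_df$gene1, edges_df$gene2)))
  nbrs <- lapply(nodes, function(g) {
    sort(unique(c(edges_df$gene2[edges_df$gene1 == g],
                  edges_df$gene1[edges_df$gene2 == g])))
  })
  names(nbrs) <- nodes
  deg <- vapply(nbrs, length, integer(1))
  full <- cbind(reference, perturbed[rownames(reference)])
  out <- vector("list", nrow(edges_df))
  for (k in seq_len(nrow(edges_df))) {
    g1 <- edges_df$gene1[k]
    g2 <- edges_df$gene2[k]
    alpha <- deg[[g1]]
    beta <- deg[[g2]]
    wa <- alpha / (alpha + beta)
    wb <- beta / (alpha + beta)
    h_ref <- wa * oracle_node_entropy(g1, nbrs[[g1]], reference) +
      wb * oracle_node_entropy(g2, nbrs[[g2]], reference)
    h_pert <- wa * oracle_node_entropy(g1, nbrs[[g1]], full) +
      wb * oracle_node_entropy(g2, nbrs[[g2]], full)
    sd_ref <- wa * stats::sd(reference[g1, ]) + wb * stats::sd(reference[g2, ])
    sd_pert <- wa * stats::sd(full[g1, ]) + wb * stats::sd(full[g2, ])
    out[[k]] <- data.frame(
      gene1 = g1, gene2 = g2,
      h_ref = h_ref, sd_ref = sd_ref,
      h_pert = h_pert, sd_pert = sd_pert,
      delta = abs(sd_pert - sd_ref) * abs(h_pert - h_ref),
      stringsAsFactors = FALSE
    )
  }
  recs <- do.call(rbind, out)
  recs[order(recs$gene1, recs$gene2), , drop = FALSE]
}
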