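test_that("pearson correlation matches hand values and degenerate convention", {
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_equal(pcc(c(1, 1, 1), c(1, 2, 3)), 0)
  expect_error(pcc(1:3, 1:4), "equal length")
  expect_error(pcc(1:2, 1:2), "at least 3")
})

test_that("neighbor weights normalize absolute correlations with fallbacks", {
  expr <- matrix(c(
    1, 2, 3, 4,
    1.1, 2.2, 2.8, 4.3,   # strongly correlated with x
    4, 1, 3, 2            # weakly related
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("x", "n1", "n2"), paste0("s", 1:4)))
  w <- neighbor_weights("x", c("n1", "n2"), expr)
  a <- c(abs(cor(expr["x", ], expr["n1", ])),
         abs(cor(expr["x", ], expr["n2", ])))
  expect_equal(unname(w), a / sum(a))
  expect_equal(sum(w), 1)

  # direct normalization: |PCC| = (0.3, 0.1) -> (0.75, 0.25)
  expect_equal(c(0.3, 0.1) / sum(c(0.3, 0.1)), c(0.75, 0.25))

  # constant gene: every PCC is 0 -> uniform fallback
  expr_const <- expr
  expr_const["x", ] <- 5
  expect_equal(unname(neighbor_weights("x", c("n1", "n2"), expr_const)),
               c(0.5, 0.5))

  expect_error(neighbor_weights("x", "n1", expr), "M >= 2")
  expect_error(neighbor_weights("x", c("n1", "zz"), expr), "absent")
})

test_that("normalized entropy hits its closed-form values", {
  expect_identical(node_entropy(c(0.5, 0.5)), 1)
  expect_identical(node_entropy(c(1, 0)), 0)
  expect_equal(node_entropy(c(0.75, 0.25)), 0.8112781, tolerance = 1e-7)
  expect_equal(node_entropy(rep(1 / 5, 5)), 1)
  expect_error(node_entropy(0.9), "M >= 2")
  expect_error(node_entropy(c(0.7, 0.2)), "sum to 1")
})

test_that("entropy is independent of the logarithm base", {
  w <- c(0.6, 0.25, 0.1, 0.05)
  expect_equal(node_entropy(w, base = 2), node_entropy(w, base = exp(1)),
               tolerance = 1e-14)
  expect_equal(node_entropy(w, base = 10), node_entropy(w, base = exp(1)),
               tolerance = 1e-14)
})

test_that("node standard deviation uses the s-1 divisor", {
  expr <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), paste0("s", 1:3)))
  expect_equal(node_sd("a", expr), 1)
  expect_equal(node_sd("b", expr), 0)
  expr2 <- matrix(c(0, 10), nrow = 1, dimnames = list("a", c("s1", "s2")))
  expect_equal(node_sd("a", expr2), 7.071068, tolerance = 1e-6)
  expect_error(node_sd("zz", expr), "absent")
})

test_that("edge entropy and SD are degree-weighted combinations of node values", {
  inst <- random_instance(5, n_genes = 15, p = 0.25, n_samples = 6)
  net <- inst$net
  e <- net$edges[3, ]
  ctx <- edge_context(net, e$gene1, e$gene2)
  expect_equal(ctx$alpha, unname(net$degree[e$gene1]))
  expect_equal(ctx$M1, ctx$alpha)
  expect_equal(ctx$M2, ctx$beta)
  expect_true(e$gene2 %in% ctx$neighbors1 && e$gene1 %in% ctx$neighbors2)

  h1 <- node_entropy(neighbor_weights(e$gene1, ctx$neighbors1, inst$reference))
  h2 <- node_entropy(neighbor_weights(e$gene2, ctx$neighbors2, inst$reference))
  wgt <- ctx$alpha / (ctx$alpha + ctx$beta)
  expect_equal(edge_entropy(ctx, inst$reference),
               wgt * h1 + (1 - wgt) * h2, tolerance = 1e-14)
  expect_equal(edge_sd(ctx, inst$reference),
               wgt * node_sd(e$gene1, inst$reference) +
                 (1 - wgt) * node_sd(e$gene2, inst$reference),
               tolerance = 1e-14)
  expect_error(edge_context(net, "nope", e$gene2), "not in the network")
})

test_that("per-edge differential score matches the naive oracle", {
  for (seed in c(2, 7)) {
    inst <- random_instance(seed, n_genes = 12, p = 0.3, n_samples = 8)
    oracle <- oracle_score_sample(inst$net$edges, inst$reference,
                                  inst$perturbed)
    e <- inst$net$edges[1, ]
    ctx <- edge_context(inst$net, e$gene1, e$gene2)
    rec <- differential_edge_score(ctx, inst$reference, inst$perturbed)
    orec <- oracle[oracle$gene1 == e$gene1 & oracle$gene2 == e$gene2, ]
    for (col in c("h_ref", "sd_ref", "h_pert", "sd_pert", "delta")) {
      expect_equal(rec[[col]], orec[[col]], tolerance = 1e-10)
    }
    expect_gte(rec$delta, 0)
  }
})

test_that("an SD-neutral perturbed sample annihilates the differential score", {
  # appending v = mean + sd * sqrt((s+1)/s) leaves each gene's sample SD
  # unchanged, so the |SD(s+1) - SD(s)| factor vanishes for every edge and
  # delta collapses to ~0 no matter how the entropies move
  inst <- random_instance(61, n_genes = 15, p = 0.25, n_samples = 8)
  s <- ncol(inst$reference)
  v <- rowMeans(inst$reference) +
    apply(inst$reference, 1, sd) * sqrt((s + 1) / s)
  res <- score_sample(inst$net, inst$reference, v, "neutral")
  expect_equal(res$sd_pert, res$sd_ref, tolerance = 1e-12)
  expect_true(all(res$delta < 1e-12))
  expect_false(all(res$h_pert == res$h_ref))
})

test_that("vectorized scoring equals the compositional per-edge path", {
  inst <- random_instance(13, n_genes = 18, p = 0.2, n_samples = 7)
  res <- suppressWarnings(
    score_sample(inst$net, inst$reference, inst$perturbed, "p")
  )
  for (k in c(1, nrow(res))) {
    ctx <- edge_context(inst$net, res$gene1[k], res$gene2[k])
    rec <- differential_edge_score(ctx, inst$reference, inst$perturbed)
    expect_equal(res$delta[k], rec$delta, tolerance = 1e-12)
    expect_equal(res$h_ref[k], rec$h_ref, tolerance = 1e-12)
    expect_equal(res$h_pert[k], rec$h_pert, tolerance = 1e-12)
  }
  expect_equal(global_score(res), mean(res$delta))
  expect_true(all(res$h_ref >= 0 & res$h_ref <= 1))
  expect_true(all(res$h_pert >= 0 & res$h_pert <= 1))
  expect_true(all(res$delta >= 0))
})

test_that("reference column order never changes any edge record", {
  inst <- random_instance(21, n_genes = 16, p = 0.22, n_samples = 9)
  res <- score_sample(inst$net, inst$reference, inst$perturbed, "p")
  for (seed in 1:3) {
    perm <- withr::with_seed(seed, sample(ncol(inst$reference)))
    res_p <- score_sample(inst$net, inst$reference[, perm],
                          inst$perturbed, "p")
    expect_equal(as.data.frame(res), as.data.frame(res_p), tolerance = 1e-14)
  }
})

test_that("scaling expression by c > 0 fixes entropies and scales deltas by c", {
  inst <- random_instance(31, n_genes = 16, p = 0.22, n_samples = 8)
  res <- score_sample(inst$net, inst$reference, inst$perturbed, "p")
  for (c_fac in c(0.5, 3)) {
    res_c <- score_sample(inst$net, c_fac * inst$reference,
                          c_fac * inst$perturbed, "p")
    expect_equal(res_c$h_ref, res$h_ref, tolerance = 1e-12)
    expect_equal(res_c$h_pert, res$h_pert, tolerance = 1e-12)
    expect_equal(res_c$sd_ref, c_fac * res$sd_ref, tolerance = 1e-12)
    expect_equal(res_c$delta, c_fac * res$delta, tolerance = 1e-12)
    expect_equal(global_score(res_c), c_fac * global_score(res),
                 tolerance = 1e-12)
  }
})

test_that("a strongly shifted profile outscores the mean profile (paired)", {
  hits <- 0L
  for (seed in 1:20) {
    inst <- random_instance(100 + seed, n_genes = 15, p = 0.25, n_samples = 10)
    mean_prof <- rowMeans(inst$reference)
    shifted <- mean_prof + 5 * apply(inst$reference, 1, sd)
    g_mean <- global_score(
      score_sample(inst$net, inst$reference, mean_prof, "m"))
    g_shift <- global_score(
      score_sample(inst$net, inst$reference, shifted, "s"))
    hits <- hits + (g_shift > g_mean)
  }
  expect_gte(hits, 18L)
})

test_that("local aggregation reduces to the global score on the full edge set", {
  inst <- random_instance(41, n_genes = 15, p = 0.25, n_samples = 8)
  res <- score_sample(inst$net, inst$reference, inst$perturbed, "p")
  all_edges <- as.data.frame(res[, c("gene1", "gene2")])
  expect_identical(local_score(res, all_edges), global_score(res))
  one <- all_edges[5, ]
  expect_equal(local_score(res, one), res$delta[5])

  fake <- fake_result(c(0.2, 0.4))
  edges <- as.data.frame(fake[, c("gene1", "gene2")])
  expect_equal(local_score(fake, edges, reduction = "mean"), 0.3)
  expect_equal(local_score(fake, edges, reduction = "sum"),
               0.6000000000000001)
  expect_error(local_score(fake, character(0)), "empty")
  expect_error(local_score(fake, "zz--ww"), "not present")
})

test_that("scored results round-trip through TSV + JSON sidecar and broom verbs", {
  inst <- random_instance(51, n_genes = 14, p = 0.25, n_samples = 8)
  res <- score_sample(inst$net, inst$reference, inst$perturbed, "p7")
  g <- generics::glance(res)
  expect_equal(g$sample, "p7")
  expect_equal(g$global_score, global_score(res))
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "niee_result"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_niee_result(res, path)
  back <- read_niee_result(path)
  expect_equal(attr(back, "sample"), "p7")
  expect_equal(global_score(back), global_score(res), tolerance = 1e-10)
  expect_equal(back$delta, res$delta, tolerance = 1e-10)
})
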