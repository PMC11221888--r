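#' Define a synthetic tipping-point scenario
#'
#' Bundles and validates every parameter of the seeded generator: a random
#' background network, a reference cohort drawn from a multivariate normal
#' whose correlation follows the network, and a perturbed time series in
#' which a planted gene module's variance and mutual correlation surge at a
#' chosen tipping time — the dynamic-network-biomarker signature of an
#' approaching critical transition.
#'
#' @param n_genes number of genes before pruning.
#' @param network_model `"erdos_renyi"` (edge probability `edge_density`) or
#'   `"scale_free"` (preferential attachment, `attachment_power`).
#' @param edge_density edge probability of the Erdos-Renyi model; the default
#'   0.12 yields roughly 150 edges on 50 genes.
#' @param attachment_power preferential-attachment exponent (scale-free model).
#' @param n_reference reference cohort size (>= 3; small cohorts warn).
#' @param time_points ordered labels of the perturbed series.
#' @param module_size number of genes in the planted module (wired into a
#'   clique), or supply `module_genes` explicitly.
#' @param module_genes optional explicit module members.
#' @param tipping_time element of `time_points` at which the surge starts.
#' @param sd_boost multiplier (>= 1) on the module genes' standard deviation
#'   at and after the tipping time; 1 means no variance surge.
#' @param rho_boost mutual correlation of module genes at and after the
#'   tipping time, in \[0, 1).
#' @param baseline_rho correlation of network-adjacent gene pairs in the
#'   reference state, in \[0, 1).
#' @param noise_sd standard deviation of i.i.d. measurement noise added to
#'   every value.
#' @param seed integer seed; every generated artifact is reproducible from it.
#' @return a validated list of class `niee_scenario`.
#' @export
niee_scenario <- function(n_genes = 50,
                          network_model = c("erdos_renyi", "scale_free"),
                          edge_density = 0.12,
                          attachment_power = 1,
                          n_reference = 20,
                          time_points = paste0("t", 1:10),
                          module_size = 5,
                          module_genes = NULL,
                          tipping_time = "t6",
                          sd_boost = 3,
                          rho_boost = 0.9,
                          baseline_rho = 0.3,
                          noise_sd = 0.1,
                          seed = 1) {
  network_model <- match.arg(network_model)
  if (n_genes < 4) stop_niee("`n_genes` must be at least 4")
  if (network_model == "erdos_renyi" &&
      (edge_density <= 0 || edge_density > 1)) {
    stop_niee("`edge_density` must be in (0, 1]")
  }
  if (n_reference < 3) {
    stop_niee("`n_reference` must be at least 3 (correlation needs 3 points)")
  }
  if (length(time_points) < 2 || anyDuplicated(time_points)) {
    stop_niee("`time_points` must be >= 2 distinct labels")
  }
  if (!tipping_time %in% time_points) {
    stop_niee("`tipping_time` must be one of `time_points`")
  }
  if (sd_boost < 1) stop_niee("`sd_boost` must be >= 1")
  if (rho_boost < 0 || rho_boost >= 1) stop_niee("`rho_boost` must be in [0, 1)")
  if (baseline_rho < 0 || baseline_rho >= 1) {
    stop_niee("`baseline_rho` must be in [0, 1)")
  }
  if (noise_sd <= 0) stop_niee("`noise_sd` must be positive")
  if (is.null(module_genes)) {
    if (module_size < 2 || module_size > n_genes) {
      stop_niee("`module_size` must be in [2, n_genes]")
    }
  }
  structure(
    list(
      n_genes = as.integer(n_genes), network_model = network_model,
      edge_density = edge_density, attachment_power = attachment_power,
      n_reference = as.integer(n_reference),
      time_points = as.character(time_points),
      module_size = as.integer(module_size), module_genes = module_genes,
      tipping_time = tipping_time, sd_boost = sd_boost,
      rho_boost = rho_boost, baseline_rho = baseline_rho,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "niee_scenario"
  )
}

#' Generate the scenario's background network
#'
#' Draws the seeded random graph, prunes it (isolated nodes, iterative leaf
#' peeling), picks the planted module among the surviving genes and rewires
#' it into a clique so its internal edges are guaranteed to exist. Synthetic
#' confidences are drawn uniformly in \[0.85, 1\].
#'
#' @param scenario a [niee_scenario()].
#' @return a [background_network()] with attribute `module_genes`.
#' @export
simulate_network <- function(scenario) {
  stopifnot(inherits(scenario, "niee_scenario"))
  withr::with_seed(scenario$seed, {
    g <- switch(scenario$network_model,
      erdos_renyi = igraph::sample_gnp(scenario$n_genes,
                                       scenario$edge_density),
      scale_free = igraph::sample_pa(scenario$n_genes,
                                     power = scenario$attachment_power,
                                     m = 2, directed = FALSE)
    )
    igraph::V(g)$name <- sprintf("g%03d", seq_len(scenario$n_genes))
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) stop_niee("scenario parameters produced no edges")
    edges <- tibble(
      gene1 = el[, 1], gene2 = el[, 2],
      confidence = round(stats::runif(nrow(el), 0.85, 1), 3)
    )
    net <- prune_leaves(prune_isolated(background_network(edges)))
    if (n_edges(net) == 0) {
      stop_niee("scenario parameters produced an empty network after pruning")
    }
    module <- scenario$module_genes
    if (is.null(module)) {
      if (length(net$nodes) < scenario$module_size) {
        stop_niee("too few genes survive pruning to host the module")
      }
      module <- sort(sample(net$nodes, scenario$module_size))
    } else if (!all(module %in% net$nodes)) {
      stop_niee("explicit `module_genes` must survive network pruning")
    }
    # wire the module into a clique so every internal edge exists
    pairs <- utils::combn(sort(module), 2)
    clique <- tibble(gene1 = pairs[1, ], gene2 = pairs[2, ],
                     confidence = 0.95)
    have <- edge_key(net$edges$gene1, net$edges$gene2)
    add <- clique[!edge_key(clique$gene1, clique$gene2) %in% have, ]
    net <- prune_leaves(prune_isolated(
      background_network(dplyr::bind_rows(net$edges, add))
    ))
    attr(net, "module_genes") <- module
    net
  })
}

# target correlation: 1 on the diagonal, baseline_rho on network-adjacent
# pairs; module block overridden when boost parameters say so; repaired to
# the nearest positive-definite correlation when the patchwork is not PD
scenario_correlation <- function(scenario, net, boosted) {
  nodes <- net$nodes
  n <- length(nodes)
  s <- diag(1, n)
  dimnames(s) <- list(nodes, nodes)
  i <- match(net$edges$gene1, nodes)
  j <- match(net$edges$gene2, nodes)
  s[cbind(i, j)] <- scenario$baseline_rho
  s[cbind(j, i)] <- scenario$baseline_rho
  if (boosted) {
    m <- match(attr(net, "module_genes"), nodes)
    s[m, m] <- scenario$rho_boost
    diag(s)[m] <- 1
  }
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    rlang::warn(
      "target correlation not positive definite; repaired with nearPD",
      .frequency = "once", .frequency_id = "niee_nearpd"
    )
    s <- as.matrix(Matrix::nearPD(s, corr = TRUE)$mat)
    dimnames(s) <- list(nodes, nodes)
  }
  s
}

scenario_covariance <- function(scenario, net, boosted) {
  s <- scenario_correlation(scenario, net, boosted)
  if (boosted && scenario$sd_boost != 1) {
    sds <- rep(1, length(net$nodes))
    sds[match(attr(net, "module_genes"), net$nodes)] <- scenario$sd_boost
    s <- s * tcrossprod(sds)
  }
  s
}

draw_samples <- function(scenario, net, n, boosted) {
  sigma <- scenario_covariance(scenario, net, boosted)
  mu <- rep(10, length(net$nodes))
  x <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  x <- matrix(x, nrow = n)
  x <- x + stats::rnorm(length(x), sd = scenario$noise_sd)
  t(x)
}

#' Generate the reference cohort
#'
#' Draws `n_reference` samples from the baseline multivariate normal: unit
#' variance everywhere, correlation `baseline_rho` on network-adjacent gene
#' pairs and ~0 elsewhere, mean expression level 10, plus i.i.d. Gaussian
#' measurement noise.
#'
#' @param scenario a [niee_scenario()].
#' @param net the network from [simulate_network()].
#' @return genes-by-samples matrix (columns `ref_01`, `ref_02`, ...).
#' @export
simulate_reference <- function(scenario, net) {
  stopifnot(inherits(scenario, "niee_scenario"))
  check_reference_size(scenario$n_reference)
  withr::with_seed(scenario$seed + 1L, {
    x <- draw_samples(scenario, net, scenario$n_reference, boosted = FALSE)
    dimnames(x) <- list(net$nodes,
                        sprintf("ref_%02d", seq_len(scenario$n_reference)))
    x
  })
}

#' Generate the perturbed time series
#'
#' One sample per time point. Before the tipping time samples come from the
#' reference distribution; at and after it the module genes' standard
#' deviation is multiplied by `sd_boost` and their mutual correlation raised
#' to `rho_boost` — the planted pre-disease signature. With `sd_boost = 1`
#' and `rho_boost = baseline_rho` the series is a draw from the reference
#' distribution (null scenario).
#'
#' @inheritParams simulate_reference
#' @return genes-by-time-points matrix with attribute `ground_truth`: a list
#'   with `module_genes`, `module_edges` (keys of the network's
#'   module-internal edges), `tipping_time` and `tipping_index`.
#' @export
simulate_perturbed <- function(scenario, net) {
  stopifnot(inherits(scenario, "niee_scenario"))
  tp <- scenario$time_points
  tip <- match(scenario$tipping_time, tp)
  withr::with_seed(scenario$seed + 2L, {
    n_pre <- tip - 1L
    n_post <- length(tp) - n_pre
    pre <- if (n_pre > 0) {
      draw_samples(scenario, net, n_pre, boosted = FALSE)
    } else {
      matrix(numeric(0), nrow = length(net$nodes), ncol = 0)
    }
    post <- draw_samples(scenario, net, n_post, boosted = TRUE)
    x <- cbind(pre, post)
    dimnames(x) <- list(net$nodes, tp)
    module <- attr(net, "module_genes")
    in_module <- net$edges$gene1 %in% module & net$edges$gene2 %in% module
    attr(x, "ground_truth") <- list(
      module_genes = module,
      module_edges = edge_key(net$edges$gene1[in_module],
                              net$edges$gene2[in_module]),
      tipping_time = scenario$tipping_time,
      tipping_index = tip
    )
    x
  })
}

#' Generate the full scenario bundle
#'
#' @param scenario a [niee_scenario()].
#' @return list with elements `scenario`, `network`, `reference`,
#'   `perturbed` (matrix with ground-truth attribute) and `ground_truth`.
#' @export
simulate_scenario <- function(scenario) {
  net <- simulate_network(scenario)
  ref <- simulate_reference(scenario, net)
  pert <- simulate_perturbed(scenario, net)
  list(
    scenario = scenario,
    network = net,
    reference = ref,
    perturbed = pert,
    ground_truth = attr(pert, "ground_truth")
  )
}
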