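test_that("the abundance filter keeps taxa above the cutoff", {
  m <- fixture_abundance_6x4()
  expect_identical(filter_taxa(m, network_config(min_abundance = 0)), m)
  m2 <- cbind(m, rare = rep(5e-5, 6))
  kept <- filter_taxa(m2, network_config(min_abundance = 1e-4))
  expect_false("rare" %in% colnames(kept))
  # max statistic can rescue a spiky rare taxon
  m3 <- cbind(m, spiky = c(rep(1e-5, 5), 0.02))
  expect_false("spiky" %in% colnames(
    filter_taxa(m3, network_config(min_abundance = 4e-3, filter_stat = "mean"))))
  expect_true("spiky" %in% colnames(
    filter_taxa(m3, network_config(min_abundance = 4e-3, filter_stat = "max"))))
  expect_warning(filter_taxa(m, network_config(min_abundance = 1)), "cutoff")
})

test_that("perfect monotone pairs give r = +1 / -1 edges", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  m <- cbind(a = x, dup = 2 * x, rev = rev(x) + 0.01)
  edges <- spearman_edges(m, network_config(r_threshold = 0.7))
  dup_edge <- edges[edges$taxon_a == "a" & edges$taxon_b == "dup", ]
  rev_edge <- edges[edges$taxon_a == "a" & edges$taxon_b == "rev", ]
  expect_equal(dup_edge$r, 1)
  expect_equal(dup_edge$sign, "positive")
  expect_equal(rev_edge$r, -1)
  expect_equal(rev_edge$sign, "negative")
})

test_that("constant taxa are skipped with a warning", {
  m <- cbind(fixture_abundance_6x4(), flat = rep(0.2, 6))
  expect_warning(edges <- spearman_edges(m), "constant")
  expect_false(any(edges$taxon_a == "flat" | edges$taxon_b == "flat"))
})

test_that("small-sample edges match the exhaustive-permutation oracle", {
  m <- fixture_abundance_6x4()
  cfg <- network_config(r_threshold = 0.7, p_threshold = 0.05)
  edges <- suppressWarnings(spearman_edges(m, cfg))
  taxa <- colnames(m)
  oracle_edges <- character(0)
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (j <= i) next
      if (length(unique(m[, i])) == 1 || length(unique(m[, j])) == 1) next
      r <- cor(m[, i], m[, j], method = "spearman")
      p <- oracle_spearman_p(m[, i], m[, j])
      if (abs(r) > cfg$r_threshold && p < cfg$p_threshold) {
        oracle_edges <- c(oracle_edges, paste(taxa[i], taxa[j]))
      }
    }
  }
  expect_setequal(paste(edges$taxon_a, edges$taxon_b), oracle_edges)
  # p-values themselves agree with the oracle on every tested pair
  for (k in seq_len(nrow(edges))) {
    expect_equal(edges$p[k],
                 oracle_spearman_p(m[, edges$taxon_a[k]], m[, edges$taxon_b[k]]),
                 tolerance = 1e-12)
  }
})

test_that("raising the correlation threshold never adds edges", {
  sp <- abundance_spec(n_per_group = 6, groups = c("a", "b"), n_taxa = 15,
                       blocks = list(list(taxa = 1:5, rho = 0.8)), seed = 21)
  tab <- simulate_abundances(sp)
  last <- Inf
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    n <- nrow(spearman_edges(tab, network_config(r_threshold = thr)))
    expect_lte(n, last)
    last <- n
  }
})

test_that("edges and topology are invariant to taxon ordering", {
  sp <- abundance_spec(n_per_group = 6, groups = c("a", "b"), n_taxa = 12,
                       blocks = list(list(taxa = 1:4, rho = 0.9)), seed = 8)
  tab <- simulate_abundances(sp)
  net1 <- build_cooccurrence(tab)
  perm <- sample(ncol(tab))
  net2 <- build_cooccurrence(tab[, perm])
  key <- function(e) sort(paste(pmin(e$taxon_a, e$taxon_b),
                                pmax(e$taxon_a, e$taxon_b)))
  expect_identical(key(net1$edges), key(net2$edges))
  t1 <- topology(net1); t2 <- topology(net2)
  for (metric in c("nodes", "edges", "positive_edge_ratio", "average_degree",
                   "density", "clustering_coefficient", "modularity",
                   "components", "diameter", "average_path_length")) {
    expect_equal(t1[[metric]], t2[[metric]], label = metric)
  }
})

test_that("topology metrics match hand-computed values on tiny graphs", {
  # triangle
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  tri <- cbind(a = x, b = x + 0.01, c = 2 * x)
  t_tri <- topology(build_cooccurrence(tri))
  expect_equal(t_tri$nodes, 3)
  expect_equal(t_tri$edges, 3)
  expect_equal(t_tri$density, 1)
  expect_equal(t_tri$clustering_coefficient, 1)
  expect_equal(t_tri$diameter, 1)
  expect_equal(t_tri$components, 1)
  expect_equal(t_tri$positive_edge_ratio, 1)
  # two disjoint edges: second pair rank-independent of the first
  y <- c(0.3, 0.1, 0.6, 0.2, 0.5, 0.35)
  two <- cbind(a = x, b = x + 0.01, c = y, d = y * 3)
  t_two <- topology(build_cooccurrence(two))
  expect_equal(t_two$nodes, 4)
  expect_equal(t_two$edges, 2)
  expect_equal(t_two$components, 2)
  expect_equal(t_two$average_degree, 1)
  # empty network is flagged
  t_empty <- topology(build_cooccurrence(cbind(a = x, c = y)))
  expect_true(t_empty$empty)
  expect_equal(t_empty$edges, 0)
})

test_that("planted two-block structure yields modular communities", {
  sp <- abundance_spec(n_per_group = 6, groups = c("a", "b", "c", "d"),
                       n_taxa = 30,
                       blocks = list(list(taxa = 1:5, rho = 0.95),
                                     list(taxa = 6:10, rho = 0.95)),
                       seed = 31)
  tab <- simulate_abundances(sp)
  net <- build_cooccurrence(tab)
  top <- topology(net)
  expect_gte(top$modularity, 0.3)
  comm <- igraph::cluster_fast_greedy(net$graph, weights = NULL)
  member <- igraph::membership(comm)
  b1 <- member[paste0("taxon_", sprintf("%02d", 1:5))]
  b2 <- member[paste0("taxon_", sprintf("%02d", 6:10))]
  expect_equal(length(unique(b1)), 1L)
  expect_equal(length(unique(b2)), 1L)
  expect_false(unique(b1) == unique(b2))
})

test_that("Benjamini-Hochberg correction prunes borderline edges", {
  sp <- abundance_spec(n_per_group = 3, groups = c("a", "b"), n_taxa = 20,
                       seed = 17)
  tab <- simulate_abundances(sp)
  raw <- spearman_edges(tab, network_config(r_threshold = 0))
  bh <- spearman_edges(tab, network_config(r_threshold = 0, p_adjust = "BH"))
  expect_lte(nrow(bh), nrow(raw))
})
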