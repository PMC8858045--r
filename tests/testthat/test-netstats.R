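test_that("induced subnetworks match a brute-force edge filter", {
  g <- igraph::graph_from_literal(A - B, B - C, C - A)
  sub <- induce_subnetwork(g, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1)
  expect_setequal_chr(igraph::V(sub)$name, c("A", "B"))

  # genes with no edges among them error after the isolate drop
  g2 <- igraph::graph_from_literal(A - B, C - D)
  expect_error(induce_subnetwork(g2, c("A", "C")), "isolated")
  expect_error(induce_subnetwork(g2, c("X", "Y")), "none")

  # oracle: edges of the induced graph = edge-list rows with both ends kept
  for (s in 1:3) {
    g3 <- random_named_graph(25, 0.15, seed = s)
    keep <- sprintf("V%02d", 1:12)
    el <- igraph::as_edgelist(g3)
    manual <- el[el[, 1] %in% keep & el[, 2] %in% keep, , drop = FALSE]
    sub3 <- tryCatch(induce_subnetwork(g3, keep), error = function(e) NULL)
    if (is.null(sub3)) {
      expect_equal(nrow(manual), 0)
    } else {
      expect_equal(igraph::ecount(sub3), nrow(manual))
    }
  }
})

test_that("degree ranking is deterministic with alphabetical tie-break", {
  star <- igraph::graph_from_literal(C - A, C - B, C - D, C - E, C - F)
  r <- degree_rank(star)
  expect_equal(r$gene[1], "C")
  expect_equal(r$degree[1], 5)
  expect_equal(r$gene[-1], sort(r$gene[-1]))

  g <- random_named_graph(20, 0.2, seed = 4)
  r2 <- degree_rank(g)
  manual <- vapply(r2$gene, function(v) {
    sum(igraph::as_edgelist(g) == v)
  }, numeric(1))
  expect_equal(r2$degree, unname(as.integer(manual)))
})

test_that("GSEA running sum hits its closed-form extremes", {
  ranks <- data.frame(gene = paste0("g", 1:10), score = 10:1)
  # single top-ranked gene: running sum peaks at 1 immediately
  res_top <- preranked_gsea(ranks, list(top = "g1"), n_perm = 50, seed = 1)
  expect_equal(res_top$es, 1)
  # single bottom-ranked gene, weight 0: sum drifts to -1 then recovers
  res_bot <- preranked_gsea(ranks, list(bot = "g10"), n_perm = 50,
                            weight_p = 0, seed = 1)
  expect_equal(res_bot$es, -1)
  # p-values respect the one-plus floor
  expect_gte(res_top$p_perm, 1 / 51)

  # symmetry: negating scores and reversing rank flips the ES sign
  set.seed(2)
  sc <- setNames(sort(runif(12), decreasing = TRUE), paste0("g", 1:12))
  set1 <- list(s = c("g2", "g3", "g5"))
  es_fwd <- preranked_gsea(sc, set1, n_perm = 10, weight_p = 0, seed = 1)$es
  es_rev <- preranked_gsea(-sc, set1, n_perm = 10, weight_p = 0, seed = 1)$es
  expect_equal(es_rev, -es_fwd)

  # sets outside the universe are skipped with a warning
  expect_warning(
    res <- preranked_gsea(ranks, list(top = "g1", gone = "zz"),
                          n_perm = 20, seed = 1),
    "no members")
  expect_equal(res$set, "top")
})

test_that("hand-countable disease statistics on a path graph D-X-C", {
  g <- igraph::graph_from_literal(D - X, X - C)
  g <- set_node_classes(g, "D", c("X", "C"))
  st <- node_disease_stats(g, n_perm = 100, seed = 1)
  x <- st[st$gene == "X", ]
  expect_equal(x$degree, 2)
  expect_equal(x$disease_neighbor_count, 1)
  expect_equal(x$interaction_ratio, 0.5)
  expect_equal(x$mean_sp_disease, 1)
  expect_equal(x$mean_sp_candidate, 1)
  expect_equal(x$shortest_ratio, 1)
  cc <- st[st$gene == "C", ]
  expect_equal(cc$degree, 1)
  expect_equal(cc$disease_neighbor_count, 0)
  expect_equal(cc$mean_sp_disease, 2)
  expect_equal(cc$mean_sp_candidate, 1)
})

test_that("shortest-path means agree with a Floyd-Warshall oracle", {
  for (s in 1:3) {
    g <- random_named_graph(30 + 5 * s, 0.12, seed = s * 13)
    nodes <- igraph::V(g)$name
    set.seed(s)
    shuffled <- sample(nodes)
    dis <- shuffled[1:8]
    cand <- shuffled[9:20]
    gg <- set_node_classes(g, dis, cand)
    st <- node_disease_stats(gg, n_perm = 20, seed = s)
    Dm <- floyd_warshall(as.matrix(igraph::as_adjacency_matrix(g)))
    for (i in seq_len(nrow(st))) {
      v <- st$gene[i]
      if (st$degree[i] == 0) next
      dd <- Dm[v, dis]
      dd <- dd[is.finite(dd) & dd > 0]
      expect_equal(st$mean_sp_disease[i],
                   if (length(dd)) mean(dd) else NA_real_)
      dc <- Dm[v, setdiff(cand, v)]
      dc <- dc[is.finite(dc) & dc > 0]
      expect_equal(st$mean_sp_candidate[i],
                   if (length(dc)) mean(dc) else NA_real_)
    }
    # internal consistency: ratio * degree = neighbor count, exactly
    ok <- !is.na(st$interaction_ratio)
    expect_equal(st$interaction_ratio[ok] * st$degree[ok],
                 as.numeric(st$disease_neighbor_count[ok]))
    # analytic neighbor-count p matches enumeration-grade phyper inputs
    expect_true(all(st$p_count_hyper[ok] > 0 & st$p_count_hyper[ok] <= 1))
    expect_true(all(st$p_ratio_perm[ok] > 0 & st$p_ratio_perm[ok] <= 1))
  }
})

test_that("key-gene selection applies all four thresholds", {
  # a stats table carrying published-scale p-values for three hub candidates
  tab <- data.frame(
    gene = c("K1", "K2", "K3", "weak"),
    degree = c(17, 24, 21, 3),
    disease_neighbor_count = c(16, 21, 18, 1),
    interaction_ratio = c(0.94, 0.87, 0.86, 0.33),
    p_count_hyper = c(0.000609, 3.04e-06, 8.84e-05, 0.4),
    p_ratio_perm = c(0.024, 0.041, 0.048, 0.6),
    shortest_ratio = c(0.76, 0.77, 0.76, 1.1),
    p_shortest_perm = c(0.01, 0.015, 0.01, 0.7),
    degree_percentile = c(0.97, 0.99, 0.98, 0.30))
  expect_equal(select_key_genes(tab, alpha = 0.05), c("K1", "K2", "K3"))
  expect_equal(select_key_genes(tab, alpha = 0), character(0))
})

test_that("candidates wired into the disease neighborhood are recovered", {
  net <- simulate_scale_free_network(250, 3, seed = 6)
  dis <- plant_disease_genes(net, 25, locality = 0.8, seed = 6)
  pk <- plant_key_genes(net, dis, n_key = 4, links_per_key = 12, seed = 6)
  set.seed(106)
  others <- sample(setdiff(igraph::V(pk$network)$name,
                           c(dis, pk$key_genes)), 20)
  g <- set_node_classes(pk$network, dis, c(pk$key_genes, others))
  st <- node_disease_stats(g, n_perm = 300, seed = 6)
  sel <- select_key_genes(st, alpha = 0.05)
  expect_gte(length(intersect(sel, pk$key_genes)), 3)
  expect_lte(length(setdiff(sel, pk$key_genes)), 1)
})

test_that("the rewiring null is available and keeps classes fixed", {
  net <- simulate_scale_free_network(80, 2, seed = 31)
  nodes <- igraph::V(net)$name
  g <- set_node_classes(net, nodes[1:10], nodes[11:20])
  st <- node_disease_stats(g, n_perm = 30, seed = 3, null = "rewire")
  expect_equal(nrow(st), 10)
  expect_true(all(st$p_ratio_perm > 0 & st$p_ratio_perm <= 1, na.rm = TRUE))
  # observed columns identical to the class-shuffle run (null only affects p)
  st2 <- node_disease_stats(g, n_perm = 30, seed = 3)
  cols <- c("gene", "degree", "disease_neighbor_count", "interaction_ratio",
            "mean_sp_disease", "mean_sp_candidate", "shortest_ratio")
  expect_equal(st[cols], st2[cols])
})
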