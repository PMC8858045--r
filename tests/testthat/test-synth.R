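test_that("latent-factor limits give the expected correlation structure", {
  # zero noise, full loading: every module gene equals the factor -> r = 1
  sim <- simulate_expression(n_genes = 20, n_samples_per_condition = 5,
                             module_sizes = c(10, 10), effect = 0,
                             loading = 1, noise_sd = 0, seed = 1,
                             n_disease_modules = 0, n_background_disease = 0)
  g1 <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene == "M1"]
  C <- cor(t(sim$expr$values[g1, ]))
  expect_equal(unname(C), matrix(1, 10, 10))

  # zero loading: i.i.d. noise, mean |off-diagonal r| small
  sim0 <- simulate_expression(n_genes = 60, n_samples_per_condition = 30,
                              module_sizes = c(30, 30), effect = 0,
                              loading = 0, noise_sd = 1, seed = 2,
                              n_disease_modules = 0, n_background_disease = 0)
  C0 <- cor(t(sim0$expr$values))
  off <- abs(C0[upper.tri(C0)])
  expect_lt(mean(off), 3 / sqrt(ncol(sim0$expr$values)))
})

test_that("default fixture has stronger within- than between-module correlation", {
  sim <- simulate_expression(seed = 1)
  mog <- sim$truth$module_of_gene
  C <- cor(t(sim$expr$values))
  same <- outer(mog, mog, "==") & mog != "background"
  diag(same) <- FALSE
  between <- outer(mog, mog, "!=") & outer(mog != "background",
                                           mog != "background", "&")
  expect_gt(mean(abs(C[same])), mean(abs(C[between])))
})

test_that("disease-module factors shift in cases", {
  sim <- simulate_expression(seed = 3)
  expr <- sim$expr
  case <- expr$condition == "case"
  dm_genes <- sim$truth$module_of_gene %in% sim$truth$disease_modules
  shift_dm <- mean(expr$values[dm_genes, case]) -
    mean(expr$values[dm_genes, !case])
  expect_gt(shift_dm, 1)   # loading 0.8 * effect 2 = 1.6 expected
})

test_that("preferential-attachment generator is deterministic and heavy-tailed", {
  g <- simulate_scale_free_network(10, 1, seed = 5)
  expect_equal(igraph::ecount(g), 9)       # tree
  expect_true(igraph::is_connected(g))

  g1 <- simulate_scale_free_network(200, 3, seed = 7)
  g2 <- simulate_scale_free_network(200, 3, seed = 7)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  g3 <- simulate_scale_free_network(500, 3, seed = 1)
  deg <- igraph::degree(g3)
  expect_gte(max(deg), 5 * median(deg))

  expect_error(simulate_scale_free_network(3, 5), "n_nodes")
})

test_that("planted disease genes cluster topologically with locality", {
  g <- simulate_scale_free_network(300, 3, seed = 11)
  d0 <- plant_disease_genes(g, 25, locality = 0, seed = 1)
  expect_length(d0, 25)
  expect_true(all(d0 %in% igraph::V(g)$name))

  # locality 1 on a connected graph gives a connected induced subgraph
  d1 <- plant_disease_genes(g, 25, locality = 1, seed = 1)
  sub <- igraph::induced_subgraph(g, d1)
  expect_true(igraph::is_connected(sub))

  # mean pairwise shortest path shrinks with locality (seeds 1..20)
  msp <- function(genes) {
    D <- igraph::distances(g, v = genes, to = genes)
    mean(D[upper.tri(D)])
  }
  sp_hi <- sapply(1:20, function(s) msp(plant_disease_genes(g, 25, 0.9, seed = s)))
  sp_lo <- sapply(1:20, function(s) msp(plant_disease_genes(g, 25, 0.0, seed = s)))
  expect_lt(mean(sp_hi), mean(sp_lo))
})

test_that("planted key genes are disease-adjacent hubs", {
  g <- simulate_scale_free_network(200, 3, seed = 2)
  dis <- plant_disease_genes(g, 20, 0.8, seed = 2)
  pk <- plant_key_genes(g, dis, n_key = 4, links_per_key = 10, seed = 2)
  expect_length(pk$key_genes, 4)
  expect_true(all(!pk$key_genes %in% dis))
  for (kg in pk$key_genes) {
    nb <- igraph::neighbors(pk$network, kg)$name
    expect_gte(sum(nb %in% dis), 10)
  }
  # pool restriction honored
  pool <- setdiff(igraph::V(g)$name, dis)[1:10]
  pk2 <- plant_key_genes(g, dis, n_key = 3, links_per_key = 5, seed = 3,
                         pool = pool)
  expect_true(all(pk2$key_genes %in% pool))
})

test_that("simulated drug classes separate by network distance", {
  g <- simulate_scale_free_network(200, 3, seed = 3)
  dis <- plant_disease_genes(g, 20, 0.8, seed = 3)
  dr <- simulate_drugs(g, dis, n_proximal = 20, n_random = 20,
                       targets_per_drug = 4, seed = 3)
  expect_setequal_chr(unique(dr$drug_class), c("proximal", "random"))
  by_drug <- split(dr$drug_targets$target, dr$drug_targets$drug_id)
  d <- vapply(names(by_drug), function(id) {
    as.numeric(drug_distance(g, dis, by_drug[[id]]))
  }, numeric(1))
  cls <- dr$drug_class[names(by_drug)]
  expect_lt(mean(d[cls == "proximal"]), mean(d[cls == "random"]))

  # n_proximal = 0 -> all drugs labelled random
  dr0 <- simulate_drugs(g, dis, n_proximal = 0, n_random = 5,
                        targets_per_drug = 3, seed = 4)
  expect_true(all(dr0$drug_class == "random"))

  # determinism
  dr2 <- simulate_drugs(g, dis, 20, 20, 4, seed = 3)
  expect_identical(dr$drug_targets, dr2$drug_targets)
})
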