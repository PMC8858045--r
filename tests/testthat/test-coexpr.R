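test_that("TOM closed forms hold for two-gene and equal-triangle adjacencies", {
  # two genes, single edge weight a: TOM_12 = a
  for (a in c(0.1, 0.5, 0.9)) {
    A <- matrix(c(0, a, a, 0), 2, 2)
    tom <- tom_from_adjacency(A)
    expect_equal(tom[1, 2], a)
    expect_equal(diag(tom), c(1, 1))
  }
  # triangle with all adjacencies a: TOM_ij = (a^2 + a) / (a + 1) = a
  for (a in c(0.1, 0.5, 0.9)) {
    A <- matrix(a, 3, 3); diag(A) <- 0
    tom <- tom_from_adjacency(A)
    expect_equal(tom[1, 2], a, tolerance = 1e-12)
    expect_equal(tom[2, 3], a, tolerance = 1e-12)
  }
})

test_that("TOM matches the brute-force oracle and stays in [0,1]", {
  set.seed(10)
  for (n in c(10, 20, 30)) {
    C <- cor(matrix(rnorm(n * 15), 15, n))
    A <- abs(C)^4
    diag(A) <- 0
    tom <- tom_from_adjacency(A)
    expect_equal(tom, tom_oracle(A), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("build_matrices enforces its invariants", {
  sim <- make_two_module_expr()
  mats <- build_matrices(sim$expr, power = 6)
  expect_equal(mats$adjacency,
               {A <- abs(mats$correlation)^6; diag(A) <- 0; A})
  expect_equal(mats$dissimilarity, 1 - mats$tom,
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_equal(unname(diag(mats$dissimilarity)), rep(0, nrow(mats$tom)))

  # constant gene is a named error
  v <- sim$expr$values
  v["G0001", ] <- 3
  expect_error(build_matrices(dg_expression(v, sim$expr$condition), 6),
               "G0001")
})

test_that("soft-threshold scan is gene-order invariant and honors forced choice", {
  sim <- make_two_module_expr(n_per_module = 20, n_bg = 10)
  expr <- sim$expr
  sft <- suppressWarnings(pick_soft_threshold(expr, powers = c(2, 4, 6)))

  set.seed(3)
  perm <- sample(nrow(expr$values))
  expr_p <- dg_expression(expr$values[perm, ], expr$condition)
  sft_p <- suppressWarnings(pick_soft_threshold(expr_p, powers = c(2, 4, 6)))
  expect_equal(sft$table, sft_p$table)
  expect_equal(sft$chosen_power, sft_p$chosen_power)

  # singleton grid: that power is chosen; warning flag iff below cutoff
  one <- suppressWarnings(pick_soft_threshold(expr, powers = 5,
                                              r2_cutoff = 0.999))
  expect_equal(one$chosen_power, 5)
  expect_true(one$no_qualifier)
  one2 <- suppressWarnings(pick_soft_threshold(expr, powers = 5,
                                               r2_cutoff = 0))
  expect_equal(one2$chosen_power, 5)
  expect_false(one2$no_qualifier)
})

test_that("module detection recovers planted modules and merges shared factors", {
  sim <- make_two_module_expr(n_per_module = 35, n_bg = 30, seed = 9)
  sft_power <- 8
  mats <- build_matrices(sim$expr, sft_power)
  det <- detect_modules(mats, sim$expr, min_size = 20)
  mog <- det$partition$module_of_gene
  mods <- setdiff(unique(mog), "unassigned")
  expect_equal(length(mods), 2)
  # each detected module is dominated by one planted module
  for (m in mods) {
    tr <- sim$truth$module_of_gene[names(mog)[mog == m]]
    expect_gte(max(table(tr)) / length(tr), 0.85)
  }

  # two planted modules driven by one shared factor merge into one module
  set.seed(21)
  n_s <- 20
  f <- rnorm(n_s)
  vals <- rbind(
    matrix(0.9 * rep(f, each = 40) + rnorm(40 * n_s, sd = 0.3), 40),
    matrix(0.9 * rep(f, each = 40) + rnorm(40 * n_s, sd = 0.3), 40),
    matrix(rnorm(60 * n_s), 60))
  dimnames(vals) <- list(sprintf("G%03d", 1:140), sprintf("S%02d", 1:n_s))
  expr2 <- dg_expression(vals)
  det2 <- detect_modules(build_matrices(expr2, 6), expr2, min_size = 20)
  expect_equal(setdiff(unique(det2$partition$module_of_gene), "unassigned"),
               "M1")
  expect_gte(sum(det2$partition$module_of_gene == "M1"), 75)

  # impossible min_size errors
  expect_error(detect_modules(mats, sim$expr, min_size = 10000),
               "unassigned")
})

test_that("module labels are canonical under gene input order", {
  sim <- make_two_module_expr(n_per_module = 30, n_bg = 20, seed = 4)
  mats <- build_matrices(sim$expr, 8)
  det <- detect_modules(mats, sim$expr, min_size = 20)

  set.seed(8)
  perm <- sample(nrow(sim$expr$values))
  expr_p <- dg_expression(sim$expr$values[perm, ], sim$expr$condition)
  mats_p <- build_matrices(expr_p, 8)
  det_p <- detect_modules(mats_p, expr_p, min_size = 20)
  a <- det$partition$module_of_gene
  b <- det_p$partition$module_of_gene[names(a)]
  expect_equal(a, b)
})

test_that("eigengenes have unit norm and sign aligned with the module mean", {
  sim <- make_two_module_expr(seed = 6)
  mats <- build_matrices(sim$expr, 8)
  det <- detect_modules(mats, sim$expr, min_size = 20)
  me <- det$eigengenes$eigengenes
  mog <- det$partition$module_of_gene
  for (m in colnames(me)) {
    expect_equal(sum(me[, m]^2), 1)
    xs <- t(scale(t(sim$expr$values[names(mog)[mog == m], ])))
    expect_gte(cor(me[, m], colMeans(xs)), 0)
  }
  expect_true(all(det$eigengenes$var_explained > 0 &
                  det$eigengenes$var_explained <= 1))
})

test_that("module-trait statistics behave at their boundary cases", {
  # eigengene equal to the condition indicator: r = 1, tiny p
  cond <- rep(c("control", "case"), each = 6)
  me <- matrix(scale(as.numeric(cond == "case")), 12, 1,
               dimnames = list(sprintf("S%02d", 1:12), "M1"))
  mog <- setNames(rep("M1", 10), sprintf("G%02d", 1:10))
  tt <- module_trait_stats(me, cond, disease_genes = character(0),
                           partition = mog)
  expect_equal(tt$pearson_r, 1)
  expect_lt(tt$p_corr, 1e-6)
  # module disjoint from disease genes: P(X >= 0) = 1
  expect_equal(tt$p_overlap, 1)
  expect_gte(tt$fdr_diff, tt$p_diff)

  # overlap example: universe 10, disease 5, module 4, overlap 4
  mog2 <- setNames(c(rep("M1", 4), rep("unassigned", 6)), paste0("g", 1:10))
  me2 <- matrix(me[, 1], 12, 1,
                dimnames = list(rownames(me), "M1"))
  tt2 <- module_trait_stats(me2, cond, disease_genes = paste0("g", 1:5),
                            partition = mog2)
  expect_equal(tt2$overlap_count, 4)
  expect_equal(tt2$p_overlap, 5 / 210)
  expect_equal(tt2$p_overlap, hyper_enum_p(4, 5, 10, 4))
})

test_that("disease-module selection applies the triple criterion", {
  tab <- data.frame(module = c("M1", "M2", "M3"),
                    p_corr = c(0.01, 0.2, 0.01),
                    fdr_diff = c(0.01, 0.01, 0.01),
                    p_overlap = c(0.01, 0.01, 0.5))
  expect_equal(select_disease_modules(tab), "M1")
})
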