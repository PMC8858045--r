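# Weighted co-expression core: soft-threshold scan against scale-free
# topology, powered adjacency, topological overlap, average-linkage module
# detection with eigengene merging, and module-trait statistics.

gene_correlation <- function(expr) {
  v <- expr$values
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    stop("constant gene(s): ",
         paste(rownames(v)[sds == 0][1:min(3, sum(sds == 0))], collapse = ", "))
  }
  stats::cor(t(v))
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  n_distinct <- length(unique(k))
  if (n_distinct < n_bins) {
    warning("fewer than ", n_bins, " distinct connectivity values; ",
            "reducing bin count")
    n_bins <- max(2, n_distinct)
  }
  # equal-width bins over the connectivity range (the standard scale-free
  # fit index binning); empty bins are dropped before the regression
  breaks <- unique(seq(min(k), max(k), length.out = n_bins + 1))
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & kmean > 0
  df <- data.frame(x = log10(kmean[keep]), y = log10(freq[keep]))
  if (nrow(df) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(y ~ x, data = df)
  list(r2 = summary(fit)$r.squared, slope = stats::coef(fit)[["x"]])
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power beta the adjacency `A = |cor|^beta` is formed and
#' the connectivity `k_i = sum_j A_ij` (diagonal excluded) computed. The
#' degree distribution is binned and
#' `log10(frequency)` regressed on `log10(mean k)` over 10 bins; the signed fit is
#' `R^2 * sign(-slope)`, positive only when frequency decays with
#' connectivity as a scale-free topology requires. Binning is equal-width
#' over the connectivity range. The chosen power is the
#' smallest with signed R^2 at or above `r2_cutoff`; if none qualifies the
#' best-fitting power is returned with a warning flag.
#'
#' @param expr A [dg_expression()] with at least 3 samples.
#' @param powers Candidate integer powers. The default grid extends to 30:
#'   unsigned networks built from few samples (under ~20) carry strong
#'   baseline correlation noise and routinely need powers above 20 to reach
#'   scale-free topology.
#' @param r2_cutoff Signed R^2 required to accept a power (default 0.85).
#' @return List of class `dg_sft`: `table` (power, signed R^2, slope, mean
#'   connectivity), `chosen_power`, `r2_cutoff`, `no_qualifier` flag.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, seq(12, 30, 2)),
                                r2_cutoff = 0.85) {
  stopifnot(inherits(expr, "dg_expr"), length(powers) >= 1)
  if (ncol(expr$values) < 3) stop("need at least 3 samples")
  C <- gene_correlation(expr)
  absC <- abs(C)
  diag(absC) <- 0
  rows <- lapply(powers, function(p) {
    A <- absC^p
    k <- colSums(A)
    fit <- scale_free_fit(k)
    data.frame(power = p,
               r2_signed = if (is.na(fit$r2)) NA_real_
                           else fit$r2 * sign(-fit$slope),
               slope = fit$slope,
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r2_signed) & tab$r2_signed >= r2_cutoff)
  if (length(ok) > 0) {
    chosen <- tab$power[ok[1]]
    no_qualifier <- FALSE
  } else {
    chosen <- tab$power[which.max(tab$r2_signed)]
    no_qualifier <- TRUE
    warning("no power reached signed R^2 >= ", r2_cutoff,
            "; returning the best fit (power ", chosen, ")")
  }
  structure(list(table = tab, chosen_power = chosen,
                 r2_cutoff = r2_cutoff, no_qualifier = no_qualifier),
            class = "dg_sft")
}

#' Build correlation, adjacency, TOM and dissimilarity matrices
#'
#' `C` is the gene-gene Pearson correlation across samples; the weighted
#' adjacency is `A = |C|^power` with its diagonal set to zero so that
#' connectivity sums exclude self-adjacency. The unsigned topological overlap
#' is
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` for
#' `i != j` and `TOM_ii = 1`; the clustering input is `1 - TOM`.
#'
#' @param expr A [dg_expression()]; genes must be non-constant.
#' @param power Integer soft-thresholding power (>= 1).
#' @return List of class `dg_coexpr` with matrices `correlation`,
#'   `adjacency`, `tom`, `dissimilarity` and the `power` used.
#' @export
build_matrices <- function(expr, power) {
  stopifnot(inherits(expr, "dg_expr"), power >= 1)
  C <- gene_correlation(expr)
  A <- abs(C)^power
  diag(A) <- 0
  tom <- tom_from_adjacency(A)
  diss <- 1 - tom
  diag(diss) <- 0
  structure(list(correlation = C, adjacency = A, tom = tom,
                 dissimilarity = diss, power = power),
            class = "dg_coexpr")
}

#' Topological overlap from a weighted adjacency matrix
#'
#' Unsigned topological overlap:
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` for
#' `i != j` with `TOM_ii = 1`, where `k_i` is node i's connectivity. Values
#' stay in \[0, 1\] whenever the adjacency does.
#'
#' @param A Symmetric numeric matrix with entries in \[0, 1\]; the diagonal
#'   is ignored (treated as 0).
#' @return The TOM matrix, same dimnames as `A`.
#' @export
tom_from_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  diag(A) <- 0
  k <- colSums(A)
  L <- A %*% A                       # shared-neighbor term sum_u A_iu A_uj
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

# Recursive static cut: average-linkage clustering cut at
# frac * max merge height, re-applied within each resulting cluster until
# clusters are small (< 2 * min_size) or depth runs out. Over-splitting is
# harmless because the eigengene merge reunites fragments that share a
# latent factor; a single top-level cut, in contrast, glues distinct modules
# together at low soft powers where baseline correlation noise is strong.
static_cut_recursive <- function(diss, frac, min_size, depth) {
  members <- rownames(diss)
  if (depth == 0 || length(members) < 2 * min_size) return(list(members))
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (max(hc$height) <= 0) return(list(members))
  cl <- stats::cutree(hc, h = frac * max(hc$height))
  parts <- split(members, cl)
  if (length(parts) < 2) return(list(members))
  unlist(lapply(parts, function(m) {
    static_cut_recursive(diss[m, m, drop = FALSE], frac, min_size, depth - 1)
  }), recursive = FALSE)
}

# First principal component of the scaled module expression: the module
# eigengene. Unit norm; sign aligned with the module's mean scaled profile.
module_eigengenes <- function(expr, module_of_gene) {
  labels <- setdiff(unique(module_of_gene), "unassigned")
  labels <- sort(labels)
  v <- expr$values
  me <- matrix(NA_real_, ncol(v), length(labels),
               dimnames = list(colnames(v), labels))
  varexp <- setNames(numeric(length(labels)), labels)
  for (m in labels) {
    genes <- names(module_of_gene)[module_of_gene == m]
    xs <- t(scale(t(v[genes, , drop = FALSE])))
    xs[!is.finite(xs)] <- 0
    s <- svd(xs, nu = 0, nv = 1)
    e <- s$v[, 1]
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    me[, m] <- e
    varexp[m] <- s$d[1]^2 / sum(s$d^2)
  }
  list(eigengenes = me, var_explained = varexp)
}

#' Detect co-expression modules by average-linkage clustering of 1 - TOM
#'
#' Genes are clustered by average-linkage agglomeration of the TOM
#' dissimilarity and the dendrogram cut at
#' `cut_height_fraction * max merge height`; the same cut is re-applied
#' recursively inside each resulting cluster (up to `split_depth` levels,
#' stopping once a cluster is smaller than twice `min_size`), which resolves
#' modules that a single top-level cut leaves glued together when the soft
#' power is low. Provisional clusters whose
#' eigengene dissimilarity (1 - Pearson correlation) falls below `merge_cut`
#' are then merged iteratively, closest pair first, with eigengenes
#' recomputed after each merge; the merge runs before the size filter so
#' that over-split fragments sharing a latent factor are reassembled rather
#' than discarded. Clusters still smaller than `min_size` become
#' `"unassigned"`. Final labels are `M1`, `M2`, ...
#' in decreasing size order (ties broken by the alphabetically first member),
#' which makes them invariant to gene input order.
#'
#' @param coexpr A `dg_coexpr` from [build_matrices()] (or any symmetric
#'   dissimilarity matrix).
#' @param expr The [dg_expression()] the matrices came from.
#' @param min_size Minimum module size (default 30).
#' @param cut_height_fraction Static cut as a fraction of the maximum merge
#'   height (default 0.99).
#' @param merge_cut Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param split_depth Maximum recursion depth of the static cut (default 10;
#'   recursion stops earlier once clusters fall below `2 * min_size`).
#' @return List with `partition` (named label vector `module_of_gene` plus
#'   the parameters) and `eigengenes` (samples x modules matrix,
#'   variance-explained fractions).
#' @export
detect_modules <- function(coexpr, expr, min_size = 30,
                           cut_height_fraction = 0.99, merge_cut = 0.25,
                           split_depth = 10) {
  diss <- if (inherits(coexpr, "dg_coexpr")) coexpr$dissimilarity else coexpr
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  genes <- rownames(diss)
  parts <- static_cut_recursive(diss, cut_height_fraction, min_size,
                                split_depth)
  assignment <- setNames(rep(NA_character_, length(genes)), genes)
  for (i in seq_along(parts)) assignment[parts[[i]]] <- as.character(i)

  # iterative eigengene merging of the provisional clusters, closest pair
  # first; running it before the size filter reassembles fragmented modules
  es <- module_eigengenes(expr, assignment)
  me <- es$eigengenes
  repeat {
    if (ncol(me) < 2) break
    dm <- 1 - stats::cor(me)
    dm[is.na(dm)] <- Inf
    diag(dm) <- Inf
    i <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    if (dm[i[1], i[2]] >= merge_cut) break
    to <- colnames(dm)[i[1]]
    from <- colnames(dm)[i[2]]
    assignment[assignment == from] <- to
    merged <- module_eigengenes(expr, assignment[assignment == to])
    me <- me[, setdiff(colnames(me), from), drop = FALSE]
    me[, to] <- merged$eigengenes[, to]
  }

  sizes <- table(assignment)
  small <- names(sizes)[sizes < min_size]
  assignment[assignment %in% small] <- "unassigned"
  if (all(assignment == "unassigned")) {
    stop("all genes unassigned: lower min_size or raise the cut height")
  }

  # canonical size-ranked labels
  mods <- setdiff(unique(assignment), "unassigned")
  sizes <- vapply(mods, function(m) sum(assignment == m), integer(1))
  first_gene <- vapply(mods, function(m) {
    min(names(assignment)[assignment == m])
  }, character(1))
  ord <- order(-sizes, first_gene)
  relabel <- setNames(sprintf("M%d", seq_along(mods)), mods[ord])
  assignment[assignment != "unassigned"] <-
    relabel[assignment[assignment != "unassigned"]]

  es <- module_eigengenes(expr, assignment)
  list(partition = list(module_of_gene = assignment, min_size = min_size,
                        merge_cut = merge_cut,
                        cut_height_fraction = cut_height_fraction),
       eigengenes = es)
}

#' Module-trait statistics
#'
#' For each module: Pearson correlation of the eigengene with the 0/1
#' condition (two-sided p from the t transform), a two-sided Wilcoxon
#' rank-sum test of eigengene values in cases versus controls
#' (Benjamini-Hochberg corrected across modules), and the upper-tail
#' hypergeometric p-value of the module's overlap with a known disease gene
#' set given the gene universe.
#'
#' @param eigengenes Samples x modules eigengene matrix (or the list from
#'   [detect_modules()]).
#' @param condition Per-sample `"case"`/`"control"` labels.
#' @param disease_genes Character vector of known disease genes.
#' @param partition Partition list (or named `module_of_gene` vector).
#' @param universe Optional character vector of universe genes; defaults to
#'   all genes in the partition (including unassigned ones).
#' @return Data frame with one row per module: `pearson_r`, `p_corr`,
#'   `diff_stat`, `p_diff`, `fdr_diff`, `overlap_count`, `p_overlap`.
#' @export
module_trait_stats <- function(eigengenes, condition, disease_genes,
                               partition, universe = NULL) {
  me <- if (is.list(eigengenes) && !is.null(eigengenes$eigengenes)) {
    eigengenes$eigengenes
  } else eigengenes
  mog <- if (is.list(partition) && !is.null(partition$module_of_gene)) {
    partition$module_of_gene
  } else partition
  condition <- check_condition(condition, nrow(me))
  y <- as.numeric(condition == "case")
  if (is.null(universe)) universe <- names(mog)
  disease_u <- intersect(disease_genes, universe)
  N <- length(universe)
  K <- length(disease_u)

  mods <- colnames(me)
  n <- nrow(me)
  out <- lapply(mods, function(m) {
    e <- me[, m]
    if (sd(e) == 0) {
      r <- NA_real_; p_corr <- NA_real_
    } else {
      r <- stats::cor(e, y)
      p_corr <- cor_test_p(r, n)
    }
    wt <- suppressWarnings(stats::wilcox.test(e[y == 1], e[y == 0],
                                              exact = FALSE))
    members <- intersect(names(mog)[mog == m], universe)
    k <- length(intersect(members, disease_u))
    data.frame(module = m, size = length(members), pearson_r = r,
               p_corr = p_corr, diff_stat = unname(wt$statistic),
               p_diff = wt$p.value, overlap_count = k,
               p_overlap = hyper_upper_p(k, K, N, length(members)))
  })
  tab <- do.call(rbind, out)
  tab$fdr_diff <- bh_fdr(tab$p_diff)
  tab[, c("module", "size", "pearson_r", "p_corr", "diff_stat", "p_diff",
          "fdr_diff", "overlap_count", "p_overlap")]
}

#' Select disease-associated modules by the triple criterion
#'
#' A module is disease-associated when its eigengene-condition correlation is
#' significant (`p_corr < alpha`), its case/control eigengene difference
#' survives FDR correction (`fdr_diff < fdr_cutoff`), and it is significantly
#' enriched for known disease genes (`p_overlap < alpha`).
#'
#' @param trait_table Output of [module_trait_stats()].
#' @param alpha Significance level for correlation and overlap (default 0.05).
#' @param fdr_cutoff FDR level for the group-difference test (default 0.05).
#' @return Character vector of selected module labels.
#' @export
select_disease_modules <- function(trait_table, alpha = 0.05,
                                   fdr_cutoff = 0.05) {
  sel <- !is.na(trait_table$p_corr) & trait_table$p_corr < alpha &
    trait_table$fdr_diff < fdr_cutoff & trait_table$p_overlap < alpha
  sort(trait_table$module[sel])
}
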