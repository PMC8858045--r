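# Over-representation analysis and the core-gene filter (module membership
# kME and per-gene ROC AUC).

#' Over-representation analysis against a gene set collection
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set and
#' each set in a collection, with Benjamini-Hochberg correction across the
#' collection. Query members outside the universe are dropped (and counted);
#' each collection set is intersected with the universe before testing.
#'
#' @param query Character vector of query genes.
#' @param collection Named list of character vectors (e.g. from
#'   [read_gene_sets_gmt()]).
#' @param universe Character vector of background genes.
#' @return Data frame sorted by p-value with columns `set`, `set_size`,
#'   `overlap`, `expected`, `p`, `fdr`, `genes` (comma-separated overlap).
#'   Attribute `n_query_dropped` counts query genes outside the universe.
#' @export
ora <- function(query, collection, universe) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  query <- unique(query)
  universe <- unique(universe)
  dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  if (length(query) == 0) stop("query is empty after universe filtering")
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    ov <- intersect(query, s)
    data.frame(set = nm, set_size = length(s), overlap = length(ov),
               expected = q * length(s) / N,
               p = hyper_upper_p(length(ov), length(s), N, q),
               genes = paste(sort(ov), collapse = ","))
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_fdr(tab$p)
  tab <- tab[order(tab$p, tab$set), c("set", "set_size", "overlap",
                                      "expected", "p", "fdr", "genes")]
  rownames(tab) <- NULL
  attr(tab, "n_query_dropped") <- dropped
  tab
}

#' Per-gene two-class ranking AUC
#'
#' Mann-Whitney AUC of a single gene's expression for case versus control,
#' with ties counted one half, oriented as `max(auc, 1 - auc)` so that both
#' over- and under-expressed markers score above 0.5.
#'
#' @param x Numeric expression vector over samples.
#' @param condition Per-sample `"case"`/`"control"` labels.
#' @return AUC in \[0.5, 1\].
#' @export
gene_auc <- function(x, condition) {
  condition <- check_condition(condition, length(x))
  if (!any(condition == "case") || !any(condition == "control")) {
    stop("both classes must be non-empty")
  }
  a <- rank_auc(x[condition == "case"], x[condition == "control"])
  max(a, 1 - a)
}

#' Select core genes by module membership and discriminative AUC
#'
#' Restricted to genes in the given disease modules, computes each gene's
#' module membership kME (Pearson correlation with its own module's
#' eigengene) and its two-class AUC; a gene is selected when `|kME|` exceeds
#' `kme_cutoff` and AUC exceeds `auc_cutoff`.
#'
#' @param expr A [dg_expression()] with condition labels.
#' @param partition Partition list or named `module_of_gene` vector.
#' @param eigengenes Eigengene matrix (or [detect_modules()] output element).
#' @param disease_modules Module labels to restrict to; default all modules.
#' @param kme_cutoff Module-membership threshold (default 0.7).
#' @param auc_cutoff AUC threshold (default 0.8).
#' @return Data frame (ordered by module then gene) with `gene`, `module`,
#'   `kme`, `auc`, `selected`.
#' @export
select_core_genes <- function(expr, partition, eigengenes,
                              disease_modules = NULL,
                              kme_cutoff = 0.7, auc_cutoff = 0.8) {
  stopifnot(inherits(expr, "dg_expr"))
  condition <- check_condition(expr$condition, ncol(expr$values))
  mog <- if (is.list(partition) && !is.null(partition$module_of_gene)) {
    partition$module_of_gene
  } else partition
  me <- if (is.list(eigengenes) && !is.null(eigengenes$eigengenes)) {
    eigengenes$eigengenes
  } else eigengenes
  if (is.null(disease_modules)) {
    disease_modules <- setdiff(unique(mog), "unassigned")
  }
  genes <- names(mog)[mog %in% disease_modules]
  genes <- intersect(genes, rownames(expr$values))
  if (length(genes) == 0) stop("no genes in the given modules")
  rows <- lapply(genes, function(g) {
    m <- mog[[g]]
    x <- expr$values[g, ]
    kme <- if (sd(x) == 0) NA_real_ else stats::cor(x, me[, m])
    data.frame(gene = g, module = m, kme = kme,
               auc = gene_auc(x, condition))
  })
  tab <- do.call(rbind, rows)
  tab$selected <- !is.na(tab$kme) & abs(tab$kme) > kme_cutoff &
    tab$auc > auc_cutoff
  tab <- tab[order(tab$module, tab$gene), ]
  rownames(tab) <- NULL
  tab
}
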