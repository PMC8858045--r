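# Disease-specific interactome statistics: induced subnetworks, degree
# ranking, degree-ranked GSEA, per-candidate disease-neighborhood statistics
# with permutation nulls, and key-gene selection.

#' Induce a subnetwork on a gene set
#'
#' Subgraph on the intersection of `genes` with the network's nodes; nodes
#' left without any edge are dropped and counted (mirroring the usual loss of
#' unconnected genes when mapping a gene list onto an interactome).
#'
#' @param network An `igraph` graph with named nodes.
#' @param genes Character vector of gene names.
#' @return The induced `igraph` subgraph; attribute `n_isolated_dropped`
#'   counts removed isolated nodes, `n_missing` genes absent from the
#'   network.
#' @export
induce_subnetwork <- function(network, genes) {
  nodes <- igraph::V(network)$name
  present <- intersect(genes, nodes)
  if (length(present) == 0) stop("none of the genes are in the network")
  sub <- igraph::induced_subgraph(network, present)
  iso <- igraph::V(sub)$name[igraph::degree(sub) == 0]
  sub <- igraph::delete_vertices(sub, iso)
  if (igraph::vcount(sub) == 0) {
    stop("no edges among the given genes (all nodes isolated)")
  }
  attr(sub, "n_isolated_dropped") <- length(iso)
  attr(sub, "n_missing") <- length(genes) - length(present)
  sub
}

#' Rank network nodes by degree
#'
#' @param network A non-empty `igraph` graph with named nodes.
#' @return Data frame `gene`, `degree`, ordered by decreasing degree with
#'   alphabetical tie-break.
#' @export
degree_rank <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network")
  d <- igraph::degree(network)
  tab <- data.frame(gene = names(d), degree = as.integer(d))
  tab <- tab[order(-tab$degree, tab$gene), ]
  rownames(tab) <- NULL
  tab
}

# Weighted Kolmogorov-Smirnov running sum over a ranked list. Hits increment
# |score|^weight_p (normalized by the in-set sum); misses decrement
# 1/(N - set size). ES is the maximum signed deviation from zero.
gsea_es <- function(in_set, scores, weight_p) {
  N <- length(in_set)
  nh <- sum(in_set)
  w <- abs(scores)^weight_p
  nr <- sum(w[in_set])
  step <- ifelse(in_set,
                 if (nr > 0) w / nr else 1 / max(nh, 1),
                 -1 / (N - nh))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Preranked gene set enrichment analysis
#'
#' Classic running-sum GSEA on a ranked list (here typically node degree):
#' the enrichment score is the extreme deviation of the weighted running sum;
#' the null is built by permuting gene labels (`n_perm` draws of random
#' member positions), the p-value is one-plus-corrected among same-sign null
#' scores, NES divides ES by the mean same-sign null magnitude, and FDR is
#' Benjamini-Hochberg across sets.
#'
#' @param ranks Data frame `gene`/`score` (e.g. [degree_rank()] with `degree`
#'   as score) or a named numeric vector. Ordered by decreasing score with
#'   alphabetical tie-break.
#' @param collection Named list of gene sets.
#' @param n_perm Number of label permutations (default 1000).
#' @param weight_p Running-sum weight exponent (default 1).
#' @param seed Integer seed.
#' @return Data frame `set`, `size`, `es`, `nes`, `p_perm`, `fdr`; sets with
#'   no members in the ranked universe are skipped with a warning.
#' @export
preranked_gsea <- function(ranks, collection, n_perm = 1000, weight_p = 1,
                           seed = 1) {
  if (is.data.frame(ranks)) {
    score_col <- setdiff(colnames(ranks), "gene")[1]
    scores <- setNames(as.numeric(ranks[[score_col]]), ranks$gene)
  } else {
    scores <- ranks
  }
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  genes <- names(scores)
  N <- length(genes)
  set.seed(seed)
  rows <- list()
  for (nm in names(collection)) {
    members <- intersect(collection[[nm]], genes)
    nh <- length(members)
    if (nh == 0) {
      warning("gene set '", nm, "' has no members in the ranked list; skipped")
      next
    }
    if (nh == N) {
      warning("gene set '", nm, "' covers the whole ranked list; skipped")
      next
    }
    in_set <- genes %in% members
    es <- gsea_es(in_set, scores, weight_p)
    null_es <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(N, nh)
      hit <- logical(N)
      hit[idx] <- TRUE
      gsea_es(hit, scores, weight_p)
    }, numeric(1))
    same <- null_es * sign(es) > 0
    p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + n_perm)
    nes <- if (any(same)) es / mean(abs(null_es[same])) else NA_real_
    rows[[nm]] <- data.frame(set = nm, size = nh, es = es, nes = nes,
                             p_perm = p)
  }
  if (length(rows) == 0) stop("no usable gene sets")
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_fdr(tab$p_perm)
  rownames(tab) <- NULL
  tab
}

#' Disease-neighborhood statistics per candidate node
#'
#' For every candidate node in a class-labelled network (vertex attribute
#' `class` in disease/candidate/other): degree, disease-neighbor count and
#' ratio, an analytic upper-tail hypergeometric p-value for the neighbor
#' count (drawing `degree` neighbors from the other `N - 1` nodes of which
#' `K` are disease), mean shortest-path length to reachable disease nodes and
#' to reachable other candidates, their ratio, and permutation p-values from
#' a class-shuffling null: node class labels of all non-focal nodes are
#' permuted (class counts fixed, degrees untouched) `n_perm` times and the
#' interaction ratio (upper tail) and shortest-path ratio (lower tail)
#' recomputed for the focal node, with the one-plus rule so p is never zero.
#' Class shuffling keeps every degree fixed and isolates the class signal;
#' `null = "rewire"` instead randomizes the wiring with degree-preserving
#' edge swaps while classes stay put.
#' `degree_percentile` is the fraction of all network nodes with degree at or
#' below the candidate's. Unreachable targets are excluded from shortest-path
#' means and counted.
#'
#' @param network An `igraph` graph with vertex attributes `name` and
#'   `class`; needs >= 1 disease and >= 2 candidate nodes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param null Null model: `"class_shuffle"` (default) permutes node class
#'   labels with class counts fixed; `"rewire"` applies degree-preserving
#'   edge swaps to the graph with classes fixed.
#' @return Data frame with one row per candidate: `gene`, `degree`,
#'   `disease_neighbor_count`, `interaction_ratio`, `p_count_hyper`,
#'   `p_ratio_perm`, `mean_sp_disease`, `mean_sp_candidate`,
#'   `shortest_ratio`, `p_shortest_perm`, `degree_percentile`,
#'   `n_unreachable`. Isolated candidates carry `NA` statistics.
#' @export
node_disease_stats <- function(network, n_perm = 1000, seed = 1,
                               null = c("class_shuffle", "rewire")) {
  null <- match.arg(null)
  cls <- igraph::vertex_attr(network, "class")
  if (is.null(cls)) stop("network needs a 'class' vertex attribute")
  nodes <- igraph::V(network)$name
  names(cls) <- nodes
  n_dis <- sum(cls == "disease")
  cand <- nodes[cls == "candidate"]
  if (n_dis < 1 || length(cand) < 2) {
    stop("need >= 1 disease and >= 2 candidate nodes")
  }
  N <- length(nodes)
  deg <- igraph::degree(network)
  D <- igraph::distances(network)
  set.seed(seed)

  sp_mean <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }

  # observed statistics per candidate
  obs <- lapply(cand, function(v) {
    others <- setdiff(nodes, v)
    cls_o <- cls[others]
    drow <- D[v, others]
    nb <- others %in% igraph::neighbors(network, v)$name
    d_v <- unname(deg[v])
    if (d_v == 0) {
      return(list(gene = v, degree = 0L, dnc = NA_integer_,
                  ratio = NA_real_, p_count = NA_real_, msd = NA_real_,
                  msc = NA_real_, sr = NA_real_, n_unreach = NA_integer_,
                  others = others, cls_o = cls_o, drow = drow, nb = nb))
    }
    dnc <- sum(nb & cls_o == "disease")
    is_dis <- cls_o == "disease"
    is_cand <- cls_o == "candidate"
    msd <- sp_mean(drow[is_dis])
    msc <- sp_mean(drow[is_cand])
    list(gene = v, degree = as.integer(d_v), dnc = as.integer(dnc),
         ratio = dnc / d_v, p_count = hyper_upper_p(dnc, n_dis, N - 1, d_v),
         msd = msd, msc = msc,
         sr = if (is.na(msd) || is.na(msc) || msc == 0) NA_real_
              else msd / msc,
         n_unreach = sum(!is.finite(drow[is_dis | is_cand])),
         others = others, cls_o = cls_o, drow = drow, nb = nb)
  })
  names(obs) <- cand

  cnt_ratio <- setNames(integer(length(cand)), cand)
  cnt_sr <- setNames(integer(length(cand)), cand)
  n_sr_valid <- setNames(integer(length(cand)), cand)

  if (null == "class_shuffle") {
    for (o in obs) {
      if (o$degree == 0) next
      n_o <- length(o$others)
      for (b in seq_len(n_perm)) {
        perm <- o$cls_o[sample.int(n_o)]
        pd <- perm == "disease"
        if (sum(o$nb & pd) / o$degree >= o$ratio) {
          cnt_ratio[o$gene] <- cnt_ratio[o$gene] + 1L
        }
        if (!is.na(o$sr)) {
          msd_b <- sp_mean(o$drow[pd])
          msc_b <- sp_mean(o$drow[perm == "candidate"])
          if (!is.na(msd_b) && !is.na(msc_b) && msc_b > 0) {
            n_sr_valid[o$gene] <- n_sr_valid[o$gene] + 1L
            if (msd_b / msc_b <= o$sr) cnt_sr[o$gene] <- cnt_sr[o$gene] + 1L
          }
        }
      }
    }
  } else {
    dis_nodes <- nodes[cls == "disease"]
    for (b in seq_len(n_perm)) {
      gb <- igraph::rewire(network,
                           igraph::keeping_degseq(niter = 10 * igraph::ecount(network)))
      Db <- igraph::distances(gb, v = cand, to = igraph::V(gb))
      for (o in obs) {
        if (o$degree == 0) next
        nb_b <- igraph::neighbors(gb, o$gene)$name
        if (sum(nb_b %in% dis_nodes) / o$degree >= o$ratio) {
          cnt_ratio[o$gene] <- cnt_ratio[o$gene] + 1L
        }
        if (!is.na(o$sr)) {
          drow_b <- Db[o$gene, setdiff(nodes, o$gene)]
          cls_b <- cls[setdiff(nodes, o$gene)]
          msd_b <- sp_mean(drow_b[cls_b == "disease"])
          msc_b <- sp_mean(drow_b[cls_b == "candidate"])
          if (!is.na(msd_b) && !is.na(msc_b) && msc_b > 0) {
            n_sr_valid[o$gene] <- n_sr_valid[o$gene] + 1L
            if (msd_b / msc_b <= o$sr) cnt_sr[o$gene] <- cnt_sr[o$gene] + 1L
          }
        }
      }
    }
  }

  rows <- lapply(obs, function(o) {
    if (o$degree == 0) {
      return(data.frame(gene = o$gene, degree = 0L,
                        disease_neighbor_count = NA_integer_,
                        interaction_ratio = NA_real_,
                        p_count_hyper = NA_real_, p_ratio_perm = NA_real_,
                        mean_sp_disease = NA_real_,
                        mean_sp_candidate = NA_real_,
                        shortest_ratio = NA_real_,
                        p_shortest_perm = NA_real_,
                        degree_percentile = mean(deg <= 0),
                        n_unreachable = NA_integer_))
    }
    data.frame(gene = o$gene, degree = o$degree,
               disease_neighbor_count = o$dnc,
               interaction_ratio = o$ratio, p_count_hyper = o$p_count,
               p_ratio_perm = (1 + cnt_ratio[[o$gene]]) / (1 + n_perm),
               mean_sp_disease = o$msd, mean_sp_candidate = o$msc,
               shortest_ratio = o$sr,
               p_shortest_perm = if (is.na(o$sr) ||
                                     n_sr_valid[[o$gene]] == 0) NA_real_
                 else (1 + cnt_sr[[o$gene]]) / (1 + n_sr_valid[[o$gene]]),
               degree_percentile = mean(deg <= o$degree),
               n_unreachable = o$n_unreach)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$gene), ]
  rownames(tab) <- NULL
  tab
}

#' Select key genes from disease-network statistics
#'
#' A candidate is a key gene when all four signals agree at level `alpha`:
#' significantly many disease neighbors (analytic hypergeometric),
#' significantly high interaction ratio and significantly low shortest-path
#' ratio (both against the class-permutation null), and a degree in the top
#' `alpha` fraction of the network.
#'
#' @param stats Data frame from [node_disease_stats()] (or any table with the
#'   same columns).
#' @param alpha Significance level (default 0.05).
#' @return Character vector of selected gene names (sorted).
#' @export
select_key_genes <- function(stats, alpha = 0.05) {
  sel <- !is.na(stats$p_ratio_perm) & stats$p_ratio_perm <= alpha &
    !is.na(stats$p_shortest_perm) & stats$p_shortest_perm <= alpha &
    !is.na(stats$p_count_hyper) & stats$p_count_hyper <= alpha &
    !is.na(stats$degree_percentile) & stats$degree_percentile >= 1 - alpha
  sort(stats$gene[sel])
}
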