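# Drug-disease network proximity: weighted closest distance d(S,T), a
# permutation reference distribution of random target sets, the proximity
# z-score, and the FDR drug screen.

# Minimum shortest-path distance from every node to the disease set S, plus
# the per-node omega weight (-ln(degree + 1) for nodes inside S, else 0).
min_dist_to_set <- function(network, S) {
  nodes <- igraph::V(network)$name
  S <- intersect(S, nodes)
  if (length(S) == 0) stop("disease set has no nodes in the network")
  Dm <- igraph::distances(network, v = S, to = igraph::V(network))
  mind <- apply(Dm, 2, min)
  names(mind) <- nodes
  omega <- setNames(numeric(length(nodes)), nodes)
  omega[S] <- -log(igraph::degree(network)[S] + 1)
  list(min_dist = mind, omega = omega, S = S)
}

dist_from_cache <- function(cache, targets) {
  d <- cache$min_dist[targets] + cache$omega[targets]
  d <- d[is.finite(d)]
  if (length(d) == 0) return(list(d = NA_real_, n_valid = 0))
  list(d = mean(d), n_valid = length(d))
}

#' Weighted closest network distance from a drug's targets to a disease set
#'
#' `d(S,T) = (1/|T|) * sum_t [ min_s dist(s, t) + omega_t ]` where the weight
#' `omega_t = -ln(degree(t) + 1)` applies when target t is itself a disease
#' gene and is zero otherwise, rewarding drugs that hit hub disease genes.
#' Targets absent from the network are dropped and counted; targets
#' unreachable from every disease gene are skipped and counted.
#'
#' @param network An `igraph` graph with named nodes.
#' @param disease_set Character vector S of disease gene names.
#' @param targets Character vector T of drug target names.
#' @return The distance (numeric scalar) with attributes `n_valid_targets`,
#'   `n_missing`, `n_unreachable`.
#' @export
drug_distance <- function(network, disease_set, targets) {
  if (length(targets) == 0) stop("empty target set")
  nodes <- igraph::V(network)$name
  present <- intersect(unique(targets), nodes)
  n_missing <- length(unique(targets)) - length(present)
  if (length(present) == 0) stop("no drug target maps to the network")
  cache <- min_dist_to_set(network, disease_set)
  res <- dist_from_cache(cache, present)
  if (res$n_valid == 0) stop("all mapped targets are unreachable from the disease set")
  structure(res$d, n_valid_targets = res$n_valid, n_missing = n_missing,
            n_unreachable = length(present) - res$n_valid)
}

# Null distances for random target sets of a given size (shared machinery
# for proximity_z and screen_drugs). Draws are uniform over network nodes,
# without replacement within a draw. When `degree_bins` is supplied
# (a per-node bin label), each draw matches the observed targets' degree-bin
# profile instead of sampling uniformly.
null_distances <- function(cache, nodes, size, n_perm, degree_bins = NULL,
                           targets = NULL) {
  if (is.null(degree_bins)) {
    return(vapply(seq_len(n_perm), function(b) {
      R <- sample(nodes, size)
      dist_from_cache(cache, R)$d
    }, numeric(1)))
  }
  profile <- table(degree_bins[targets])
  by_bin <- split(nodes, degree_bins)
  vapply(seq_len(n_perm), function(b) {
    R <- unlist(lapply(names(profile), function(bn) {
      sample(by_bin[[bn]], min(profile[[bn]], length(by_bin[[bn]])))
    }), use.names = FALSE)
    dist_from_cache(cache, R)$d
  }, numeric(1))
}

# Degree-decile bin label per node, for degree-matched null sampling.
degree_bin_labels <- function(network) {
  deg <- igraph::degree(network)
  br <- unique(quantile(deg, probs = seq(0, 1, 0.1)))
  if (length(br) < 2) return(setNames(rep("b1", length(deg)), names(deg)))
  setNames(as.character(cut(deg, breaks = br, include.lowest = TRUE)),
           names(deg))
}

proximity_row <- function(d_obs, nulls, n_valid, drug_id = NA_character_,
                          drug_name = NA_character_) {
  nulls <- nulls[!is.na(nulls)]
  mu <- mean(nulls)
  sigma <- sd(nulls)
  z <- if (is.na(sigma) || sigma == 0) NA_real_ else (d_obs - mu) / sigma
  p <- (1 + sum(nulls <= d_obs)) / (1 + length(nulls))
  data.frame(drug_id = drug_id, drug_name = drug_name, d_obs = d_obs,
             mu_null = mu, sigma_null = sigma, z = z, p_emp = p,
             n_valid_targets = n_valid)
}

#' Proximity z-score of a target set against a random-target null
#'
#' Draws `n_perm` uniform node sets of the same size as the mapped target
#' set, computes the reference distribution of `d(S,R)`, and standardizes the
#' observed distance: `z = (d_obs - mu_null) / sigma_null`. The empirical
#' p-value is lower-tailed (smaller distance = closer than random) with the
#' one-plus rule.
#'
#' @param network An `igraph` graph with named nodes.
#' @param disease_set Character vector S.
#' @param targets Character vector T.
#' @param n_perm Null draws (default 1000).
#' @param seed Integer seed.
#' @param degree_matched When `TRUE`, null target sets match the observed
#'   targets' degree-decile profile instead of being drawn uniformly
#'   (default `FALSE`: plain uniform draws).
#' @return One-row data frame: `d_obs`, `mu_null`, `sigma_null`, `z`,
#'   `p_emp`, `n_valid_targets`. `z` is `NA` (flagged) when the null is
#'   degenerate.
#' @export
proximity_z <- function(network, disease_set, targets, n_perm = 1000,
                        seed = 1, degree_matched = FALSE) {
  nodes <- igraph::V(network)$name
  present <- intersect(unique(targets), nodes)
  if (length(present) > length(nodes)) stop("more targets than nodes")
  d_obs <- drug_distance(network, disease_set, targets)
  cache <- min_dist_to_set(network, disease_set)
  set.seed(seed)
  bins <- if (degree_matched) degree_bin_labels(network) else NULL
  nulls <- null_distances(cache, nodes, length(present), n_perm,
                          degree_bins = bins, targets = present)
  proximity_row(as.numeric(d_obs), nulls,
                attr(d_obs, "n_valid_targets"))[, -(1:2)]
}

#' Screen a drug library by network proximity
#'
#' Computes the proximity z and empirical p for every drug, corrects p-values
#' by Benjamini-Hochberg across drugs, and flags drugs with FDR below the
#' cutoff. Null target sets are generated once per distinct target-set size
#' (sizes processed in increasing order), so results are independent of drug
#' input order.
#'
#' @param network An `igraph` graph with named nodes.
#' @param disease_set Character vector S.
#' @param drug_targets Long data frame with columns `drug_id`, `drug_name`,
#'   `target`.
#' @param n_perm Null draws per target-set size (default 1000).
#' @param seed Integer seed.
#' @param fdr_cutoff Selection threshold (default 0.05).
#' @param degree_matched When `TRUE`, null target sets match each drug's
#'   degree-decile profile (default `FALSE`: uniform draws).
#' @return Data frame sorted by `z` ascending with the per-drug proximity
#'   columns plus `fdr` and `selected`; attribute `unmapped_drugs` lists
#'   drugs whose targets were all absent from the network.
#' @export
screen_drugs <- function(network, disease_set, drug_targets, n_perm = 1000,
                         seed = 1, fdr_cutoff = 0.05,
                         degree_matched = FALSE) {
  need <- c("drug_id", "drug_name", "target")
  stopifnot(all(need %in% colnames(drug_targets)))
  if (nrow(drug_targets) == 0) stop("no drugs to screen")
  nodes <- igraph::V(network)$name
  cache <- min_dist_to_set(network, disease_set)
  split_t <- split(drug_targets$target, drug_targets$drug_id)
  names_by_id <- tapply(drug_targets$drug_name, drug_targets$drug_id,
                        function(x) x[1])
  ids <- sort(names(split_t))
  mapped <- lapply(split_t, function(t) intersect(unique(t), nodes))
  unmapped <- ids[vapply(mapped[ids], length, integer(1)) == 0]
  ids <- setdiff(ids, unmapped)
  if (length(ids) == 0) stop("no drug has targets in the network")
  bins <- if (degree_matched) degree_bin_labels(network) else NULL
  # one reference distribution per null-key (target-set size, or degree-bin
  # profile when matching), generated in sorted key order so that results do
  # not depend on drug input order
  null_key <- vapply(ids, function(id) {
    if (degree_matched) {
      paste(sort(bins[mapped[[id]]]), collapse = "|")
    } else as.character(length(mapped[[id]]))
  }, character(1))
  set.seed(seed)
  nulls_by_key <- list()
  for (key in sort(unique(null_key))) {
    id1 <- ids[null_key == key][1]
    nulls_by_key[[key]] <- null_distances(cache, nodes,
                                          length(mapped[[id1]]), n_perm,
                                          degree_bins = bins,
                                          targets = mapped[[id1]])
  }
  rows <- lapply(ids, function(id) {
    t_m <- mapped[[id]]
    res <- dist_from_cache(cache, t_m)
    if (res$n_valid == 0) {
      return(data.frame(drug_id = id, drug_name = names_by_id[[id]],
                        d_obs = NA_real_, mu_null = NA_real_,
                        sigma_null = NA_real_, z = NA_real_, p_emp = NA_real_,
                        n_valid_targets = 0L))
    }
    proximity_row(res$d, nulls_by_key[[null_key[[id]]]],
                  res$n_valid, id, names_by_id[[id]])
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_fdr(tab$p_emp)
  tab$selected <- !is.na(tab$fdr) & tab$fdr < fdr_cutoff
  tab <- tab[order(tab$z, tab$drug_id, na.last = TRUE), ]
  rownames(tab) <- NULL
  attr(tab, "unmapped_drugs") <- unmapped
  tab
}
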