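# Synthetic data with known ground truth: expression with planted correlated
# modules, scale-free interactomes with locality-clustered disease genes,
# planted high-disease-connectivity key genes, and drug-target sets at
# controlled network proximity.

#' Simulate expression with planted co-expression modules
#'
#' Latent-factor model: each planted module m has a per-sample factor
#' f_m ~ N(0, 1); for disease modules the factor mean of case samples is
#' shifted by `effect`. A member gene's expression is
#' `loading * f_m + N(0, noise_sd^2)`, giving an analytic within-module
#' correlation of `loading^2 / (loading^2 + noise_sd^2)`. Background genes
#' are pure N(0, 1) noise (matching the unit variance of module genes at the
#' defaults). A "known disease gene" set is planted as a random half of each
#' disease module plus a slice of background genes, so module/disease-gene
#' overlap enrichment is recoverable downstream.
#'
#' @param n_genes Total genes (planted modules plus background).
#' @param n_samples_per_condition Samples in each of case and control.
#' @param module_sizes Integer vector of planted module sizes.
#' @param effect Case-sample shift of the latent factor mean in disease
#'   modules (units of factor SD).
#' @param loading Factor loading in (0, 1].
#' @param noise_sd Gene-level noise standard deviation (> 0 for a proper
#'   model; 0 is allowed for exact-limit checks).
#' @param n_disease_modules How many planted modules respond to condition.
#' @param disease_gene_frac Fraction of each disease module planted into the
#'   known disease gene set.
#' @param n_background_disease Background genes added to the disease gene set.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List with `expr` (a [dg_expression()]) and `truth` (list with
#'   `module_of_gene`, `disease_modules`, `disease_genes`).
#' @export
simulate_expression <- function(n_genes = 400,
                                n_samples_per_condition = 8,
                                module_sizes = rep(50, 4),
                                effect = 2,
                                loading = 0.8,
                                noise_sd = 0.6,
                                n_disease_modules = 2,
                                disease_gene_frac = 0.5,
                                n_background_disease = 25,
                                seed = 1) {
  if (any(module_sizes <= 0) || n_genes <= 0 || n_samples_per_condition <= 0) {
    stop("sizes must be positive")
  }
  if (sum(module_sizes) > n_genes) stop("module sizes exceed n_genes")
  if (n_disease_modules > length(module_sizes)) {
    stop("more disease modules than planted modules")
  }
  if (loading < 0 || loading > 1) stop("loading must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)

  n_samples <- 2 * n_samples_per_condition
  condition <- rep(c("control", "case"), each = n_samples_per_condition)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  k <- length(module_sizes)
  module_labels <- sprintf("M%d", seq_len(k))
  disease_modules <- module_labels[seq_len(n_disease_modules)]

  module_of_gene <- rep("background", n_genes)
  idx <- 1
  values <- matrix(NA_real_, n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  for (m in seq_len(k)) {
    f <- rnorm(n_samples)
    if (module_labels[m] %in% disease_modules) {
      f[condition == "case"] <- f[condition == "case"] + effect
    }
    rows <- idx:(idx + module_sizes[m] - 1)
    noise <- matrix(rnorm(length(rows) * n_samples, sd = noise_sd),
                    length(rows), n_samples)
    values[rows, ] <- loading * rep(f, each = length(rows)) + noise
    module_of_gene[rows] <- module_labels[m]
    idx <- idx + module_sizes[m]
  }
  n_bg <- n_genes - sum(module_sizes)
  if (n_bg > 0) {
    values[idx:n_genes, ] <- rnorm(n_bg * n_samples)
  }
  names(module_of_gene) <- gene_ids

  disease_genes <- character(0)
  for (m in disease_modules) {
    members <- gene_ids[module_of_gene == m]
    disease_genes <- c(disease_genes,
                       sample(members, round(disease_gene_frac * length(members))))
  }
  bg_genes <- gene_ids[module_of_gene == "background"]
  if (n_bg > 0 && n_background_disease > 0) {
    disease_genes <- c(disease_genes,
                       sample(bg_genes, min(n_background_disease, n_bg)))
  }

  list(expr = dg_expression(values, condition = condition),
       truth = list(module_of_gene = module_of_gene,
                    disease_modules = disease_modules,
                    disease_genes = sort(disease_genes)))
}

#' Simulate a scale-free interaction network
#'
#' Preferential attachment (Barabasi-Albert) growth: each new node attaches
#' to `edges_per_new_node` existing nodes with probability proportional to
#' degree, which yields the heavy-tailed degree distribution characteristic
#' of protein interaction networks. The graph is connected and simple, and
#' identical seeds give identical edge sets.
#'
#' @param n_nodes Number of nodes (> `edges_per_new_node`).
#' @param edges_per_new_node Edges added per arriving node (>= 1).
#' @param seed Integer seed.
#' @return An `igraph` undirected simple graph with node names `N0001`, ...
#' @export
simulate_scale_free_network <- function(n_nodes, edges_per_new_node = 3,
                                        seed = 1) {
  if (edges_per_new_node < 1 || n_nodes <= edges_per_new_node) {
    stop("need n_nodes > edges_per_new_node >= 1")
  }
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = edges_per_new_node, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%04d", seq_len(n_nodes))
  igraph::simplify(g)
}

#' Plant a locality-clustered disease gene set on a network
#'
#' Grows a disease gene set one node at a time: with probability `locality`
#' the next gene is drawn from the neighborhood of the genes chosen so far
#' (giving a topologically clustered set, as curated disease genes tend to
#' be), otherwise uniformly from the remaining nodes. If the neighborhood is
#' exhausted the draw falls back to uniform.
#'
#' @param network An `igraph` graph with named nodes.
#' @param n_disease Number of disease genes (< node count).
#' @param locality Probability in \[0, 1\] of a neighborhood draw.
#' @param seed Integer seed.
#' @return Character vector of disease gene names (sorted).
#' @export
plant_disease_genes <- function(network, n_disease, locality = 0.8, seed = 1) {
  nodes <- igraph::V(network)$name
  if (n_disease >= length(nodes)) stop("n_disease must be < node count")
  if (locality < 0 || locality > 1) stop("locality must be in [0, 1]")
  set.seed(seed)
  chosen <- sample(nodes, 1)
  while (length(chosen) < n_disease) {
    pool <- character(0)
    if (runif(1) < locality) {
      nb <- unique(unlist(lapply(chosen, function(v) {
        igraph::neighbors(network, v)$name
      })))
      pool <- setdiff(nb, chosen)
    }
    if (length(pool) == 0) pool <- setdiff(nodes, chosen)
    chosen <- c(chosen, sample(pool, 1))
  }
  sort(chosen)
}

#' Plant high-disease-connectivity key genes
#'
#' Picks `n_key` non-disease nodes and wires each to a random sample of
#' `links_per_key` disease genes. The planted nodes become hubs whose
#' neighborhoods are dominated by disease genes - the signature the
#' disease-network statistics are designed to detect - so recovery can be
#' scored against this truth.
#'
#' @param network An `igraph` graph with named nodes.
#' @param disease_genes Character vector of disease gene names.
#' @param n_key Number of key genes to plant.
#' @param links_per_key Disease genes wired to each key gene.
#' @param seed Integer seed.
#' @param pool Optional character vector restricting which nodes may become
#'   key genes (disease genes are always excluded); defaults to all
#'   non-disease nodes.
#' @return List with `network` (edges added, still simple) and `key_genes`.
#' @export
plant_key_genes <- function(network, disease_genes, n_key = 5,
                            links_per_key = 15, seed = 1, pool = NULL) {
  nodes <- igraph::V(network)$name
  stopifnot(all(disease_genes %in% nodes))
  if (links_per_key > length(disease_genes)) {
    stop("links_per_key exceeds number of disease genes")
  }
  cand_pool <- setdiff(if (is.null(pool)) nodes else intersect(pool, nodes),
                       disease_genes)
  if (n_key > length(cand_pool)) stop("not enough eligible non-disease nodes")
  set.seed(seed)
  key <- sample(cand_pool, n_key)
  new_edges <- character(0)
  for (kg in key) {
    to <- sample(disease_genes, links_per_key)
    new_edges <- c(new_edges, rbind(kg, to))
  }
  g <- igraph::add_edges(network, new_edges)
  list(network = igraph::simplify(g), key_genes = sort(key))
}

#' Simulate drug-target sets at controlled network proximity
#'
#' Proximal drugs draw their targets from the disease genes and their direct
#' network neighbors: each target lands on a disease gene itself with
#' probability `p_direct` (mimicking drugs whose targets are disease
#' proteins, which also earn the hub weight in the proximity distance) and on
#' a first neighbor otherwise. Background ("random") drugs draw targets
#' uniformly from all nodes. The returned truth labels let a proximity
#' screen be scored for its ability to separate the two classes.
#'
#' @param network An `igraph` graph with named nodes.
#' @param disease_genes Character vector of disease gene names (in network).
#' @param n_proximal,n_random Drug counts per class.
#' @param targets_per_drug Targets per drug (>= 1).
#' @param p_direct Probability that a proximal drug's target is a disease
#'   gene rather than a neighbor (default 0.7).
#' @param seed Integer seed.
#' @return List with `drug_targets` (long data frame `drug_id`, `drug_name`,
#'   `target`) and `drug_class` (named vector, `"proximal"` or `"random"`).
#' @export
simulate_drugs <- function(network, disease_genes, n_proximal = 20,
                           n_random = 80, targets_per_drug = 4,
                           p_direct = 0.7, seed = 1) {
  if (targets_per_drug < 1) stop("targets_per_drug must be >= 1")
  nodes <- igraph::V(network)$name
  stopifnot(all(disease_genes %in% nodes))
  nb <- unique(unlist(lapply(disease_genes, function(v) {
    igraph::neighbors(network, v)$name
  })))
  nb_only <- setdiff(nb, disease_genes)
  prox_pool <- union(disease_genes, nb)
  if (n_proximal > 0 && targets_per_drug > length(prox_pool)) {
    stop("targets_per_drug exceeds the proximal candidate pool")
  }
  if (targets_per_drug > length(nodes)) {
    stop("targets_per_drug exceeds the node count")
  }
  set.seed(seed)
  rows <- list()
  classes <- character(0)
  add_drug <- function(id, name, targets) {
    rows[[length(rows) + 1]] <<- data.frame(drug_id = id, drug_name = name,
                                            target = targets)
  }
  for (i in seq_len(n_proximal)) {
    id <- sprintf("DRUG_P%02d", i)
    n_direct <- stats::rbinom(1, targets_per_drug, p_direct)
    n_direct <- min(n_direct, length(disease_genes))
    n_nb <- min(targets_per_drug - n_direct, length(nb_only))
    targets <- c(sample(disease_genes, n_direct), sample(nb_only, n_nb))
    # top up from the full pool if a sub-pool ran short
    if (length(targets) < targets_per_drug) {
      targets <- c(targets, sample(setdiff(prox_pool, targets),
                                   targets_per_drug - length(targets)))
    }
    add_drug(id, id, targets)
    classes[id] <- "proximal"
  }
  for (i in seq_len(n_random)) {
    id <- sprintf("DRUG_R%02d", i)
    add_drug(id, id, sample(nodes, targets_per_drug))
    classes[id] <- "random"
  }
  list(drug_targets = do.call(rbind, rows), drug_class = classes)
}

#' Assign disease/candidate/other node classes on a network
#'
#' @param network An `igraph` graph with named nodes.
#' @param disease_genes,candidate_genes Character vectors of node names;
#'   overlap resolves in favor of `disease`.
#' @return The graph with a vertex attribute `class` in
#'   `{"disease", "candidate", "other"}`.
#' @export
set_node_classes <- function(network, disease_genes, candidate_genes) {
  nodes <- igraph::V(network)$name
  cls <- rep("other", length(nodes))
  cls[nodes %in% candidate_genes] <- "candidate"
  cls[nodes %in% disease_genes] <- "disease"
  igraph::set_vertex_attr(network, "class", value = cls)
}
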