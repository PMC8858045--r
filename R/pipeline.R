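# Config-driven pipeline: synthetic generation (or file inputs) ->
# co-expression modules -> disease-module and core-gene selection ->
# disease-network statistics -> drug proximity screen -> diagnostic panel.

#' Build a pipeline configuration
#'
#' All thresholds default to the method's standard values: soft-threshold
#' scan over powers 1..20 at signed R^2 >= 0.85, minimum module size 30,
#' eigengene merge cut 0.25, kME cutoff 0.7, per-gene AUC cutoff 0.8,
#' significance level 0.05, FDR 0.05, 1000 permutations for network and
#' proximity nulls. The single `seed` drives every random step.
#'
#' @param seed Integer seed recorded in every output report.
#' @param out_dir Optional output directory for per-stage TSVs and the JSON
#'   summary; `NULL` keeps results in memory only.
#' @param synth Named list of synthetic-generation parameters (see Details);
#'   used for any input not supplied in `inputs`.
#' @param inputs Named list of file paths: `expression`, `labels`,
#'   `network`, `disease_genes` (GMT, first set used), `drug_targets`,
#'   `gene_sets` (GMT collection for degree-ranked GSEA). Any `NULL` entry is
#'   synthesized (or, for `disease_genes`, causes the network stages to be
#'   skipped when no synthetic generation is configured).
#' @param thresholds Named list overriding individual threshold defaults.
#' @param cv_folds Cross-validation folds for the diagnostic panel.
#'
#' @details Synthetic defaults: expression with 4 planted modules of 50 genes
#' plus 200 background genes over 8 case and 8 control samples (effect 2,
#' loading 0.8, noise SD 0.6, 2 disease modules); a 400-node preferential
#' attachment network (3 edges per node) relabelled with the expression gene
#' ids; 5 planted key genes wired to 15 disease genes each; 20 proximal and
#' 80 random drugs with 4 targets each.
#' @return List of class `dg_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL, synth = list(),
                            inputs = list(), thresholds = list(),
                            cv_folds = 10) {
  synth_def <- list(
    n_genes = 400, n_samples_per_condition = 8, module_sizes = rep(50, 4),
    effect = 2, loading = 0.8, noise_sd = 0.6, n_disease_modules = 2,
    disease_gene_frac = 0.5, n_background_disease = 25,
    edges_per_new_node = 3, n_key = 5, links_per_key = 15,
    n_proximal = 20, n_random = 80, targets_per_drug = 4)
  thr_def <- list(
    powers = c(1:10, seq(12, 30, 2)), r2_cutoff = 0.85, min_module_size = 30,
    cut_height_fraction = 0.99, merge_cut = 0.25, kme_cutoff = 0.7,
    auc_cutoff = 0.8, alpha = 0.05, fdr = 0.05, n_perm_net = 1000,
    n_perm_prox = 1000, n_perm_gsea = 1000, gsea_weight_p = 1,
    edge_score_min = NULL)
  synth_def[names(synth)] <- synth
  thr_def[names(thresholds)] <- thresholds
  inp_def <- list(expression = NULL, labels = NULL, network = NULL,
                  disease_genes = NULL, drug_targets = NULL,
                  gene_sets = NULL)
  inp_def[names(inputs)] <- inputs
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synth = synth_def, inputs = inp_def, thresholds = thr_def,
                 cv_folds = cv_folds),
            class = "dg_config")
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full inference pipeline
#'
#' Stages run in order: expression (load or simulate) and per-batch
#' standardization; soft-threshold scan; adjacency/TOM; module detection;
#' module-trait statistics and disease-module selection; core-gene filter;
#' interaction network (load or simulate) with disease/candidate classes;
#' disease-network statistics and key-gene selection; drug proximity screen;
#' panel cross-validation on the key genes. If no disease gene set is
#' available the network, proximity and diagnostics stages are skipped and
#' noted in the summary. With `out_dir` set, per-stage TSVs and a JSON
#' summary (seed, thresholds, selections, metrics) are written; identical
#' seeds give identical summaries.
#'
#' @param config A [pipeline_config()].
#' @return List of class `dg_result` with per-stage objects and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dg_config"))
  thr <- config$thresholds
  syn <- config$synth
  seed <- config$seed
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- "expression"
  res <- list(config = config)
  summary <- list(seed = seed, thresholds = thr[setdiff(names(thr), "powers")],
                  skipped = character(0))
  tryCatch({
    # --- expression ---------------------------------------------------
    truth <- NULL
    if (!is.null(config$inputs$expression)) {
      expr <- read_expression_tsv(config$inputs$expression,
                                  labels = config$inputs$labels)
    } else {
      sim <- simulate_expression(
        n_genes = syn$n_genes,
        n_samples_per_condition = syn$n_samples_per_condition,
        module_sizes = syn$module_sizes, effect = syn$effect,
        loading = syn$loading, noise_sd = syn$noise_sd,
        n_disease_modules = syn$n_disease_modules,
        disease_gene_frac = syn$disease_gene_frac,
        n_background_disease = syn$n_background_disease, seed = seed)
      expr <- sim$expr
      truth <- sim$truth
    }
    expr <- standardize_per_batch(expr)
    res$expr <- expr
    res$truth <- truth

    # --- disease gene set ---------------------------------------------
    disease_genes <- NULL
    if (!is.null(config$inputs$disease_genes)) {
      sets <- read_gene_sets_gmt(config$inputs$disease_genes)
      disease_genes <- sets[[1]]
    } else if (!is.null(truth)) {
      disease_genes <- truth$disease_genes
    }

    # --- co-expression ------------------------------------------------
    stage <- "coexpr"
    sft <- pick_soft_threshold(expr, powers = thr$powers,
                               r2_cutoff = thr$r2_cutoff)
    mats <- build_matrices(expr, sft$chosen_power)
    det <- detect_modules(mats, expr, min_size = thr$min_module_size,
                          cut_height_fraction = thr$cut_height_fraction,
                          merge_cut = thr$merge_cut)
    res$soft_threshold <- sft
    res$modules <- det
    summary$chosen_power <- sft$chosen_power
    summary$scale_free_r2 <-
      sft$table$r2_signed[sft$table$power == sft$chosen_power]
    summary$n_modules <-
      length(setdiff(unique(det$partition$module_of_gene), "unassigned"))
    write_stage_tsv(data.frame(gene = names(det$partition$module_of_gene),
                               module = det$partition$module_of_gene),
                    out_dir, "module_assignment")
    write_stage_tsv(data.frame(sample_id = rownames(det$eigengenes$eigengenes),
                               det$eigengenes$eigengenes,
                               check.names = FALSE),
                    out_dir, "eigengenes")

    # --- module selection ----------------------------------------------
    stage <- "module_select"
    if (is.null(disease_genes)) {
      summary$skipped <- c(summary$skipped, "module_trait_overlap",
                           "netstats", "proximity")
      trait <- NULL
      dis_mods <- character(0)
    } else {
      trait <- module_trait_stats(det$eigengenes, expr$condition,
                                  disease_genes, det$partition)
      dis_mods <- select_disease_modules(trait, alpha = thr$alpha,
                                         fdr_cutoff = thr$fdr)
      write_stage_tsv(trait, out_dir, "module_trait")
    }
    res$module_trait <- trait
    summary$disease_modules <- dis_mods

    core <- NULL
    core_genes <- character(0)
    if (length(dis_mods) > 0) {
      core <- select_core_genes(expr, det$partition, det$eigengenes,
                                disease_modules = dis_mods,
                                kme_cutoff = thr$kme_cutoff,
                                auc_cutoff = thr$auc_cutoff)
      core_genes <- core$gene[core$selected]
      write_stage_tsv(core, out_dir, "core_genes")
    }
    res$core_genes <- core
    summary$n_core_genes <- length(core_genes)

    # --- interaction network -------------------------------------------
    stage <- "netstats"
    key_genes <- character(0)
    stats_tab <- NULL
    if (!is.null(disease_genes) && length(core_genes) > 0) {
      if (!is.null(config$inputs$network)) {
        net <- read_edge_list(config$inputs$network,
                              min_score = thr$edge_score_min)
        truth_keys <- NULL
      } else {
        net <- simulate_scale_free_network(nrow(expr$values),
                                           syn$edges_per_new_node,
                                           seed = seed)
        # nodes take the expression gene ids so classes map onto the graph
        igraph::V(net)$name <- rownames(expr$values)
        # plant key genes among disease-module members that are not
        # themselves disease genes: the nodes core-gene selection screens
        key_pool <- if (!is.null(truth)) {
          names(truth$module_of_gene)[
            truth$module_of_gene %in% truth$disease_modules]
        } else NULL
        planted <- plant_key_genes(net, intersect(disease_genes,
                                                  igraph::V(net)$name),
                                   n_key = syn$n_key,
                                   links_per_key = syn$links_per_key,
                                   seed = seed, pool = key_pool)
        net <- planted$network
        truth_keys <- planted$key_genes
        if (!is.null(truth)) res$truth$key_genes <- truth_keys
      }
      net <- set_node_classes(net, disease_genes,
                              union(core_genes, character(0)))
      res$network <- net
      n_cand <- sum(igraph::V(net)$class == "candidate")
      if (n_cand >= 2) {
        stats_tab <- node_disease_stats(net, n_perm = thr$n_perm_net,
                                        seed = seed)
        key_genes <- select_key_genes(stats_tab, alpha = thr$alpha)
        write_stage_tsv(stats_tab, out_dir, "network_stats")
      } else {
        summary$skipped <- c(summary$skipped, "netstats")
      }

      # degree-ranked GSEA when a gene-set collection is supplied
      if (!is.null(config$inputs$gene_sets)) {
        coll <- read_gene_sets_gmt(config$inputs$gene_sets)
        gsea <- preranked_gsea(degree_rank(net), coll,
                               n_perm = thr$n_perm_gsea,
                               weight_p = thr$gsea_weight_p, seed = seed)
        res$gsea <- gsea
        write_stage_tsv(gsea, out_dir, "gsea")
      }
    }
    res$network_stats <- stats_tab
    summary$key_genes <- key_genes

    # --- drug proximity -------------------------------------------------
    stage <- "proximity"
    screen <- NULL
    if (!is.null(disease_genes) && !is.null(res$network)) {
      if (!is.null(config$inputs$drug_targets)) {
        dt <- read_drug_targets_tsv(config$inputs$drug_targets)
        res$drug_class <- NULL
      } else {
        drugs <- simulate_drugs(res$network,
                                intersect(disease_genes,
                                          igraph::V(res$network)$name),
                                n_proximal = syn$n_proximal,
                                n_random = syn$n_random,
                                targets_per_drug = syn$targets_per_drug,
                                seed = seed)
        dt <- drugs$drug_targets
        res$drug_class <- drugs$drug_class
      }
      screen <- screen_drugs(res$network, disease_genes, dt,
                             n_perm = thr$n_perm_prox, seed = seed,
                             fdr_cutoff = thr$fdr)
      write_stage_tsv(screen, out_dir, "drug_screen")
      summary$selected_drugs <- screen$drug_id[screen$selected]
    }
    res$drug_screen <- screen

    # --- diagnostics ----------------------------------------------------
    stage <- "diagnostics"
    panel <- key_genes
    if (length(panel) < 2 && length(core_genes) > 0) {
      ord <- core[order(-core$auc, core$gene), ]
      panel <- unique(c(panel, ord$gene[ord$selected]))[
        seq_len(min(3, sum(ord$selected)))]
    }
    if (length(panel) >= 1) {
      cv <- cross_validate(expr, panel = panel, k = config$cv_folds,
                           seed = seed)
      res$diagnostics <- cv
      summary$panel <- panel
      summary$cv_accuracy <- cv$confusion$accuracy
      summary$cv_auc <- cv$roc$auc
      write_stage_tsv(cv$predictions, out_dir, "cv_predictions")
    } else {
      summary$skipped <- c(summary$skipped, "diagnostics")
    }
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  res$summary <- summary
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  class(res) <- "dg_result"
  res
}

#' @export
print.dg_result <- function(x, ...) {
  s <- x$summary
  cat("dgnet pipeline result (seed ", s$seed, ")\n", sep = "")
  cat("  modules: ", s$n_modules, "; disease modules: ",
      paste(s$disease_modules, collapse = ", "), "\n", sep = "")
  cat("  core genes:", s$n_core_genes,
      "| key genes:", length(s$key_genes), "\n")
  if (!is.null(s$cv_accuracy)) {
    cat(sprintf("  panel CV accuracy %.3f, AUC %.3f\n",
                s$cv_accuracy, s$cv_auc))
  }
  invisible(x)
}
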