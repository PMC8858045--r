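# Readers and writers for the package's plain-text interchange formats:
# expression TSV (+ sample label sidecar), GMT gene sets, edge-list TSV,
# drug-target TSV.

#' Read an expression TSV
#'
#' The file has one header row of unique sample ids and a first column of
#' gene ids. Duplicate gene ids (e.g. multiple probes mapped to one gene) are
#' collapsed by the per-cell median. Rows containing missing values (`NA` or
#' empty cells) are dropped and counted; any other non-numeric cell is an
#' error naming its row and column.
#'
#' @param path Path to the TSV file.
#' @param labels Optional per-sample metadata: a path to a TSV with columns
#'   `sample_id`, `condition` and optionally `batch`, or a data frame with
#'   those columns. When omitted, the returned object carries no condition.
#' @return A [dg_expression()] object. Attribute `n_dropped_missing` records
#'   how many input rows were removed for missing values.
#' @export
read_expression_tsv <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression TSV needs a gene column plus samples")
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  gene_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  missing <- cells %in% c("", "NA", "NaN") | is.na(cells)
  dim(missing) <- dim(cells)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- is.na(num) & !missing
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric value '", cells[bad][1], "' at gene '",
         gene_ids[ij[1]], "', sample '", sample_ids[ij[2]], "'")
  }
  drop <- apply(missing, 1, any)
  n_dropped <- sum(drop)
  num <- num[!drop, , drop = FALSE]
  gene_ids <- gene_ids[!drop]
  # collapse duplicate gene ids by per-cell median (probe-to-gene rule)
  if (anyDuplicated(gene_ids)) {
    split_idx <- split(seq_along(gene_ids), gene_ids)
    collapsed <- t(vapply(split_idx, function(ix) {
      if (length(ix) == 1) num[ix, ] else apply(num[ix, , drop = FALSE], 2, median)
    }, numeric(ncol(num))))
    num <- collapsed[order(match(rownames(collapsed),
                                 unique(gene_ids))), , drop = FALSE]
    gene_ids <- rownames(num)
  }
  dimnames(num) <- list(gene_ids, sample_ids)

  condition <- NULL
  batch <- NULL
  if (!is.null(labels)) {
    lab <- if (is.character(labels)) {
      utils::read.delim(labels, header = TRUE, sep = "\t",
                        check.names = FALSE, colClasses = "character")
    } else as.data.frame(labels)
    if (!all(c("sample_id", "condition") %in% colnames(lab))) {
      stop("labels need columns sample_id and condition")
    }
    m <- match(sample_ids, lab$sample_id)
    if (any(is.na(m))) stop("labels missing for samples: ",
                            paste(sample_ids[is.na(m)], collapse = ", "))
    condition <- lab$condition[m]
    if ("batch" %in% colnames(lab)) batch <- lab$batch[m]
  }
  out <- dg_expression(num, condition = condition, batch = batch)
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

#' Write an expression TSV (plus optional label sidecar)
#'
#' @param expr A [dg_expression()] object.
#' @param path Output TSV path.
#' @param labels_path Optional path for a `sample_id`/`condition`/`batch`
#'   sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path, labels_path = NULL) {
  stopifnot(inherits(expr, "dg_expr"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    lab <- data.frame(sample_id = colnames(expr$values),
                      condition = if (is.null(expr$condition)) NA
                                  else expr$condition,
                      batch = expr$batch)
    utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name TAB description TAB member TAB member ...`. Members are
#' deduplicated; sets that end up empty are dropped with a warning; duplicate
#' set names or lines with fewer than three fields are errors.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, " has fewer than 3 fields")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate gene set name '", nm,
                                  "' at line ", i)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning("gene set '", nm, "' is empty after deduplication; dropped")
      next
    }
    sets[[nm]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network from an edge-list TSV
#'
#' Accepts two columns (node, node) or three (node, node, confidence score).
#' The result is a simple undirected graph: self-loops are removed and
#' duplicate or reciprocal edges collapsed. An optional score threshold keeps
#' only edges with confidence at or above `min_score` (no filter by default).
#'
#' @param path Path to the edge-list TSV (no header by default).
#' @param min_score Optional numeric confidence cutoff (requires 3 columns).
#' @param header Logical; does the file carry a header row?
#' @return An `igraph` undirected simple graph.
#' @export
read_edge_list <- function(path, min_score = NULL, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0 || length(readLines(path, n = 1)) == 0) {
    warning("empty edge list: returning empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  df <- utils::read.delim(path, header = header, sep = "\t",
                          check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("edge list needs at least 2 columns")
  if (!is.null(min_score)) {
    if (ncol(df) < 3) stop("score filtering requires a 3rd (score) column")
    score <- as.numeric(df[[3]])
    df <- df[!is.na(score) & score >= min_score, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    warning("no edges after filtering: returning empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a 2-column edge-list TSV
#' @param network An `igraph` graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a drug-target table
#'
#' Long-format TSV with header columns `drug_id`, `drug_name`, `target`
#' (one row per drug-target pair). Target lists are deduplicated per drug.
#'
#' @param path Path to the TSV.
#' @return A data frame with columns `drug_id`, `drug_name`, `target`.
#' @export
read_drug_targets_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  need <- c("drug_id", "drug_name", "target")
  if (!all(need %in% colnames(df))) {
    stop("drug-target TSV needs columns: ", paste(need, collapse = ", "))
  }
  df <- unique(df[, need])
  if (nrow(df) == 0) stop("drug-target table is empty")
  df
}

#' Write a drug-target table
#' @param drug_targets Data frame with columns `drug_id`, `drug_name`,
#'   `target`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_targets_tsv <- function(drug_targets, path) {
  utils::write.table(drug_targets[, c("drug_id", "drug_name", "target")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
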