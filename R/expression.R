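#' Expression matrix with sample metadata
#'
#' Container for a genes-by-samples matrix of log-scale expression values
#' together with a per-sample condition label (`"case"` / `"control"`) and an
#' optional batch label. All analysis functions in the package take this
#' object as their expression input.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param condition Character vector of per-sample labels, `"case"` or
#'   `"control"`. May be `NULL` for purely structural operations.
#' @param batch Optional character vector of per-sample batch labels. When
#'   `NULL` a single batch is assumed.
#'
#' @return An object of class `dg_expr`: a list with elements `values`,
#'   `condition` and `batch`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' dg_expression(m, condition = c("case", "case", "control", "control"))
dg_expression <- function(values, condition = NULL, batch = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (!is.null(condition)) {
    condition <- check_condition(condition, ncol(values))
    names(condition) <- colnames(values)
  }
  if (is.null(batch)) {
    batch <- rep("batch1", ncol(values))
  } else if (length(batch) != ncol(values)) {
    stop("batch length does not match number of samples")
  }
  names(batch) <- colnames(values)
  structure(list(values = values, condition = condition,
                 batch = as.character(batch)),
            class = "dg_expr")
}

#' @export
print.dg_expr <- function(x, ...) {
  cat("dg_expr:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  if (!is.null(x$condition)) {
    cat("  condition:", sum(x$condition == "case"), "case /",
        sum(x$condition == "control"), "control\n")
  }
  cat("  batches:", length(unique(x$batch)), "\n")
  invisible(x)
}

#' @export
dim.dg_expr <- function(x) dim(x$values)

#' Standardize expression within each batch
#'
#' A deliberately simple batch-adjustment stand-in: within each batch, every
#' gene row is centered to mean zero and scaled to unit standard deviation.
#' This removes per-batch location/scale differences (the dominant batch
#' artifact in merged microarray series) without the empirical-Bayes
#' moderation of full batch-correction methods; the transformation applied is
#' recorded so downstream reports can state it. Genes that are constant
#' within a batch are set to zero there and flagged.
#'
#' @param expr A [dg_expression()] object with at least 2 samples per batch.
#' @return A `dg_expr` with standardized values; attribute
#'   `flagged_constant` lists `gene:batch` combinations that were zeroed.
#' @export
standardize_per_batch <- function(expr) {
  stopifnot(inherits(expr, "dg_expr"))
  v <- expr$values
  flagged <- character(0)
  for (b in unique(expr$batch)) {
    idx <- which(expr$batch == b)
    if (length(idx) < 2) {
      stop("batch '", b, "' has fewer than 2 samples")
    }
    sub <- v[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, sd)
    const <- sdv == 0
    sdv[const] <- 1
    v[, idx] <- (sub - mu) / sdv
    if (any(const)) {
      v[const, idx] <- 0
      flagged <- c(flagged, paste0(rownames(v)[const], ":", b))
    }
  }
  out <- dg_expression(v, expr$condition, expr$batch)
  attr(out, "flagged_constant") <- flagged
  out
}
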