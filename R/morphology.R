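# Ten morphological features summarized per cell line. cell_wl (cell
# width/length, elongation) is derived per cell from the raw width and length
# columns before aggregation; the remaining nine are raw columns.
SHAPE_FEATURES <- c("cell_wl", "cell_area", "nuc_width", "nuc_length",
                    "nuc_area", "nc_area", "centers_dist", "neighbor_frac",
                    "protrusion_area", "ruffliness")

# Raw per-cell columns expected in a cell table (plus cell_line).
CELL_COLUMNS <- c("cell_width", "cell_length", "cell_area", "nuc_width",
                  "nuc_length", "nuc_area", "nc_area", "centers_dist",
                  "neighbor_frac", "protrusion_area", "ruffliness")

#' Names of the morphological feature statistics
#'
#' The 20 per-line statistics screened against expression: the mean and the
#' sample SD of each of the ten features, named \code{<feature>_mean} and
#' \code{<feature>_sd}.
#' @return Character vector of length 20.
#' @export
feature_statistics <- function() {
  as.vector(t(outer(SHAPE_FEATURES, c("mean", "sd"), paste, sep = "_")))
}

#' Summarize single-cell morphology per cell line
#'
#' Computes, for each cell line, the mean and sample SD (n-1 denominator) of
#' the ten morphological features. Cell elongation (cell_wl) is derived per
#' cell as cell_width / cell_length before aggregation.
#'
#' @param cells data.frame with a \code{cell_line} column and the raw per-cell
#'   feature columns (\code{CELL_COLUMNS}); no missing values allowed.
#' @return A \code{feature_summary}: data.frame with one row per cell line and
#'   one column per feature statistic (plus \code{cell_line}).
#' @export
summarize_features <- function(cells) {
  stopifnot(is.data.frame(cells), "cell_line" %in% names(cells))
  missing_cols <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing_cols)) {
    stop("cell table lacks feature columns: ", paste(missing_cols, collapse = ", "))
  }
  feat_cols <- cells[CELL_COLUMNS]
  if (anyNA(feat_cols)) stop("cell table contains missing feature values")
  n_per <- table(cells$cell_line)
  small <- names(n_per)[n_per < 2L]
  if (length(small)) {
    stop("cell line(s) with fewer than 2 cells: ", paste(small, collapse = ", "))
  }
  per_cell <- data.frame(cell_wl = cells$cell_width / cells$cell_length,
                         feat_cols[setdiff(CELL_COLUMNS, c("cell_width", "cell_length"))],
                         check.names = FALSE)
  lines <- sort(unique(as.character(cells$cell_line)))
  out <- data.frame(cell_line = lines, stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(cells)), as.character(cells$cell_line))
  for (f in SHAPE_FEATURES) {
    v <- per_cell[[f]]
    out[[paste0(f, "_mean")]] <- vapply(lines, function(l) mean(v[idx[[l]]]), numeric(1))
    out[[paste0(f, "_sd")]] <- vapply(lines, function(l) stats::sd(v[idx[[l]]]), numeric(1))
  }
  rownames(out) <- NULL
  class(out) <- c("feature_summary", "data.frame")
  out
}

#' Construct an expression matrix object
#'
#' Probe-level continuous (log-scale) expression with a probe-to-gene map.
#'
#' @param values numeric matrix, probes x samples, finite, with rownames =
#'   probe ids.
#' @param genes character vector mapping each probe (row) to one gene symbol.
#' @return An \code{expr_matrix} object.
#' @export
expr_matrix <- function(values, genes) {
  stopifnot(is.matrix(values), is.numeric(values), length(genes) == nrow(values))
  if (is.null(rownames(values))) stop("expression values need probe rownames")
  if (anyDuplicated(rownames(values))) stop("probe ids must be unique")
  if (!all(is.finite(values))) stop("expression values must be finite")
  structure(list(values = values, genes = as.character(genes)),
            class = "expr_matrix")
}

#' Collapse probes to per-gene profiles by averaging
#'
#' Probes mapping to the same gene are averaged first; this matches the
#' convention of averaging multi-probe profiles before any filtering.
#'
#' @param expr an \code{expr_matrix}.
#' @return numeric matrix genes x samples, rows in first-appearance order.
#' @export
collapse_probes <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- unique(expr$genes)
  g <- factor(expr$genes, levels = genes)
  out <- rowsum(expr$values, g) / as.vector(table(g))
  rownames(out) <- genes
  out
}

#' Filter out genes with low cross-sample variability
#'
#' Collapses multi-probe genes by averaging, then removes genes whose
#' cross-sample sample SD is at or below \code{sd_cutoff}. The published
#' screen uses this to separate the low-variability mode of the SD
#' distribution from informative genes.
#'
#' @param expr an \code{expr_matrix} with >= 3 samples.
#' @param sd_cutoff SD floor (genes with SD <= cutoff are removed).
#' @return Character vector of surviving gene ids in input order.
#' @export
filter_variable_genes <- function(expr, sd_cutoff = 0.3) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr$values) < 3L) stop("need at least 3 samples")
  m <- collapse_probes(expr)
  sds <- apply(m, 1L, stats::sd)
  rownames(m)[sds > sd_cutoff]
}

# Spearman rho with average-rank tie handling, plus the t-approximation
# two-sided p on n-2 df. |rho| = 1 is reported at the smallest positive
# double rather than p = 0.
spearman_test <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  c(rho = rho, p = p)
}

# Storey q-values with the lambda = 0.5 plug-in pi0 estimate (clamped to
# (0, 1]); kept simple and deterministic.
storey_qvalue <- function(p) {
  m <- length(p)
  pi0 <- min(1, max(sum(p > 0.5) / (0.5 * m), 1 / m))
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))
  q
}

#' Screen genes for correlation with morphological feature statistics
#'
#' Computes the Spearman correlation (average-rank ties) of every
#' variability-filtered gene against every per-line feature statistic (mean
#' and SD of each of the ten features), with a two-sided p from the
#' t-approximation and FDR q-values over all tested pairs. The significant
#' subset is |rho| > \code{rho_cutoff}.
#'
#' @param expr an \code{expr_matrix}; samples must match the summary lines.
#' @param summary a \code{feature_summary}.
#' @param config a \code{pipeline_config}.
#' @return List with \code{records} (all gene x statistic pairs: gene,
#'   statistic, rho, p, q) and \code{significant} (the |rho| > cutoff subset).
#' @export
correlate_shape <- function(expr, summary, config = pipeline_config()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(summary, "feature_summary"))
  samples <- colnames(expr$values)
  if (!setequal(samples, summary$cell_line)) {
    stop("expression samples and summary cell lines are not the same set")
  }
  n <- length(samples)
  if (n < 4L) stop("need at least 4 samples for the correlation screen")
  m <- collapse_probes(expr)
  keep <- filter_variable_genes(expr, config$sd_cutoff)
  m <- m[keep, , drop = FALSE]
  stats_tab <- summary[match(samples, summary$cell_line), , drop = FALSE]
  stat_names <- feature_statistics()
  recs <- vector("list", length(stat_names))
  for (si in seq_along(stat_names)) {
    s <- stat_names[si]
    sv <- stats_tab[[s]]
    if (stats::sd(sv) == 0) {
      # zero-variance statistic: rho undefined, excluded from testing
      message("statistic '", s, "' has zero variance; excluded from testing")
      recs[[si]] <- data.frame(gene = rownames(m), statistic = s,
                               rho = NA_real_, p = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    rr <- t(apply(m, 1L, spearman_test, y = sv))
    recs[[si]] <- data.frame(gene = rownames(m), statistic = s,
                             rho = rr[, "rho"], p = rr[, "p"],
                             stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  tested <- !is.na(records$p)
  records$q <- NA_real_
  records$q[tested] <- if (config$fdr_method == "storey") {
    storey_qvalue(records$p[tested])
  } else {
    stats::p.adjust(records$p[tested], method = "BH")
  }
  sig <- records[tested & abs(records$rho) > config$rho_cutoff, , drop = FALSE]
  rownames(sig) <- NULL
  list(records = records, significant = sig)
}

#' Read a single-cell morphology table from TSV
#' @param path TSV with header: cell_line plus the raw feature columns.
#' @return data.frame cell table.
#' @export
read_cell_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an expression matrix from TSV
#'
#' First column = probe id, second = gene symbol, remaining = samples.
#' @param path TSV path.
#' @return an \code{expr_matrix}.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(vals) <- d[[1L]]
  expr_matrix(vals, d[[2L]])
}

#' Write an expression matrix to TSV (probe id, gene, samples)
#' @param expr an \code{expr_matrix}.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(probe_id = rownames(expr$values), gene = expr$genes,
                  expr$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write correlation records to TSV
#' @param records data.frame from \code{\link{correlate_shape}}.
#' @param path output path.
#' @export
write_correlations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
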