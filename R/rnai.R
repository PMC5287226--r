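#' Construct a raw knockdown panel
#'
#' @param values numeric matrix, measured genes x perturbation columns, on the
#'   panel's (approximately z-scored) scale; rownames = measured genes,
#'   colnames = perturbation ids.
#' @param target character vector: the gene each perturbation column targets.
#' @return A \code{kd_panel} object (raw, not yet consolidated).
#' @export
kd_panel <- function(values, target) {
  stopifnot(is.matrix(values), length(target) == ncol(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("knockdown panel needs gene rownames and perturbation colnames")
  }
  structure(list(values = values, target = as.character(target),
                 consolidated = FALSE), class = "kd_panel")
}

#' Consolidate and normalize a knockdown panel
#'
#' A perturbation column is valid only if it drives its targeted gene's
#' z-score below \code{kd_valid_z} (and the target is a measured gene).
#' Valid columns targeting the same gene are averaged to one profile per
#' gene; the consolidated matrix is then re-z-scored per measured gene across
#' all knockdowns.
#'
#' @param raw a \code{kd_panel} from \code{\link{kd_panel}}.
#' @param config a \code{pipeline_config}.
#' @return A consolidated \code{kd_panel} (one column per targeted gene,
#'   columns named by gene) with attribute \code{dropped}: the invalid
#'   perturbation ids.
#' @export
preprocess_panel <- function(raw, config = pipeline_config()) {
  stopifnot(inherits(raw, "kd_panel"), !raw$consolidated)
  measured <- rownames(raw$values)
  valid <- logical(ncol(raw$values))
  for (j in seq_len(ncol(raw$values))) {
    tg <- raw$target[j]
    valid[j] <- tg %in% measured && raw$values[tg, j] < config$kd_valid_z
  }
  dropped <- colnames(raw$values)[!valid]
  keep_targets <- unique(raw$target[valid])
  if (!length(keep_targets)) stop("no valid knockdown columns remain")
  cons <- vapply(keep_targets, function(g) {
    cols <- which(valid & raw$target == g)
    rowMeans(raw$values[, cols, drop = FALSE])
  }, numeric(nrow(raw$values)))
  # re-z-score each measured gene across all consolidated knockdowns
  mu <- rowMeans(cons)
  sdv <- apply(cons, 1L, stats::sd)
  sdv[sdv == 0] <- 1  # flat gene: leave centered at 0 rather than NaN
  z <- (cons - mu) / sdv
  out <- structure(list(values = z, target = keep_targets, consolidated = TRUE),
                   class = "kd_panel")
  attr(out, "dropped") <- dropped
  out
}

#' Define a TF's target set from its knockdown column
#'
#' Targets are the measured genes (excluding the TF itself) whose z-score in
#' the TF-knockdown column strictly exceeds \code{target_z} in absolute value,
#' recorded with the sign of the change.
#'
#' @param panel a consolidated \code{kd_panel}.
#' @param tf TF gene symbol; must have a consolidated column.
#' @param config a \code{pipeline_config}.
#' @return A \code{tf_target_set}: list(tf, targets = named sign vector, K).
#' @export
define_targets <- function(panel, tf, config = pipeline_config()) {
  stopifnot(inherits(panel, "kd_panel"), panel$consolidated)
  if (!tf %in% colnames(panel$values)) {
    stop("TF '", tf, "' has no valid consolidated knockdown column")
  }
  z <- panel$values[, tf]
  z <- z[names(z) != tf]
  hit <- abs(z) > config$target_z
  targets <- sign(z[hit])
  structure(list(tf = tf, targets = targets, K = length(targets)),
            class = "tf_target_set")
}

# Upper-tail hypergeometric P(X >= k) drawing n from a universe of N with K
# successes.
hyper_upper_p <- function(k, N, K, n) {
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Classify a gene's regulatory relationship with a TF
#'
#' Emits zero or more calls from the knockdown panel:
#' \itemize{
#'   \item expression_regulator: the gene's knockdown significantly changes
#'     the TF's own expression (|z| > target_z); direction up/down by sign.
#'   \item activation_regulator: the gene's knockdown significantly changes at
#'     least \code{coverage_frac} of the TF's targets (k >= ceil(frac * K))
#'     and the overlap is hypergeometrically enriched (upper-tail
#'     P(X >= k) < hyper_alpha) in the universe of measured genes excluding
#'     the TF and the knocked-down gene; direction activator/inhibitor by
#'     sign concordance with the TF knockdown (\code{\link{call_direction}}).
#'   \item tf_effector: the TF's knockdown significantly changes the gene
#'     (|z| > target_z); direction up/down by sign.
#' }
#'
#' @param gene gene symbol with a consolidated knockdown column.
#' @param tf TF symbol with a consolidated knockdown column.
#' @param panel consolidated \code{kd_panel}.
#' @param targetset \code{tf_target_set} for \code{tf}.
#' @param config a \code{pipeline_config}.
#' @return data.frame of regulation calls (possibly 0 rows): gene, tf, mode,
#'   direction, k, n, K, N, p, concordance.
#' @export
classify_regulation <- function(gene, tf, panel, targetset,
                                config = pipeline_config()) {
  stopifnot(inherits(panel, "kd_panel"), panel$consolidated,
            inherits(targetset, "tf_target_set"), targetset$tf == tf)
  empty <- data.frame(gene = character(), tf = character(), mode = character(),
                      direction = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      concordance = numeric(), stringsAsFactors = FALSE)
  cols <- colnames(panel$values)
  if (!gene %in% cols || !tf %in% cols) {
    message("no consolidated column for ", if (!gene %in% cols) gene else tf,
            "; no call")
    return(empty)
  }
  calls <- list()
  rec <- function(mode, direction, k = NA_integer_, n = NA_integer_,
                  K = NA_integer_, N = NA_integer_, p = NA_real_,
                  conc = NA_real_) {
    data.frame(gene = gene, tf = tf, mode = mode, direction = direction,
               k = k, n = n, K = K, N = N, p = p, concordance = conc,
               stringsAsFactors = FALSE)
  }
  # (a) regulator of TF expression
  z_tf_in_gene <- panel$values[tf, gene]
  if (abs(z_tf_in_gene) > config$target_z) {
    calls <- c(calls, list(rec("expression_regulator",
                               if (z_tf_in_gene > 0) "up" else "down")))
  }
  # (b) regulator of TF activation
  gz <- panel$values[, gene]
  universe <- setdiff(rownames(panel$values), c(tf, gene))
  gz <- gz[universe]
  changed <- names(gz)[abs(gz) > config$target_z]
  tt <- targetset$targets[setdiff(names(targetset$targets), gene)]
  K <- length(tt)
  n <- length(changed)
  overlap <- intersect(changed, names(tt))
  k <- length(overlap)
  N <- length(universe)
  if (K > 0 && k >= ceiling(config$coverage_frac * K)) {
    p <- hyper_upper_p(k, N, K, n)
    if (p < config$hyper_alpha && k > 0) {
      conc <- mean(sign(panel$values[overlap, gene]) == tt[overlap])
      dir <- if (conc > 0.5) "activator" else if (conc < 0.5) "inhibitor" else "ambiguous"
      calls <- c(calls, list(rec("activation_regulator", dir, k = k, n = n,
                                 K = K, N = N, p = p, conc = conc)))
    }
  }
  # (c) TF effector
  z_gene_in_tf <- panel$values[gene, tf]
  if (abs(z_gene_in_tf) > config$target_z) {
    calls <- c(calls, list(rec("tf_effector",
                               if (z_gene_in_tf > 0) "up" else "down")))
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Activator/inhibitor direction of an activation regulator
#'
#' Over the targets the gene's knockdown perturbs, the concordance is the
#' fraction whose z-sign in the gene-knockdown column matches the sign under
#' TF knockdown. Concordance > 0.5 means the gene's depletion mimics TF
#' depletion, so the gene activates the TF; < 0.5 means it inhibits it.
#'
#' @inheritParams classify_regulation
#' @return list(direction, concordance, overlap).
#' @export
call_direction <- function(gene, tf, panel, targetset,
                           config = pipeline_config()) {
  stopifnot(inherits(panel, "kd_panel"), panel$consolidated)
  gz <- panel$values[, gene]
  tt <- targetset$targets[setdiff(names(targetset$targets), gene)]
  changed <- names(gz)[abs(gz) > config$target_z]
  overlap <- intersect(changed, names(tt))
  if (!length(overlap)) stop("no overlapping perturbed targets; direction undefined")
  conc <- mean(sign(panel$values[overlap, gene]) == tt[overlap])
  dir <- if (conc > 0.5) "activator" else if (conc < 0.5) "inhibitor" else "ambiguous"
  list(direction = dir, concordance = conc, overlap = overlap)
}

#' Classify every subnetwork gene against every subnetwork TF
#'
#' @param subnet a \code{shape_gene_network} (typically the feature-to-TF path
#'   subnetwork).
#' @param panel consolidated \code{kd_panel}.
#' @param config a \code{pipeline_config}.
#' @return data.frame of regulation calls across all (gene, TF) pairs present
#'   in the panel.
#' @export
classify_subnetwork <- function(subnet, panel, config = pipeline_config()) {
  nodes <- network_nodes(subnet)
  tfs <- intersect(nodes$node[nodes$type == "tf"], colnames(panel$values))
  genes <- intersect(nodes$node[nodes$type == "gene"], colnames(panel$values))
  out <- list()
  for (tf in tfs) {
    ts <- define_targets(panel, tf, config)
    for (g in genes) {
      out <- c(out, list(classify_regulation(g, tf, panel, ts, config)))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(), tf = character(), mode = character(),
                      direction = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      concordance = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Infer directions for interaction edges from the knockdown panel
#'
#' For each interaction edge (A, B), direction A -> B is annotated when
#' knocking down A significantly changes B's expression (|z| > target_z);
#' both directions can hold; edges with neither stay undirected.
#'
#' @param subnet a \code{shape_gene_network}.
#' @param panel consolidated \code{kd_panel}.
#' @param config a \code{pipeline_config}.
#' @return data.frame: node_a, node_b, a_to_b, b_to_a (logical).
#' @export
infer_edge_directions <- function(subnet, panel, config = pipeline_config()) {
  g <- subnet$graph
  el <- igraph::as_edgelist(g)
  etype <- igraph::E(g)$etype
  el <- el[etype == "interaction", , drop = FALSE]
  meas <- rownames(panel$values)
  cols <- colnames(panel$values)
  dir_z <- function(from, to) {
    if (from %in% cols && to %in% meas) {
      abs(panel$values[to, from]) > config$target_z
    } else NA
  }
  data.frame(node_a = el[, 1], node_b = el[, 2],
             a_to_b = vapply(seq_len(nrow(el)), function(i) isTRUE(dir_z(el[i, 1], el[i, 2])), logical(1)),
             b_to_a = vapply(seq_len(nrow(el)), function(i) isTRUE(dir_z(el[i, 2], el[i, 1])), logical(1)),
             stringsAsFactors = FALSE)
}

#' Read a knockdown panel from TSV files
#'
#' @param values_path TSV: first column = measured gene, remaining columns =
#'   perturbation ids.
#' @param map_path TSV with columns \code{perturbation} and \code{target}.
#' @return a raw \code{kd_panel}.
#' @export
read_kd_panel <- function(values_path, map_path) {
  d <- utils::read.delim(values_path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  rownames(vals) <- d[[1L]]
  map <- utils::read.delim(map_path, check.names = FALSE, stringsAsFactors = FALSE)
  tg <- map$target[match(colnames(vals), map$perturbation)]
  if (anyNA(tg)) stop("perturbation map lacks entries for some columns")
  kd_panel(vals, tg)
}

#' Write regulation calls
#' @param calls data.frame of calls.
#' @param path_tsv,path_json output paths (either may be NULL).
#' @export
write_regulation_calls <- function(calls, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(calls, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(calls, path_json, dataframe = "rows", digits = NA)
  }
  invisible(calls)
}
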