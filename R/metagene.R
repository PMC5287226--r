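# OLS residual sum of squares of response y on design cbind(1, X); returns
# Inf for rank-deficient fits so the candidate is skipped by the caller.
ols_rss <- function(y, X) {
  Xd <- cbind(1, X)
  qr_ <- qr(Xd)
  if (qr_$rank < ncol(Xd)) return(Inf)
  res <- stats::lm.fit(Xd, y)$residuals
  sum(res^2)
}

#' Fit a metagene model by forward sequential feature selection
#'
#' Greedy forward selection over a candidate gene pool: at each step the
#' candidate whose addition minimizes the residual sum of squares of the OLS
#' fit joins the model (ties broken by candidate input order). Selection
#' continues while fewer than \code{min_genes} genes are selected, and
#' thereafter while R-squared < \code{r2_stop} and fewer than
#' \code{max_genes} genes are selected. Coefficients are refit jointly on the
#' final set. Rank-deficient candidates are dropped with a message.
#'
#' @param response numeric response per sample (a morphological statistic or
#'   the TNF response), length = number of samples.
#' @param candidates numeric matrix, samples x candidate genes (column names
#'   = gene ids); typically the expression of the genes correlated with the
#'   modeled feature.
#' @param config a \code{pipeline_config}.
#' @param standardize z-score each candidate across samples before fitting
#'   (default TRUE; coefficients then apply to z-scored expression, which is
#'   how cohorts are scored).
#' @return A \code{metagene_model}: list(response_name, intercept,
#'   coefficients (named, selection order), r2, trace (step, gene, rss, r2),
#'   standardize).
#' @export
forward_select_fit <- function(response, candidates, config = pipeline_config(),
                               standardize = TRUE) {
  stopifnot(is.numeric(response), is.matrix(candidates),
            length(response) == nrow(candidates))
  if (ncol(candidates) < 2L) stop("need at least 2 candidate genes")
  if (is.null(colnames(candidates))) stop("candidates need gene column names")
  n <- length(response)
  if (standardize) {
    sds <- apply(candidates, 2L, stats::sd)
    sds[sds == 0] <- 1
    candidates <- scale(candidates, center = TRUE, scale = sds)
    attr(candidates, "scaled:center") <- NULL
  }
  tss <- sum((response - mean(response))^2)
  if (tss == 0) stop("constant response; nothing to fit")
  selected <- integer(0)
  pool <- seq_len(ncol(candidates))
  trace <- list()
  repeat {
    k <- length(selected)
    go_on <- k < config$min_genes ||
      (length(trace) > 0 && trace[[k]]$r2 < config$r2_stop && k < config$max_genes)
    if (!go_on || !length(pool)) break
    rss_try <- vapply(pool, function(j) {
      ols_rss(response, candidates[, c(selected, j), drop = FALSE])
    }, numeric(1))
    if (all(!is.finite(rss_try))) break
    best <- pool[which.min(rss_try)]  # which.min takes the first = input order
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
    rss <- min(rss_try[is.finite(rss_try)])
    trace[[length(trace) + 1L]] <- list(step = length(selected),
                                        gene = colnames(candidates)[best],
                                        rss = rss, r2 = 1 - rss / tss)
  }
  if (length(selected) < config$min_genes) {
    stop("fewer than min_genes (", config$min_genes, ") fittable candidates")
  }
  if (n < length(selected) + 2L) {
    warning("few samples relative to selected genes; fit may be unstable")
  }
  X <- candidates[, selected, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, X), response)
  coefs <- fit$coefficients[-1L]
  names(coefs) <- colnames(candidates)[selected]
  rss <- sum(fit$residuals^2)
  tr <- do.call(rbind, lapply(trace, as.data.frame))
  structure(list(response_name = "response", intercept = unname(fit$coefficients[1L]),
                 coefficients = coefs, r2 = 1 - rss / tss, trace = tr,
                 standardize = standardize),
            class = "metagene_model")
}

#' Fit a random control metagene
#'
#' Draws a standard-normal response over the samples and a random pool of 20
#' candidate genes, then runs the same forward selection as the real
#' metagenes. The resulting model should carry no clinical signal; it is the
#' negative control for the grade and survival associations.
#'
#' @param expr gene x sample numeric matrix (the candidate gene universe,
#'   e.g. the variability-filtered expression).
#' @param config a \code{pipeline_config}.
#' @param seed integer seed for the response and gene draw.
#' @param n_pool number of genes to draw (default 20).
#' @return A \code{metagene_model} with response_name "random".
#' @export
random_metagene <- function(expr, config = pipeline_config(), seed = config$seed,
                            n_pool = 20L) {
  stopifnot(is.matrix(expr), nrow(expr) >= n_pool)
  set.seed(seed)
  response <- stats::rnorm(ncol(expr))
  pool <- sample(rownames(expr), n_pool)
  model <- forward_select_fit(response, t(expr[pool, , drop = FALSE]), config)
  model$response_name <- "random"
  model
}

#' Score a cohort with a metagene model
#'
#' Each model gene present in the cohort is standardized (z across patients);
#' a patient's score is intercept + sum of coefficient * z-expression. Model
#' genes absent from the cohort contribute 0 and are reported via a message.
#'
#' @param model a \code{metagene_model}.
#' @param cohort_expr numeric matrix, genes x patients.
#' @return Named numeric vector of per-patient scores.
#' @export
score_cohort <- function(model, cohort_expr) {
  stopifnot(inherits(model, "metagene_model"), is.matrix(cohort_expr))
  genes <- names(model$coefficients)
  present <- intersect(genes, rownames(cohort_expr))
  if (!length(present)) stop("no model genes present in the cohort")
  missing <- setdiff(genes, present)
  if (length(missing)) {
    message("model genes absent from cohort (contribute 0): ",
            paste(missing, collapse = ", "))
  }
  m <- cohort_expr[present, , drop = FALSE]
  sds <- apply(m, 1L, stats::sd)
  sds[sds == 0] <- 1
  z <- (m - rowMeans(m)) / sds
  model$intercept + drop(crossprod(z, model$coefficients[present]))
}

#' NF-kB (RELA) TNF response per cell line
#'
#' The response is the natural log of the mean nuclear/cytoplasmic RELA
#' intensity ratio with TNF over the mean ratio without TNF.
#'
#' @param measurements data.frame with columns cell_line, ratio_tnf (mean
#'   nuclear/cytoplasmic ratio +TNF), ratio_ctrl (mean ratio -TNF); all
#'   ratios must be positive.
#' @return A \code{rela_response}: data.frame(cell_line, ratio_tnf,
#'   ratio_ctrl, response) with attribute log_base = "natural".
#' @export
rela_response <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("cell_line", "ratio_tnf", "ratio_ctrl") %in% names(measurements)))
  bad <- measurements$cell_line[measurements$ratio_tnf <= 0 |
                                  measurements$ratio_ctrl <= 0]
  if (length(bad)) {
    stop("non-positive RELA ratio for cell line(s): ", paste(bad, collapse = ", "))
  }
  out <- measurements
  out$response <- log(out$ratio_tnf / out$ratio_ctrl)
  attr(out, "log_base") <- "natural"
  class(out) <- c("rela_response", "data.frame")
  out
}

#' Serialize a metagene model to JSON
#' @param model a \code{metagene_model}.
#' @param path output path.
#' @export
write_metagene <- function(model, path) {
  obj <- list(response = model$response_name, intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              r2 = model$r2, standardize = model$standardize,
              trace = model$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a metagene model from JSON
#' @param path JSON path written by \code{\link{write_metagene}}.
#' @return a \code{metagene_model}.
#' @export
read_metagene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(response_name = obj$response, intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients), r2 = obj$r2,
                 trace = obj$trace, standardize = obj$standardize),
            class = "metagene_model")
}

#' @export
print.metagene_model <- function(x, ...) {
  terms <- paste(sprintf("%+.3f x %s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("metagene '%s': %s %+0.3f (R^2 = %.3f)\n",
              x$response_name, terms, x$intercept, x$r2))
  invisible(x)
}
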