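#' Pipeline configuration
#'
#' Every numeric threshold and convention used by the pipeline lives in one
#' validated object; stage code reads thresholds only from here, never from
#' literals. Defaults are the published analysis values.
#'
#' @param sd_cutoff expression-SD floor across cell lines; genes whose
#'   cross-line SD is at or below this are treated as non-variable.
#' @param rho_cutoff absolute Spearman correlation threshold for calling a
#'   gene shape-correlated.
#' @param string_min_score combined interaction score floor (0-1 scale).
#' @param kd_valid_z knockdown validity ceiling: a knockdown counts as valid
#'   only if it drives the targeted gene's z-score below this (negative) value.
#' @param target_z absolute z-score defining a significant expression change.
#' @param coverage_frac minimum fraction of a TF's targets a putative
#'   activation regulator must perturb.
#' @param hyper_alpha significance level for the hypergeometric overlap test.
#' @param dz_cutoff cluster-mean z difference above which a gene is called
#'   differentially expressed between the two cell-line clusters.
#' @param expr_floor raw (log-scale) expression floor for retaining
#'   non-differential genes in the cluster-specific networks.
#' @param r2_stop forward-selection R-squared stopping bound.
#' @param min_genes,max_genes bounds on the number of genes a metagene model
#'   may select.
#' @param cut_quantiles ordered candidate dichotomization quantiles for
#'   survival stratification.
#' @param path_slack extra hops allowed beyond the shortest feature-to-TF path
#'   when enumerating suboptimal paths.
#' @param tf_list preselected transcription-factor identifiers.
#' @param fdr_method "BH" (default) or "storey" for the correlation screen
#'   q-values.
#' @param seed master random seed.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sd_cutoff = 0.3,
                            rho_cutoff = 0.7,
                            string_min_score = 0.4,
                            kd_valid_z = -0.4,
                            target_z = 1.5,
                            coverage_frac = 0.10,
                            hyper_alpha = 0.05,
                            dz_cutoff = 0.5,
                            expr_floor = 7.0,
                            r2_stop = 0.9,
                            min_genes = 4L,
                            max_genes = 10L,
                            cut_quantiles = seq(0.2, 0.8, by = 0.1),
                            path_slack = 1L,
                            tf_list = c("KLF4", "MYC", "RELA", "SOX2", "SMAD2",
                                        "SMAD3", "SNAI1", "SNAI2", "TWIST1",
                                        "ZEB1", "ZEB2", "YAP1"),
                            fdr_method = "BH",
                            seed = 1L) {
  cfg <- list(sd_cutoff = as.numeric(sd_cutoff),
              rho_cutoff = as.numeric(rho_cutoff),
              string_min_score = as.numeric(string_min_score),
              kd_valid_z = as.numeric(kd_valid_z),
              target_z = as.numeric(target_z),
              coverage_frac = as.numeric(coverage_frac),
              hyper_alpha = as.numeric(hyper_alpha),
              dz_cutoff = as.numeric(dz_cutoff),
              expr_floor = as.numeric(expr_floor),
              r2_stop = as.numeric(r2_stop),
              min_genes = as.integer(min_genes),
              max_genes = as.integer(max_genes),
              cut_quantiles = as.numeric(cut_quantiles),
              path_slack = as.integer(path_slack),
              tf_list = as.character(tf_list),
              fdr_method = as.character(fdr_method),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$sd_cutoff) && cfg$sd_cutoff >= 0, "sd_cutoff", "must be >= 0")
  chk(num1(cfg$rho_cutoff) && cfg$rho_cutoff > 0 && cfg$rho_cutoff < 1,
      "rho_cutoff", "must lie in (0, 1)")
  chk(num1(cfg$string_min_score) && cfg$string_min_score >= 0 &&
        cfg$string_min_score <= 1, "string_min_score", "must lie in [0, 1]")
  chk(num1(cfg$kd_valid_z) && cfg$kd_valid_z < 0, "kd_valid_z", "must be < 0")
  chk(num1(cfg$target_z) && cfg$target_z > 0, "target_z", "must be > 0")
  chk(num1(cfg$coverage_frac) && cfg$coverage_frac > 0 && cfg$coverage_frac < 1,
      "coverage_frac", "must lie in (0, 1)")
  chk(num1(cfg$hyper_alpha) && cfg$hyper_alpha > 0 && cfg$hyper_alpha < 1,
      "hyper_alpha", "must lie in (0, 1)")
  chk(num1(cfg$dz_cutoff) && cfg$dz_cutoff >= 0, "dz_cutoff", "must be >= 0")
  chk(num1(cfg$expr_floor), "expr_floor", "must be a finite number")
  chk(num1(cfg$r2_stop) && cfg$r2_stop > 0 && cfg$r2_stop <= 1,
      "r2_stop", "must lie in (0, 1]")
  chk(length(cfg$min_genes) == 1L && !is.na(cfg$min_genes) && cfg$min_genes >= 1L,
      "min_genes", "must be a positive integer")
  chk(length(cfg$max_genes) == 1L && !is.na(cfg$max_genes) &&
        cfg$min_genes <= cfg$max_genes, "max_genes", "must be >= min_genes")
  chk(length(cfg$cut_quantiles) >= 1L && all(is.finite(cfg$cut_quantiles)) &&
        all(cfg$cut_quantiles > 0) && all(cfg$cut_quantiles < 1) &&
        all(diff(cfg$cut_quantiles) > 0),
      "cut_quantiles", "must be strictly increasing within (0, 1)")
  chk(length(cfg$path_slack) == 1L && !is.na(cfg$path_slack) && cfg$path_slack >= 0L,
      "path_slack", "must be a non-negative integer")
  chk(length(cfg$tf_list) >= 1L && !anyDuplicated(cfg$tf_list),
      "tf_list", "must be a non-empty set of unique identifiers")
  chk(cfg$fdr_method %in% c("BH", "storey"), "fdr_method",
      "must be 'BH' or 'storey'")
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed", "must be an integer")
  invisible(cfg)
}

#' Load a pipeline configuration from a key=value text file
#'
#' Absent keys take their defaults; unknown keys are rejected. Lines starting
#' with \code{#} and blank lines are ignored. List-valued fields
#' (\code{cut_quantiles}, \code{tf_list}) are comma-separated.
#'
#' @param path path to a plain-text key=value file.
#' @return A validated \code{pipeline_config}.
#' @export
load_config <- function(path) {
  stopifnot(length(path) == 1L, file.exists(path))
  lines <- readLines(path, warn = FALSE)
  defaults <- pipeline_config()
  out <- unclass(defaults)
  int_fields <- c("min_genes", "max_genes", "path_slack", "seed")
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config parse error at line ", i, ": expected key=value, got '",
           ln, "'", call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(out)) {
      stop("config parse error at line ", i, ": unknown key '", key, "'",
           call. = FALSE)
    }
    parsed <- if (key == "tf_list") {
      trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    } else if (key == "fdr_method") {
      val
    } else {
      v <- suppressWarnings(as.numeric(trimws(strsplit(val, ",", fixed = TRUE)[[1L]])))
      if (anyNA(v)) {
        stop("config parse error at line ", i, ": non-numeric value for '",
             key, "'", call. = FALSE)
      }
      if (key %in% int_fields) as.integer(v) else v
    }
    out[[key]] <- parsed
  }
  class(out) <- "pipeline_config"
  validate_config(out)
  out
}

#' Write a pipeline configuration
#'
#' @param cfg a \code{pipeline_config}.
#' @param path output file path.
#' @param format "keyvalue" writes the same plain-text dialect
#'   \code{\link{load_config}} reads (round-trips exactly); "json" writes the
#'   resolved configuration for run provenance.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path, format = c("keyvalue", "json")) {
  format <- match.arg(format)
  validate_config(cfg)
  if (format == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  } else {
    fmt <- vapply(names(unclass(cfg)), function(k) {
      v <- cfg[[k]]
      paste0(k, " = ", paste(format(v, digits = 17, scientific = FALSE,
                                    trim = TRUE), collapse = ","))
    }, character(1))
    writeLines(fmt, path)
  }
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (k in names(unclass(x))) {
    cat(sprintf("  %-17s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
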