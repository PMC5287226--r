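# Latent scales of the ten morphological features: grand mean, between-line
# SD of line means, and typical within-line SD. Chosen once to resemble
# adherent breast-line morphology on a pixel/micron scale; see the methods
# vignette.
FEATURE_SCALES <- data.frame(
  feature = SHAPE_FEATURES,
  grand_mean = c(0.65, 2500, 14, 18, 220, 0.12, 4, 0.35, 120, 0.25),
  between_sd = c(0.10, 700, 2, 2.5, 40, 0.03, 1, 0.12, 40, 0.07),
  within_sd = c(0.12, 800, 2, 2.5, 50, 0.03, 1.5, 0.15, 60, 0.08),
  stringsAsFactors = FALSE)

#' Default planted ground truth
#'
#' Builds the planted world every downstream stage is tested against:
#' shape-correlated genes per feature statistic, TF regulons with signed
#' targets, expression/activation regulators with direction, the planted
#' metagene coefficients (a 4-gene cell-area-SD metagene and an NF-kB
#' response metagene over the RELA regulators), the log-hazard coefficient of
#' the metagene latent, and the quantile at which the planted survival split
#' is sharpest.
#'
#' @param config a \code{pipeline_config}.
#' @return A \code{planted_truth} list: shape_genes (data.frame statistic,
#'   gene, direction, effect), regulons (TF -> named sign vector), regulators
#'   (data.frame gene, tf, mode, direction, coverage), metagene_beta (list of
#'   response -> list(genes, beta, intercept, noise_sd)), hazard_beta,
#'   cut_quantile.
#' @export
default_truth <- function(config = pipeline_config()) {
  stats_used <- c("cell_area_mean", "cell_area_sd", "cell_wl_mean",
                  "cell_wl_sd", "neighbor_frac_mean", "neighbor_frac_sd",
                  "protrusion_area_mean", "protrusion_area_sd",
                  "nc_area_mean", "centers_dist_mean")
  per_stat <- 4L
  genes <- sprintf("SHP%03d", seq_len(per_stat * length(stats_used)))
  shape_genes <- data.frame(
    statistic = rep(stats_used, each = per_stat),
    gene = genes,
    direction = rep_len(c(1, -1), per_stat * length(stats_used)),
    effect = 4,  # signal-to-noise of the planted monotone link
    stringsAsFactors = FALSE)
  # SMAD3 is the one preselected TF whose expression tracks cell elongation
  shape_genes <- rbind(shape_genes,
                       data.frame(statistic = "cell_wl_mean", gene = "SMAD3",
                                  direction = 1, effect = 4,
                                  stringsAsFactors = FALSE))
  regulon <- function(prefix, k) {
    stats::setNames(rep_len(c(1, -1), k), sprintf("%sT%02d", prefix, seq_len(k)))
  }
  regulons <- list(SMAD3 = regulon("S", 20L), RELA = regulon("R", 20L),
                   YAP1 = regulon("Y", 10L))
  regulators <- data.frame(
    gene = c("SHP001", "SHP002", "SHP005", "SHP009", "SHP010", "SHP013",
             "SHP014", "SHP017", "SHP018"),
    tf = c("SMAD3", "SMAD3", "SMAD3", "RELA", "RELA", "RELA", "RELA",
           "YAP1", "YAP1"),
    mode = c("activation", "activation", "expression",
             "activation", "activation", "expression", "activation",
             "activation", "expression"),
    direction = c("activator", "inhibitor", "down",
                  "activator", "inhibitor", "up", "activator",
                  "activator", "down"),
    coverage = 0.6,
    stringsAsFactors = FALSE)
  area_sd_genes <- shape_genes$gene[shape_genes$statistic == "cell_area_sd"]
  area_sd_beta <- c(0.23, 0.25, -0.15, 0.18)
  # the planted correlation directions of the metagene's genes agree with
  # the metagene coefficient signs, so a metagene fitted on the morphology
  # statistic tracks the cohort's planted latent
  shape_genes$direction[match(area_sd_genes, shape_genes$gene)] <-
    sign(area_sd_beta)
  rela_reg <- regulators$gene[regulators$tf == "RELA"]
  metagene_beta <- list(
    cell_area_sd = list(genes = area_sd_genes,
                        beta = area_sd_beta,
                        intercept = 1.21, noise_sd = 0.05),
    nfkb = list(genes = rela_reg, beta = c(0.4, -0.3, 0.25, 0.2),
                intercept = 0.1, noise_sd = 0.05))
  truth <- list(shape_genes = shape_genes, regulons = regulons,
                regulators = regulators, metagene_beta = metagene_beta,
                hazard_beta = 0.7, cut_quantile = 0.6)
  class(truth) <- "planted_truth"
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  if (!all(truth$regulators$tf %in% names(truth$regulons))) {
    stop("regulator references a TF absent from the regulons")
  }
  for (r in names(truth$metagene_beta)) {
    mb <- truth$metagene_beta[[r]]
    if (length(mb$genes) != length(mb$beta)) {
      stop("metagene '", r, "': genes and beta lengths differ")
    }
  }
  invisible(truth)
}

# All gene identifiers the truth plants; each must exist in the generated
# expression matrix.
truth_genes <- function(truth) {
  unique(c(truth$shape_genes$gene,
           unlist(lapply(truth$regulons, names), use.names = FALSE),
           names(truth$regulons),
           truth$regulators$gene,
           unlist(lapply(truth$metagene_beta, `[[`, "genes"), use.names = FALSE)))
}

#' Simulate a single-cell morphology table
#'
#' Per-line latent feature means are drawn from a Gaussian over lines and
#' cells are drawn Gaussian around their line mean with a line-specific SD.
#' Cell elongation (cell_wl) is generated as a latent per-cell feature and the
#' raw cell_width column is derived as cell_wl * cell_length, so the derived
#' width/length feature recovers it exactly.
#'
#' @param config a \code{pipeline_config}.
#' @param n_lines number of cell lines (>= 2).
#' @param n_cells_per_line cells per line (>= 2).
#' @param noise_scale multiplier on the within-line SDs (0 gives identical
#'   cells per line).
#' @param seed random seed (default \code{config$seed}).
#' @return list(cells = data.frame (cell_line + raw columns), latent_mean,
#'   latent_sd = lines x features matrices of the latent values).
#' @export
simulate_cell_table <- function(config = pipeline_config(), n_lines = 18L,
                                n_cells_per_line = 100L, noise_scale = 1,
                                seed = config$seed) {
  if (n_lines < 2L || n_cells_per_line < 2L) {
    stop("n_lines and n_cells_per_line must both be at least 2")
  }
  set.seed(seed)
  lines <- sprintf("BCL%02d", seq_len(n_lines))
  nf <- nrow(FEATURE_SCALES)
  latent_mean <- matrix(stats::rnorm(n_lines * nf,
                                     mean = rep(FEATURE_SCALES$grand_mean, each = n_lines),
                                     sd = rep(FEATURE_SCALES$between_sd, each = n_lines)),
                        nrow = n_lines, dimnames = list(lines, SHAPE_FEATURES))
  latent_sd <- matrix(abs(stats::rnorm(n_lines * nf,
                                       mean = rep(FEATURE_SCALES$within_sd, each = n_lines),
                                       sd = rep(FEATURE_SCALES$within_sd / 4, each = n_lines))),
                      nrow = n_lines, dimnames = list(lines, SHAPE_FEATURES)) *
    noise_scale
  total <- n_lines * n_cells_per_line
  line_idx <- rep(seq_len(n_lines), each = n_cells_per_line)
  feat <- sapply(SHAPE_FEATURES, function(f) {
    latent_mean[line_idx, f] + latent_sd[line_idx, f] * stats::rnorm(total)
  })
  cell_length <- stats::rnorm(total, 45, 4)
  cells <- data.frame(cell_line = rep(lines, each = n_cells_per_line),
                      cell_width = feat[, "cell_wl"] * cell_length,
                      cell_length = cell_length,
                      cell_area = feat[, "cell_area"],
                      nuc_width = feat[, "nuc_width"],
                      nuc_length = feat[, "nuc_length"],
                      nuc_area = feat[, "nuc_area"],
                      nc_area = feat[, "nc_area"],
                      centers_dist = feat[, "centers_dist"],
                      neighbor_frac = feat[, "neighbor_frac"],
                      protrusion_area = feat[, "protrusion_area"],
                      ruffliness = feat[, "ruffliness"],
                      stringsAsFactors = FALSE)
  list(cells = cells, latent_mean = latent_mean, latent_sd = latent_sd)
}

#' Simulate an expression matrix with planted shape-correlated genes
#'
#' Planted shape genes are monotone (linear) transforms of their feature
#' statistic plus Gaussian noise scaled by the planted effect
#' (signal-to-noise) value; other truth genes and background genes are i.i.d.
#' N(8, 1.5) on the log scale; a fraction of background genes is emitted with
#' cross-line SD below the variability cutoff to exercise the filter; a
#' fraction of genes is emitted as two probes.
#'
#' @param config a \code{pipeline_config}.
#' @param truth a \code{planted_truth}.
#' @param summary a \code{feature_summary} with >= 3 lines.
#' @param n_genes total number of genes (>= number of planted genes).
#' @param noise_scale multiplier on the planted-gene noise and the low-SD
#'   jitter (0 gives exact monotone links and constant low-SD genes).
#' @param low_sd_frac fraction of background genes generated below the SD
#'   cutoff.
#' @param multi_probe_frac fraction of genes emitted as two probes.
#' @param seed random seed (default \code{config$seed + 1}).
#' @return an \code{expr_matrix} (samples = summary cell lines).
#' @export
simulate_expression <- function(config = pipeline_config(), truth = default_truth(config),
                                summary, n_genes = 400L, noise_scale = 1,
                                low_sd_frac = 0.3, multi_probe_frac = 0.1,
                                seed = config$seed + 1L) {
  stopifnot(inherits(summary, "feature_summary"))
  if (nrow(summary) < 3L) stop("summary needs at least 3 lines")
  set.seed(seed)
  lines <- summary$cell_line
  n <- length(lines)
  planted <- truth_genes(truth)
  if (n_genes < length(planted)) {
    stop("n_genes (", n_genes, ") smaller than the ", length(planted),
         " planted genes")
  }
  n_bg <- n_genes - length(planted)
  bg_genes <- sprintf("BG%04d", seq_len(n_bg))
  all_genes <- c(planted, bg_genes)
  vals <- matrix(stats::rnorm(length(all_genes) * n, 8, 1.5),
                 nrow = length(all_genes), dimnames = list(all_genes, lines))
  # planted shape genes: linear link to the statistic, amplitude 1.2 on the
  # z scale, noise = amplitude / effect
  for (i in seq_len(nrow(truth$shape_genes))) {
    sg <- truth$shape_genes[i, ]
    sv <- summary[[sg$statistic]]
    zv <- (sv - mean(sv)) / stats::sd(sv)
    amp <- 1.2
    vals[sg$gene, ] <- 8 + amp * sg$direction * zv +
      (amp / sg$effect) * noise_scale * stats::rnorm(n)
  }
  # low-variability background mode (exercises the SD filter)
  n_low <- floor(low_sd_frac * n_bg)
  if (n_low > 0) {
    low <- bg_genes[seq_len(n_low)]
    vals[low, ] <- stats::rnorm(n_low, 8, 1.5) +
      0.05 * noise_scale * matrix(stats::rnorm(n_low * n), nrow = n_low)
  }
  # multi-probe genes: second probe = profile + small probe offset
  n_multi <- floor(multi_probe_frac * length(all_genes))
  multi <- all_genes[seq_len(n_multi)]
  probe_gene <- c(all_genes, multi)
  probe_vals <- rbind(vals, vals[multi, , drop = FALSE] +
                        0.05 * noise_scale *
                        matrix(stats::rnorm(length(multi) * n), nrow = length(multi)))
  rownames(probe_vals) <- sprintf("P%05d", seq_len(nrow(probe_vals)))
  expr_matrix(probe_vals, probe_gene)
}

#' Simulate a STRING-dialect interaction table with planted routes
#'
#' Plants, for every regulator in the truth, a high-confidence edge to its TF
#' (so each feature-statistic correlated with the regulator is two hops from
#' the TF), plus random gene-gene edges above the score floor and a set of
#' sub-threshold edges that the loader must drop. Scores are written on the
#' 0-1000 integer dialect.
#'
#' @param config a \code{pipeline_config}.
#' @param truth a \code{planted_truth}.
#' @param n_random random above-threshold edges among shape genes.
#' @param n_below sub-threshold edges.
#' @param seed random seed (default \code{config$seed + 2}).
#' @return data.frame(protein1, protein2, combined_score) on the 0-1000 scale.
#' @export
simulate_interactions <- function(config = pipeline_config(),
                                  truth = default_truth(config),
                                  n_random = 40L, n_below = 10L,
                                  seed = config$seed + 2L) {
  set.seed(seed)
  reg_edges <- data.frame(protein1 = truth$regulators$gene,
                          protein2 = truth$regulators$tf,
                          combined_score = 900L, stringsAsFactors = FALSE)
  pool <- unique(truth$shape_genes$gene)
  rnd <- function(k, lo, hi) {
    a <- sample(pool, k, replace = TRUE)
    b <- sample(pool, k, replace = TRUE)
    keep <- a != b
    data.frame(protein1 = a[keep], protein2 = b[keep],
               combined_score = sample(lo:hi, sum(keep), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(reg_edges, rnd(n_random, 400L, 999L), rnd(n_below, 100L, 399L))
  edges[!duplicated(paste(pmin(edges$protein1, edges$protein2),
                          pmax(edges$protein1, edges$protein2))), ]
}

#' Simulate a knockdown expression panel with planted regulatory effects
#'
#' Builds a raw (pre-consolidation) panel in approximate z units. Each
#' perturbation column drives its targeted gene to about -2 (valid) or -0.2
#' (planted invalid columns). A TF knockdown shifts its regulon targets by
#' their planted signs; an activation-regulator knockdown shifts the planted
#' coverage fraction of the TF's targets concordantly (activator) or
#' discordantly (inhibitor) without touching the TF itself; an
#' expression-regulator knockdown shifts the TF's measured value past the
#' significance threshold. A configurable set of perturbations is emitted as
#' duplicate probes.
#'
#' @param config a \code{pipeline_config}.
#' @param truth a \code{planted_truth}.
#' @param n_measured measured genes (>= all truth genes).
#' @param extra_perturbations background-gene knockdowns added beyond the
#'   truth-driven ones.
#' @param noise_scale baseline noise multiplier (0 = noise-free planting).
#' @param n_invalid planted invalid knockdown columns (weak on-target effect).
#' @param n_duplicate number of truth perturbations emitted as two probes.
#' @param seed random seed (default \code{config$seed + 3}).
#' @return list(panel = raw \code{kd_panel}, invalid = perturbation ids
#'   planted invalid).
#' @export
simulate_knockdown_panel <- function(config = pipeline_config(),
                                     truth = default_truth(config),
                                     n_measured = 120L,
                                     extra_perturbations = 10L,
                                     noise_scale = 1, n_invalid = 2L,
                                     n_duplicate = 2L,
                                     seed = config$seed + 3L) {
  set.seed(seed)
  tg <- truth_genes(truth)
  if (n_measured < length(tg)) {
    stop("n_measured smaller than the number of planted genes")
  }
  measured <- c(tg, sprintf("KBG%03d", seq_len(n_measured - length(tg))))
  kd_targets <- c(names(truth$regulons), truth$regulators$gene,
                  sample(setdiff(measured, c(names(truth$regulons),
                                             truth$regulators$gene)),
                         extra_perturbations))
  shift <- 2.5
  # on-target depth exceeds every planted trans effect so the targeted gene
  # keeps the most-negative value in its own column
  build_col <- function(target, valid = TRUE) {
    col <- 0.3 * noise_scale * stats::rnorm(length(measured))
    names(col) <- measured
    col[target] <- if (valid) -3 else -0.2
    if (target %in% names(truth$regulons)) {
      reg <- truth$regulons[[target]]
      col[names(reg)] <- reg * shift + 0.1 * noise_scale * stats::rnorm(length(reg))
    }
    hit <- truth$regulators[truth$regulators$gene == target, , drop = FALSE]
    for (h in seq_len(nrow(hit))) {
      tf <- hit$tf[h]
      reg <- truth$regulons[[tf]]
      if (hit$mode[h] == "activation") {
        k <- ceiling(hit$coverage[h] * length(reg))
        tt <- reg[seq_len(k)]
        sgn <- if (hit$direction[h] == "activator") 1 else -1
        col[names(tt)] <- sgn * tt * shift +
          0.1 * noise_scale * stats::rnorm(k)
      } else {
        col[tf] <- if (hit$direction[h] == "up") shift else -shift
      }
    }
    col
  }
  cols <- list()
  targets <- character(0)
  for (g in kd_targets) {
    reps <- if (match(g, kd_targets) <= n_duplicate) 2L else 1L
    for (r in seq_len(reps)) {
      id <- paste0(g, "_p", r)
      cols[[id]] <- build_col(g, valid = TRUE)
      targets <- c(targets, g)
    }
  }
  inv_genes <- utils::tail(kd_targets, n_invalid)
  invalid_ids <- character(0)
  for (g in inv_genes) {
    id <- paste0(g, "_weak")
    cols[[id]] <- build_col(g, valid = FALSE)
    targets <- c(targets, g)
    invalid_ids <- c(invalid_ids, id)
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- measured
  list(panel = kd_panel(vals, targets), invalid = invalid_ids)
}

#' Simulate a patient cohort with a planted metagene-hazard association
#'
#' Patient expression is i.i.d. Gaussian per gene; the latent metagene is the
#' planted linear combination of standardized expression; grade is a
#' three-level discretization of the latent plus noise; survival times are
#' exponential with log-hazard either proportional to the standardized latent
#' ("linear") or stepping up above the planted quantile of the latent
#' ("step"); censoring is independent; node status and tumor size are mildly
#' grade-correlated.
#'
#' @param config a \code{pipeline_config}.
#' @param truth a \code{planted_truth}.
#' @param n_patients number of patients (>= 20).
#' @param response which planted metagene drives the cohort (default
#'   "cell_area_sd").
#' @param hazard_form "linear" (log-hazard = hazard_beta * standardized
#'   latent) or "step" (log-hazard jumps by hazard_beta above the planted
#'   cut_quantile of the latent).
#' @param hazard_beta log-hazard coefficient (default
#'   \code{truth$hazard_beta}; 0 gives a null cohort).
#' @param grade_noise SD of the noise added to the latent before the grade
#'   discretization.
#' @param censor_frac approximate fraction censored (1 censors everyone).
#' @param n_background background genes added to the expression block.
#' @param extra_genes optional further gene ids measured on the cohort
#'   (i.i.d. background); lets models fitted on the cell-line transcriptome
#'   (e.g. random control metagenes) be scored on the cohort.
#' @param seed random seed (default \code{config$seed + 4}).
#' @return list(cohort = clinical data.frame, expression = genes x patients
#'   matrix, latent = planted per-patient metagene value).
#' @export
simulate_cohort <- function(config = pipeline_config(),
                            truth = default_truth(config),
                            n_patients = 400L, response = "cell_area_sd",
                            hazard_form = c("step", "linear"),
                            hazard_beta = truth$hazard_beta,
                            grade_noise = 0.5, censor_frac = 0.25,
                            n_background = 30L, extra_genes = NULL,
                            seed = config$seed + 4L) {
  hazard_form <- match.arg(hazard_form)
  if (n_patients < 20L) stop("need at least 20 patients")
  if (!response %in% names(truth$metagene_beta)) {
    stop("unknown planted response '", response, "'")
  }
  set.seed(seed)
  mb <- truth$metagene_beta[[response]]
  genes <- unique(c(unlist(lapply(truth$metagene_beta, `[[`, "genes")),
                    sprintf("CBG%03d", seq_len(n_background)), extra_genes))
  expr <- matrix(stats::rnorm(length(genes) * n_patients, 8, 1.5),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("PT%04d", seq_len(n_patients))))
  z <- t(scale(t(expr[mb$genes, , drop = FALSE])))
  latent <- drop(crossprod(z, mb$beta)) + mb$intercept +
    mb$noise_sd * stats::rnorm(n_patients)
  lz <- as.vector(scale(latent))
  grade_score <- lz + grade_noise * stats::rnorm(n_patients)
  grade <- as.integer(cut(grade_score,
                          breaks = stats::quantile(grade_score, c(0, 1/3, 2/3, 1)),
                          include.lowest = TRUE, labels = FALSE))
  base_rate <- 0.008  # per month; ~60% 10-yr event rate at the baseline
  loghaz <- if (hazard_form == "linear") {
    hazard_beta * lz
  } else {
    hazard_beta * (latent > stats::quantile(latent, truth$cut_quantile))
  }
  t_death <- stats::rexp(n_patients, rate = base_rate * exp(loghaz))
  if (censor_frac >= 1) {
    time <- stats::rexp(n_patients, rate = base_rate)
    event <- rep(0L, n_patients)
  } else {
    rate_c <- base_rate * censor_frac / (1 - censor_frac)
    t_cens <- if (rate_c > 0) stats::rexp(n_patients, rate = rate_c) else
      rep(Inf, n_patients)
    event <- as.integer(t_death <= t_cens)
    time <- pmin(t_death, t_cens)
  }
  node_count <- stats::rbinom(n_patients, 3, 0.12 + 0.1 * (grade - 1))
  tumor_size_cm <- pmax(0.2, stats::rnorm(n_patients, 1.2 + 0.4 * grade, 0.8))
  subtype <- sample(c("LumA", "LumB", "Her2", "Basal", "Normal"),
                    n_patients, replace = TRUE,
                    prob = c(0.35, 0.2, 0.15, 0.2, 0.1))
  cohort <- data.frame(patient_id = colnames(expr), time = time, event = event,
                       grade = grade, subtype = subtype,
                       node_count = node_count, tumor_size_cm = tumor_size_cm,
                       stringsAsFactors = FALSE)
  list(cohort = cohort, expression = expr, latent = latent)
}

#' Write a full synthetic dataset to disk
#'
#' Emits the five delimited inputs the real-data readers consume (single-cell
#' TSV, expression TSV, STRING-dialect edge TSV, knockdown TSV + perturbation
#' map, cohort CSV) plus a JSON truth file, all derived deterministically
#' from the config seed.
#'
#' @param dir output directory (created if needed).
#' @param config a \code{pipeline_config}.
#' @param n_lines,n_cells_per_line,n_genes,n_patients scale parameters.
#' @return Invisibly, a named vector of the written paths.
#' @export
write_synthetic_dataset <- function(dir, config = pipeline_config(),
                                    n_lines = 18L, n_cells_per_line = 100L,
                                    n_genes = 400L, n_patients = 400L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- default_truth(config)
  sim <- simulate_cell_table(config, n_lines, n_cells_per_line)
  summary <- summarize_features(sim$cells)
  expr <- simulate_expression(config, truth, summary, n_genes)
  edges <- simulate_interactions(config, truth)
  kd <- simulate_knockdown_panel(config, truth)
  coh <- simulate_cohort(config, truth, n_patients)
  p <- c(cells = file.path(dir, "cells.tsv"),
         expression = file.path(dir, "expression.tsv"),
         edges = file.path(dir, "interactions.tsv"),
         kd_values = file.path(dir, "knockdown.tsv"),
         kd_map = file.path(dir, "knockdown_map.tsv"),
         cohort = file.path(dir, "cohort.csv"),
         truth = file.path(dir, "truth.json"))
  utils::write.table(sim$cells, p["cells"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression(expr, p["expression"])
  utils::write.table(edges, p["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kd_df <- data.frame(gene = rownames(kd$panel$values), kd$panel$values,
                      check.names = FALSE)
  utils::write.table(kd_df, p["kd_values"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(perturbation = colnames(kd$panel$values),
                                target = kd$panel$target),
                     p["kd_map"], sep = "\t", quote = FALSE, row.names = FALSE)
  coh_df <- cbind(coh$cohort,
                  stats::setNames(as.data.frame(t(coh$expression)),
                                  paste0("expr_", rownames(coh$expression))))
  utils::write.csv(coh_df, p["cohort"], row.names = FALSE)
  jsonlite::write_json(unclass(truth), p["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(p)
}
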