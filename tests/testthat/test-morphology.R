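make_cells <- function(df_list) {
  # build a minimal cell table; unspecified columns get constant filler
  base <- do.call(rbind, df_list)
  for (col in setdiff(CELL_COLUMNS <- c("cell_width", "cell_length", "cell_area",
                                        "nuc_width", "nuc_length", "nuc_area",
                                        "nc_area", "centers_dist", "neighbor_frac",
                                        "protrusion_area", "ruffliness"),
                      names(base))) {
    base[[col]] <- 1
  }
  base
}

test_that("summarize_features: hand arithmetic, degenerate SD and errors", {
  cells <- make_cells(list(data.frame(cell_line = "A",
                                      cell_area = c(100, 200, 300))))
  s <- summarize_features(cells)
  expect_equal(s$cell_area_mean, 200)
  expect_equal(s$cell_area_sd, 100)  # sample SD, n-1 denominator
  expect_equal(s$cell_wl_mean, 1)    # filler width/length = 1/1
  expect_equal(s$cell_wl_sd, 0)

  same <- make_cells(list(data.frame(cell_line = "A", cell_area = c(5, 5, 5))))
  ssame <- summarize_features(same)
  expect_true(all(as.matrix(ssame[grepl("_sd$", names(ssame))]) == 0))

  one <- make_cells(list(data.frame(cell_line = c("A", "A", "B"),
                                    cell_area = c(1, 2, 3))))
  expect_error(summarize_features(one), "B")
})

test_that("summaries match an independent two-pass mean/SD recomputation", {
  sim <- simulate_cell_table(pipeline_config(), n_lines = 6, n_cells_per_line = 40,
                             seed = 7)
  s <- summarize_features(sim$cells)
  # independent recomputation with two-pass formulas
  wl <- sim$cells$cell_width / sim$cells$cell_length
  for (l in unique(sim$cells$cell_line)) {
    v <- wl[sim$cells$cell_line == l]
    mu <- sum(v) / length(v)
    sdv <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    expect_equal(s$cell_wl_mean[s$cell_line == l], mu)
    expect_equal(s$cell_wl_sd[s$cell_line == l], sdv)
  }
  # and empirical per-line means sit within 3 SE of the recorded latents
  for (f in c("cell_area", "neighbor_frac")) {
    se <- sim$latent_sd[, f] / sqrt(40)
    expect_true(all(abs(s[[paste0(f, "_mean")]] - sim$latent_mean[, f]) < 3.5 * se))
  }
})

test_that("filter_variable_genes collapses probes first and thresholds on SD", {
  n <- 18
  vals <- rbind(const = rep(7, n),
                alt = rep(c(7, 8), length.out = n),   # SD ~ 0.51 > 0.3
                g1 = rnorm(n, 8, 1.5),
                g1b = rnorm(n, 8, 1.5))
  rownames(vals) <- c("p1", "p2", "p3", "p4")
  colnames(vals) <- paste0("L", seq_len(n))
  e <- expr_matrix(vals, c("CONST", "ALT", "G1", "G1"))
  expect_equal(sd(rep(c(7, 8), length.out = n)), 0.5144958, tolerance = 1e-6)
  kept <- filter_variable_genes(e, 0.3)
  expect_false("CONST" %in% kept)
  expect_true("ALT" %in% kept)
  # the two G1 probes were averaged into one gene profile
  expect_equal(sum(kept == "G1"), 1L)
  expect_equal(unname(collapse_probes(e)["G1", ]),
               unname((vals[3, ] + vals[4, ]) / 2))
})

test_that("the screen's p-values follow the t-approximation and its examples", {
  # |rho| = 0.7 at n = 18: the t-approximation p equals the printed 0.0012
  # bound at its printed precision (the screen keeps rho strictly above 0.7,
  # so every significant pair has p below this)
  p_thresh <- 2 * pt(-0.7 * sqrt(16 / (1 - 0.49)), df = 16)
  expect_lte(round(p_thresh, 4), 0.0012)
  expect_lt(2 * pt(-0.701 * sqrt(16 / (1 - 0.701^2)), df = 16), 0.0012)

  set.seed(3)
  n <- 18
  summary <- summarize_features(simulate_cell_table(pipeline_config(),
                                                    n_lines = n,
                                                    n_cells_per_line = 20,
                                                    seed = 3)$cells)
  # a gene exactly equal to a feature statistic: rho = 1, p = smallest positive
  vals <- rbind(exact = summary$cell_area_mean, noise = rnorm(n, 8, 2))
  rownames(vals) <- c("pe", "pn")
  colnames(vals) <- summary$cell_line
  e <- expr_matrix(vals, c("EXACT", "NOISE"))
  res <- correlate_shape(e, summary, pipeline_config(sd_cutoff = 0))
  rec <- res$records[res$records$gene == "EXACT" &
                       res$records$statistic == "cell_area_mean", ]
  expect_equal(rec$rho, 1)
  expect_gt(rec$p, 0)
  expect_lt(rec$p, 1e-300)
  expect_error(correlate_shape(e, summary[1:3, ], pipeline_config()),
               "same set")
})

test_that("Spearman rho and p agree with a full permutation oracle at n = 6", {
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(6)
    y <- rnorm(6)
    o <- oracle_spearman_perm(x, y)
    got <- shapegenet:::spearman_test(x, y)
    expect_equal(unname(got["rho"]), o$rho, tolerance = 1e-12)
    # t-approximation within 2x of the exact permutation p
    expect_lt(unname(got["p"]) / o$p, 2)
    expect_gt(unname(got["p"]) / o$p, 0.5)
  }
})

test_that("screen invariants: cutoff monotonicity, BH stability, monotone maps", {
  cfg <- pipeline_config()
  sim <- simulate_cell_table(cfg, n_lines = 10, n_cells_per_line = 30, seed = 5)
  s <- summarize_features(sim$cells)
  truth <- default_truth(cfg)
  e <- simulate_expression(cfg, truth, s, n_genes = 150, seed = 5)
  lo <- correlate_shape(e, s, pipeline_config(rho_cutoff = 0.6))
  hi <- correlate_shape(e, s, pipeline_config(rho_cutoff = 0.8))
  expect_true(nrow(hi$significant) <= nrow(lo$significant))
  key <- function(d) paste(d$gene, d$statistic)
  expect_true(all(key(hi$significant) %in% key(lo$significant)))

  # q-values: permutation-invariant per pair, bounded by [min p, 1]
  r <- lo$records[!is.na(lo$records$p), ]
  expect_true(all(r$q >= min(r$p) - 1e-15 & r$q <= 1))

  # Spearman invariant under strictly monotone transforms
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(shapegenet:::spearman_test(exp(x), y),
               shapegenet:::spearman_test(x, y))
  expect_equal(shapegenet:::spearman_test(x, y^3 + 2 * y),
               shapegenet:::spearman_test(x, y))
})
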