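cfg <- pipeline_config()

# Hand-built raw panel: measured genes TF, REG, g1..g12. Columns knock down
# REG (two probes), TF, g1 (one valid + one weak/invalid) and g2..g7.
# TF regulon = {g1+, g2-, g3+, g4-}; REG perturbs g1..g3 concordantly.
# Spikes are +-5 so the planted changes survive the per-gene re-z-scoring
# across the 9 consolidated columns.
hand_panel <- function() {
  genes <- c("TF", "REG", paste0("g", 1:12))
  cols <- c("REG_p1", "REG_p2", "TF_p1", "g1_p1", "g1_weak",
            paste0("g", 2:7, "_p"))
  m <- matrix(0, nrow = length(genes), ncol = length(cols),
              dimnames = list(genes, cols))
  m["REG", c("REG_p1", "REG_p2")] <- c(-2, -1.8)
  m["TF", "TF_p1"] <- -2
  m[c("g1", "g2", "g3", "g4"), "TF_p1"] <- c(5, -5, 5, -5)     # regulon
  m[c("g1", "g2", "g3"), c("REG_p1", "REG_p2")] <- c(5, -5, 5)  # concordant
  m["g1", "g1_p1"] <- -2
  m["g1", "g1_weak"] <- -0.3
  for (g in paste0("g", 2:7)) m[g, paste0(g, "_p")] <- -2
  kd_panel(m, c("REG", "REG", "TF", "g1", "g1", paste0("g", 2:7)))
}

test_that("preprocess_panel validates, averages probes and re-z-scores", {
  raw <- hand_panel()
  panel <- preprocess_panel(raw, cfg)
  expect_true(panel$consolidated)
  expect_true("g1_weak" %in% attr(panel, "dropped"))     # z = -0.3 > -0.4
  expect_setequal(colnames(panel$values),
                  c("REG", "TF", paste0("g", 1:7)))
  # two valid REG probes averaged before the per-gene re-z-score
  cons_reg <- (raw$values[, "REG_p1"] + raw$values[, "REG_p2"]) / 2
  cons <- cbind(REG = cons_reg, TF = raw$values[, "TF_p1"],
                g1 = raw$values[, "g1_p1"],
                raw$values[, paste0("g", 2:7, "_p")])
  colnames(cons) <- c("REG", "TF", paste0("g", 1:7))
  z <- t(scale(t(cons)))
  live <- apply(cons, 1L, sd) > 0  # flat rows: package leaves them at 0
  expect_equal(unname(panel$values[live, colnames(cons)]),
               unname(z[live, ]), tolerance = 1e-12)
  expect_true(all(panel$values[!live, ] == 0))
})

test_that("define_targets applies the strict |z| threshold and drops the TF", {
  m <- matrix(0, 4, 3, dimnames = list(c("TF", "a", "b", "c"),
                                       c("TF", "x", "y")))
  m["TF", "TF"] <- -2
  panel <- structure(list(values = m, target = c("TF", "x", "y"),
                          consolidated = TRUE), class = "kd_panel")
  # column of all zeros: empty target set
  ts0 <- define_targets(panel, "TF", cfg)
  expect_equal(ts0$K, 0L)
  # boundary: z = 1.5 exactly is excluded (> 1.5 strict)
  m2 <- m
  m2["a", "TF"] <- 1.5
  m2["b", "TF"] <- 1.5000001
  panel2 <- structure(list(values = m2, target = c("TF", "x", "y"),
                           consolidated = TRUE), class = "kd_panel")
  ts <- define_targets(panel2, "TF", cfg)
  expect_setequal(names(ts$targets), "b")
  expect_error(define_targets(panel, "NOTF", cfg), "NOTF")
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  # spec worked example: N=10, K=5, n=4, k=4 -> P ~ 5/210
  p <- shapegenet:::hyper_upper_p(4, 10, 5, 4)
  expect_equal(p, oracle_hyper_enum(4, 10, 5, 4), tolerance = 1e-12)
  expect_equal(p, 5 / 210, tolerance = 1e-12)
  expect_lt(p, 0.05)
  # all N <= 12, a representative sweep of (K, n, k)
  for (N in 3:12) {
    for (K in c(1, N %/% 2, N - 1)) {
      for (n in c(1, N %/% 2)) {
        for (k in 0:min(K, n)) {
          expect_equal(shapegenet:::hyper_upper_p(k, N, K, n),
                       oracle_hyper_enum(k, N, K, n), tolerance = 1e-10)
        }
      }
    }
  }
  # saturated overlap is uninformative: k = K = n = N gives P = 1
  expect_equal(shapegenet:::hyper_upper_p(6, 6, 6, 6), 1)
})

test_that("classify_regulation implements the three scenarios", {
  raw <- hand_panel()
  panel <- preprocess_panel(raw, cfg)
  ts <- define_targets(panel, "TF", cfg)
  calls <- classify_regulation("REG", "TF", panel, ts, cfg)
  act <- calls[calls$mode == "activation_regulator", ]
  expect_equal(nrow(act), 1L)
  expect_equal(act$direction, "activator")
  expect_equal(act$concordance, 1)
  expect_true(act$p < cfg$hyper_alpha)
  # saturated example: no activation call when the overlap is uninformative
  expect_equal(nrow(calls[calls$mode == "expression_regulator", ]), 0L)

  d <- call_direction("REG", "TF", panel, ts, cfg)
  expect_equal(d$direction, "activator")
  expect_equal(d$concordance, 1)
})

test_that("sign flip swaps activator/inhibitor and keeps the p-value", {
  truth <- default_truth(cfg)
  kd <- simulate_knockdown_panel(cfg, truth, seed = 5)
  panel <- preprocess_panel(kd$panel, cfg)
  ts <- define_targets(panel, "RELA", cfg)
  base <- classify_regulation("SHP009", "RELA", panel, ts, cfg)
  flipped <- panel
  flipped$values[, "SHP009"] <- -panel$values[, "SHP009"]
  flip <- classify_regulation("SHP009", "RELA", flipped, ts, cfg)
  b <- base[base$mode == "activation_regulator", ]
  f <- flip[flip$mode == "activation_regulator", ]
  expect_equal(b$p, f$p)
  expect_setequal(c(b$direction, f$direction), c("activator", "inhibitor"))
})

test_that("raising target_z never enlarges target or changed sets", {
  truth <- default_truth(cfg)
  kd <- simulate_knockdown_panel(cfg, truth, seed = 5)
  panel <- preprocess_panel(kd$panel, cfg)
  for (tz in list(c(1.0, 1.5), c(1.5, 2.5))) {
    lo <- define_targets(panel, "SMAD3", pipeline_config(target_z = tz[1]))
    hi <- define_targets(panel, "SMAD3", pipeline_config(target_z = tz[2]))
    expect_true(all(names(hi$targets) %in% names(lo$targets)))
  }
})

test_that("edge directionality follows one-sided knockdown effects", {
  genes <- c("A", "B", "C", "D", "E", "F")
  m <- matrix(0, 6, 6, dimnames = list(genes, paste0(genes, "p")))
  diag(m) <- -2
  m["B", "Ap"] <- 4    # A-KD changes B; B-KD does not change A
  raw <- kd_panel(m, genes)
  panel <- preprocess_panel(raw, cfg)
  net <- edges_to_network(list(c("A", "B"), c("B", "C")),
                          c(A = "gene", B = "gene", C = "gene"))
  dirs <- infer_edge_directions(net, panel, cfg)
  ab <- dirs[dirs$node_a == "A" & dirs$node_b == "B" |
               dirs$node_a == "B" & dirs$node_b == "A", ]
  expect_true(xor(ab$a_to_b, ab$b_to_a))
  bc <- dirs[dirs$node_a %in% c("B", "C") & dirs$node_b %in% c("B", "C"), ]
  expect_false(bc$a_to_b || bc$b_to_a)  # neither direction: stays undirected
})

test_that("panel round-trips through the TSV readers", {
  truth <- default_truth(cfg)
  kd <- simulate_knockdown_panel(cfg, truth, n_measured = 110, seed = 9)
  vals_f <- withr::local_tempfile(fileext = ".tsv")
  map_f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(kd$panel$values),
                                kd$panel$values, check.names = FALSE),
                     vals_f, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(perturbation = colnames(kd$panel$values),
                                target = kd$panel$target),
                     map_f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_kd_panel(vals_f, map_f)
  expect_equal(back$target, kd$panel$target)
  expect_equal(back$values, kd$panel$values, tolerance = 1e-9)
})
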