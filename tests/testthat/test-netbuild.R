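write_edge_file <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("load_edges: dialect detection, threshold boundary, dedup", {
  f <- write_edge_file(data.frame(protein1 = c("A", "B", "C", "A"),
                                  protein2 = c("B", "A", "D", "A"),
                                  combined_score = c(400L, 700L, 390L, 999L)))
  e <- load_edges(f, 0.4)
  # (A,B)/(B,A) merged keeping max; 0.39 dropped; self-loop dropped;
  # integer dialect scaled to [0,1]
  expect_equal(nrow(e), 1L)
  expect_equal(e$combined_score, 0.7)

  f2 <- write_edge_file(data.frame(a = "A", b = "B", combined_score = 0.4))
  expect_equal(load_edges(f2, 0.4)$combined_score, 0.4)  # >= keeps boundary
  f3 <- write_edge_file(data.frame(a = "A", b = "B", combined_score = 5000))
  expect_error(load_edges(f3), "score scale")
})

test_that("build_network composes correlation and interaction edges", {
  cfg <- pipeline_config(tf_list = c("TF1", "TF2"))
  sig <- data.frame(gene = c("G1", "G1", "G2"),
                    statistic = c("cell_area_mean", "cell_area_sd", "cell_area_mean"),
                    rho = c(0.8, 0.75, -0.9))
  edges <- data.frame(node_a = c("G1", "G1"), node_b = c("G2", "ZZZ"),
                      combined_score = c(0.5, 0.9))
  net <- build_network(sig, edges, cfg)
  nn <- network_nodes(net)
  # nodes: G1, G2, TF1, TF2 (isolated TFs retained), two statistic nodes
  expect_setequal(nn$node, c("G1", "G2", "TF1", "TF2",
                             "cell_area_mean", "cell_area_sd"))
  # edges: 3 correlation + 1 interaction (G1-ZZZ dropped: ZZZ not retained);
  # mean and SD of the same feature are distinct nodes
  expect_equal(igraph::ecount(net$graph), 4L)
  et <- table(igraph::E(net$graph)$etype)
  expect_equal(unname(et["correlation"]), 3L)
  expect_equal(unname(et["interaction"]), 1L)
})

test_that("centralities: hand-enumerated path and star cases", {
  path3 <- edges_to_network(list(c("A", "B"), c("B", "C")),
                            c(A = "gene", B = "gene", C = "gene"))
  a <- analyze_network(path3)
  nn <- network_nodes(a)
  b <- nn[nn$node == "B", ]
  expect_equal(b$degree, 2)
  expect_equal(b$stress, 1)
  expect_equal(b$closeness, 1)
  expect_equal(b$betweenness, 1)
  # leaves carry zero stress and betweenness
  expect_true(all(nn$stress[nn$node != "B"] == 0))
  expect_true(all(nn$betweenness[nn$node != "B"] == 0))

  star <- edges_to_network(list(c("C", "L1"), c("C", "L2"), c("C", "L3"),
                                c("C", "L4")),
                           c(C = "gene", L1 = "gene", L2 = "gene",
                             L3 = "gene", L4 = "gene"))
  sn <- network_nodes(analyze_network(star))
  expect_equal(sn$stress[sn$node == "C"], 6)  # C(4,2) leaf pairs
})

test_that("all four centralities match the brute-force oracle on random graphs", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(5:12, 1)
    adj <- random_adj(n, p = 0.35)
    net <- analyze_network(adj_to_network(adj))
    nn <- network_nodes(net)
    o <- oracle_centralities(adj)
    expect_equal(nn$degree, unname(o$degree))
    expect_equal(nn$closeness, o$closeness, tolerance = 1e-12)
    expect_equal(nn$stress, o$stress)
    expect_equal(nn$betweenness, o$betweenness, tolerance = 1e-12)
  }
})

test_that("extract_paths honors slack, exclusions and disconnection", {
  cfg <- pipeline_config(tf_list = c("TF", "TF2"), path_slack = 1L)
  types <- c(F1 = "feature", G1 = "gene", G2 = "gene", G3 = "gene",
             TF = "tf", TF2 = "tf")
  net <- edges_to_network(list(c("F1", "G1"), c("G1", "TF"),
                               c("F1", "G2"), c("G2", "G3"), c("G3", "TF")),
                          types, tf_list = c("TF", "TF2"))
  ps <- extract_paths(net, "F1", "TF", cfg)
  expect_equal(ps$optimal, 2L)
  expect_equal(length(ps$paths), 2L)  # 2-hop and 3-hop with slack 1
  lens <- sort(vapply(ps$paths, length, 0L)) - 1L
  expect_equal(lens, c(2L, 3L))

  # target reachable only through another preselected TF: empty set
  net2 <- edges_to_network(list(c("F1", "G1"), c("G1", "TF2"), c("TF2", "TF")),
                           types, tf_list = c("TF", "TF2"))
  ps2 <- extract_paths(net2, "F1", "TF", cfg)
  expect_length(ps2$paths, 0L)
  expect_true(is.na(ps2$optimal))
  expect_error(extract_paths(net, "NOPE", "TF", cfg), "NOPE")
})

test_that("path enumeration equals the exhaustive DFS oracle", {
  set.seed(23)
  cfg <- pipeline_config(tf_list = "TF", path_slack = 1L)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    adj <- random_adj(n, 0.3)
    types <- rep("gene", n)
    types[1] <- "feature"
    types[n] <- "tf"
    net <- adj_to_network(adj, types)
    nm <- igraph::V(net$graph)$name
    igraph::V(net$graph)$type <- types
    net$tf_list <- nm[n]
    ps <- extract_paths(net, nm[1], nm[n], cfg)
    if (is.na(ps$optimal)) {
      expect_length(oracle_simple_paths(net$graph, nm[1], nm[n], n), 0L)
    } else {
      o <- oracle_simple_paths(net$graph, nm[1], nm[n], ps$optimal + 1L)
      key <- function(p) paste(p, collapse = ">")
      expect_setequal(vapply(ps$paths, key, ""), vapply(o, key, ""))
    }
  }
})

test_that("assemble_subnetwork keeps all parent edges among path nodes", {
  types <- c(F1 = "feature", A = "gene", B = "gene", C = "gene", D = "gene",
             TF = "tf")
  net <- edges_to_network(list(c("F1", "A"), c("A", "B"), c("B", "TF"),
                               c("F1", "C"), c("C", "TF"), c("A", "C")),
                          types, tf_list = "TF")
  cfg <- pipeline_config(tf_list = "TF", path_slack = 1L)
  ps <- extract_paths(net, "F1", "TF", cfg)
  sub <- assemble_subnetwork(list(ps), net)
  # chord A-C between two path interiors must be included
  expect_true(igraph::are_adjacent(sub$graph, "A", "C"))
  expect_false("D" %in% igraph::V(sub$graph)$name)

  # single path A-B-C contract
  net2 <- edges_to_network(list(c("F1", "A"), c("A", "TF")),
                           c(F1 = "feature", A = "gene", TF = "tf"),
                           tf_list = "TF")
  sub2 <- assemble_subnetwork(list(extract_paths(net2, "F1", "TF", cfg)), net2)
  expect_equal(igraph::vcount(sub2$graph), 3L)
  expect_equal(igraph::ecount(sub2$graph), 2L)
})

test_that("deleting a non-path node leaves the path set unchanged", {
  types <- c(F1 = "feature", A = "gene", X = "gene", TF = "tf")
  cfg <- pipeline_config(tf_list = "TF", path_slack = 1L)
  net_with <- edges_to_network(list(c("F1", "A"), c("A", "TF"), c("X", "A")),
                               types, tf_list = "TF")
  net_without <- edges_to_network(list(c("F1", "A"), c("A", "TF")),
                                  c(F1 = "feature", A = "gene", TF = "tf"),
                                  tf_list = "TF")
  p1 <- extract_paths(net_with, "F1", "TF", cfg)
  p2 <- extract_paths(net_without, "F1", "TF", cfg)
  expect_equal(p1$paths, p2$paths)
  expect_equal(p1$optimal, p2$optimal)
})
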