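#' Load a STRING-dialect interaction edge table
#'
#' Reads a TSV whose first two columns are node identifiers and which carries
#' a \code{combined_score} column (last column if not named). Scores may be on
#' the 0-1000 integer dialect or already 0-1; they are normalized to [0, 1].
#' Rows below \code{min_score} are dropped; self-loops are dropped; duplicate
#' undirected pairs are merged keeping the maximum score.
#'
#' @param path TSV path.
#' @param min_score combined-score floor on the 0-1 scale; kept with >=
#'   semantics, so a 0.4 edge survives a 0.4 floor.
#' @return data.frame with columns node_a, node_b, combined_score.
#' @export
load_edges <- function(path, min_score = 0.4) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("edge table needs two id columns plus a score")
  score_col <- if ("combined_score" %in% names(d)) "combined_score" else names(d)[ncol(d)]
  sc <- as.numeric(d[[score_col]])
  if (anyNA(sc)) stop("non-numeric combined scores in ", path)
  if (any(sc > 1000)) stop("unknown score scale: values exceed 1000")
  if (any(sc > 1)) sc <- sc / 1000  # STRING integer dialect
  edges <- data.frame(node_a = as.character(d[[1L]]),
                      node_b = as.character(d[[2L]]),
                      combined_score = sc, stringsAsFactors = FALSE)
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(edges$combined_score, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                      node_b = vapply(parts, `[`, "", 2L),
                      combined_score = as.numeric(agg), stringsAsFactors = FALSE)
  edges <- edges[edges$combined_score >= min_score, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Build the shape-gene interaction network
#'
#' Nodes are the shape-correlated genes, the preselected TFs (retained even if
#' isolated), and every feature statistic with at least one significant
#' correlation. Edges are (i) interaction edges among the retained genes/TFs
#' and (ii) one correlation edge per significant (gene, statistic) pair.
#' Feature statistics are distinct nodes (a gene correlated with both the
#' mean and the SD of a feature gets two correlation edges).
#'
#' @param sig_corr significant correlation records (gene, statistic, rho, ...).
#' @param edges interaction edge table from \code{\link{load_edges}}.
#' @param config a \code{pipeline_config}.
#' @return A \code{shape_gene_network}: list with an igraph \code{graph}
#'   (vertex attr \code{type} in gene/tf/feature; edge attr \code{etype} in
#'   interaction/correlation, \code{weight} = score or |rho|).
#' @export
build_network <- function(sig_corr, edges, config = pipeline_config()) {
  if (NROW(sig_corr) == 0L) stop("no significant correlations to build from")
  genes <- unique(sig_corr$gene)
  tfs <- config$tf_list
  feats <- unique(sig_corr$statistic)
  node_names <- unique(c(setdiff(genes, tfs), tfs, feats))
  keep <- union(genes, tfs)
  ie <- edges[edges$node_a %in% keep & edges$node_b %in% keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_names), name = node_names)
  type <- ifelse(node_names %in% tfs, "tf",
                 ifelse(node_names %in% feats, "feature", "gene"))
  igraph::V(g)$type <- type
  if (nrow(ie)) {
    g <- igraph::add_edges(g, rbind(ie$node_a, ie$node_b),
                           etype = "interaction", weight = ie$combined_score)
  }
  g <- igraph::add_edges(g, rbind(sig_corr$gene, sig_corr$statistic),
                         etype = "correlation", weight = abs(sig_corr$rho))
  net <- list(graph = g, tf_list = tfs)
  class(net) <- "shape_gene_network"
  net
}

# Single-source BFS returning distances and shortest-path counts; the basis
# for the stress/betweenness computations. adj is a list of integer neighbor
# vectors.
bfs_paths <- function(adj, s, n) {
  dist <- rep.int(NA_integer_, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  frontier <- s
  order_visited <- integer(0)
  preds <- vector("list", n)
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    order_visited <- c(order_visited, frontier)
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_visited)
}

#' Compute node centralities on a shape-gene network
#'
#' Annotates every node with degree, closeness, stress and betweenness, all on
#' the unweighted graph (interaction and correlation edges count alike):
#' \itemize{
#'   \item degree: number of incident edges;
#'   \item closeness: Wasserman-Faust component-restricted closeness,
#'     (r / (n - 1)) * (r / sum of distances to the r reachable nodes), which
#'     penalizes small components and equals classical closeness on a
#'     connected graph;
#'   \item stress: number of shortest paths between unordered node pairs
#'     passing through the node (each path counted once);
#'   \item betweenness: standard fractional shortest-path betweenness.
#' }
#'
#' @param net a \code{shape_gene_network}.
#' @return The network with vertex attributes degree, closeness, stress,
#'   betweenness set.
#' @export
analyze_network <- function(net) {
  stopifnot(inherits(net, "shape_gene_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  deg <- igraph::degree(g)
  stress <- numeric(n)
  btw <- numeric(n)
  closeness <- numeric(n)
  for (s in seq_len(n)) {
    bp <- bfs_paths(adj, s, n)
    reach <- which(!is.na(bp$dist) & seq_len(n) != s)
    r <- length(reach)
    closeness[s] <- if (r > 0) (r / (n - 1)) * (r / sum(bp$dist[reach])) else 0
    # Brandes accumulation for betweenness (divide by 2 at the end for the
    # undirected double count).
    delta <- numeric(n)
    for (w in rev(bp$order)) {
      for (v in bp$preds[[w]]) {
        delta[v] <- delta[v] + (bp$sigma[v] / bp$sigma[w]) * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
    # stress: shortest s-t paths through interior v number
    # sigma_s(v) * suffix(v), where suffix(v) counts shortest-path
    # continuations from v to every strictly-downstream t in the BFS DAG.
    suffix <- numeric(n)
    for (w in rev(bp$order)) {
      for (v in bp$preds[[w]]) {
        suffix[v] <- suffix[v] + (1 + suffix[w])
      }
    }
    for (v in seq_len(n)) {
      if (v != s && !is.na(bp$dist[v])) {
        # paths from s through v to some t beyond v: sigma_s(v) * (#paths v->t)
        stress[v] <- stress[v] + bp$sigma[v] * suffix[v]
      }
    }
  }
  igraph::V(g)$degree <- deg
  igraph::V(g)$closeness <- closeness
  igraph::V(g)$stress <- stress / 2  # each unordered pair seen from both ends
  igraph::V(g)$betweenness <- btw / 2
  net$graph <- g
  net
}

#' Extract optimal and suboptimal feature-to-TF paths
#'
#' Operates on the graph with all other feature nodes and all other
#' preselected TFs deleted (paths routed through another phenotypic feature or
#' another selected TF are excluded), then enumerates every simple path from
#' the feature statistic to the TF of length at most (shortest length +
#' \code{path_slack}).
#'
#' @param net an analyzed or raw \code{shape_gene_network}.
#' @param feature_stat source feature-statistic node name.
#' @param tf target TF node name.
#' @param config a \code{pipeline_config} (supplies \code{path_slack} and the
#'   preselected TF list).
#' @return A \code{path_set}: list(feature, tf, paths = list of node-name
#'   vectors, optimal = shortest hop count or NA, slack).
#' @export
extract_paths <- function(net, feature_stat, tf, config = pipeline_config()) {
  stopifnot(inherits(net, "shape_gene_network"))
  g <- net$graph
  vn <- igraph::V(g)$name
  if (!feature_stat %in% vn) stop("feature node '", feature_stat, "' not in network")
  if (!tf %in% vn) stop("TF node '", tf, "' not in network")
  types <- igraph::V(g)$type
  drop <- vn[(types == "feature" & vn != feature_stat) |
               (vn %in% config$tf_list & vn != tf)]
  h <- igraph::delete_vertices(g, drop)
  empty <- list(feature = feature_stat, tf = tf, paths = list(),
                optimal = NA_integer_, slack = config$path_slack)
  class(empty) <- "path_set"
  if (!feature_stat %in% igraph::V(h)$name || !tf %in% igraph::V(h)$name) {
    return(empty)
  }
  d <- igraph::distances(h, v = feature_stat, to = tf)[1, 1]
  if (!is.finite(d)) return(empty)
  bound <- as.integer(d) + config$path_slack
  sp <- igraph::all_simple_paths(h, from = feature_stat, to = tf, cutoff = bound)
  paths <- lapply(sp, function(p) igraph::V(h)$name[as.integer(p)])
  paths <- paths[vapply(paths, length, 0L) - 1L <= bound]
  out <- list(feature = feature_stat, tf = tf, paths = paths,
              optimal = as.integer(d), slack = config$path_slack)
  class(out) <- "path_set"
  out
}

#' Assemble a subnetwork from path sets
#'
#' The node set is the union of all nodes on the supplied paths; the edge set
#' is every parent-network edge among those nodes (induced subgraph), not just
#' the edges traversed by the paths.
#'
#' @param pathsets list of \code{path_set}s from the same parent network.
#' @param net the parent \code{shape_gene_network}.
#' @return A \code{shape_gene_network} restricted to the path nodes.
#' @export
assemble_subnetwork <- function(pathsets, net) {
  stopifnot(inherits(net, "shape_gene_network"))
  nodes <- unique(unlist(lapply(pathsets, function(ps) unlist(ps$paths))))
  if (is.null(nodes)) nodes <- character(0)
  sub <- igraph::induced_subgraph(net$graph, vids = nodes)
  out <- list(graph = sub, tf_list = net$tf_list)
  class(out) <- "shape_gene_network"
  out
}

#' Node attribute table of a shape-gene network
#' @param net an analyzed \code{shape_gene_network}.
#' @return data.frame: node, type, degree, closeness, stress, betweenness.
#' @export
network_nodes <- function(net) {
  g <- net$graph
  get <- function(a) {
    v <- igraph::vertex_attr(g, a)
    if (is.null(v)) rep(NA_real_, igraph::vcount(g)) else v
  }
  data.frame(node = igraph::V(g)$name, type = igraph::V(g)$type,
             degree = get("degree"), closeness = get("closeness"),
             stress = get("stress"), betweenness = get("betweenness"),
             stringsAsFactors = FALSE)
}

#' Export a network for Cytoscape
#'
#' Writes GraphML, a SIF edge list, and a node-attribute TSV (degree,
#' closeness, stress, betweenness).
#'
#' @param net a \code{shape_gene_network}.
#' @param prefix output path prefix; files \code{<prefix>.graphml},
#'   \code{<prefix>.sif}, \code{<prefix>_nodes.tsv} are written.
#' @return Invisibly, the vector of written paths.
#' @export
export_network <- function(net, prefix) {
  g <- net$graph
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  el <- igraph::as_edgelist(g)
  etype <- igraph::E(g)$etype
  sif <- paste0(prefix, ".sif")
  writeLines(paste(el[, 1], etype, el[, 2], sep = "\t"), sif)
  nodes_tsv <- paste0(prefix, "_nodes.tsv")
  utils::write.table(network_nodes(net), nodes_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(graphml, sif, nodes_tsv))
}

#' @export
print.shape_gene_network <- function(x, ...) {
  cat("shape_gene_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}
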