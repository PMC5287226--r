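#' Cluster cell lines on subnetwork-gene expression
#'
#' Gene profiles are collapsed over probes, z-scored across the cell lines,
#' and the lines are clustered by agglomerative hierarchical clustering with
#' Euclidean distance and complete linkage; the tree is cut at k = 2.
#'
#' @param expr an \code{expr_matrix} restricted (by \code{genes}) to the
#'   subnetwork genes.
#' @param genes character vector of genes to cluster on (default: all genes
#'   in \code{expr}).
#' @return A \code{cluster_assignment}: list(cluster = named integer vector
#'   (1/2) over cell lines, tree = the hclust object).
#' @export
cluster_lines <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  m <- collapse_probes(expr)
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(m))
    if (length(genes) < 2L) stop("need at least 2 subnetwork genes present")
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 4L) stop("need at least 4 cell lines")
  sds <- apply(m, 1L, stats::sd)
  if (all(sds == 0)) stop("degenerate expression: all gene profiles constant")
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  d <- stats::dist(t(z), method = "euclidean")
  tree <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(tree, k = 2)
  structure(list(cluster = cl, tree = tree, zmatrix = z),
            class = "cluster_assignment")
}

#' Derive the two cluster-specific (luminal/basal-like) networks
#'
#' Per cluster, each subnetwork gene gets its mean z-scored expression.
#' A gene is differential when the absolute difference of cluster means
#' exceeds \code{dz_cutoff}; non-differential genes are retained in a
#' cluster's network only if their within-cluster mean raw expression is at
#' least \code{expr_floor}. Edges are the subnetwork edges among each
#' cluster's retained nodes. The |mean-z difference| is exported as the node
#' sizing attribute.
#'
#' @param subnet a \code{shape_gene_network} (the feature-to-TF subnetwork).
#' @param expr an \code{expr_matrix} over the same cell lines.
#' @param clusters a \code{cluster_assignment} from \code{\link{cluster_lines}}.
#' @param config a \code{pipeline_config}.
#' @return A \code{differential_network}: list(nodes = data.frame(gene,
#'   mean_z_1, mean_z_2, mean_raw_1, mean_raw_2, dz, differential,
#'   retained_1, retained_2), graphs = list of the two igraph subgraphs).
#' @export
differential_networks <- function(subnet, expr, clusters,
                                  config = pipeline_config()) {
  stopifnot(inherits(subnet, "shape_gene_network"),
            inherits(clusters, "cluster_assignment"))
  m <- collapse_probes(expr)
  lines <- colnames(m)
  if (!all(names(clusters$cluster) %in% lines)) {
    stop("cluster lines not all present in the expression matrix")
  }
  m <- m[, names(clusters$cluster), drop = FALSE]
  sds <- apply(m, 1L, stats::sd)
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  nodes <- network_nodes(subnet)
  gg <- intersect(nodes$node[nodes$type %in% c("gene", "tf")], rownames(m))
  c1 <- names(clusters$cluster)[clusters$cluster == 1L]
  c2 <- names(clusters$cluster)[clusters$cluster == 2L]
  tab <- data.frame(gene = gg,
                    mean_z_1 = rowMeans(z[gg, c1, drop = FALSE]),
                    mean_z_2 = rowMeans(z[gg, c2, drop = FALSE]),
                    mean_raw_1 = rowMeans(m[gg, c1, drop = FALSE]),
                    mean_raw_2 = rowMeans(m[gg, c2, drop = FALSE]),
                    stringsAsFactors = FALSE)
  tab$dz <- abs(tab$mean_z_1 - tab$mean_z_2)
  tab$differential <- tab$dz > config$dz_cutoff
  # expr_floor applied per cluster: each network keeps its own expressed genes
  tab$retained_1 <- tab$differential | tab$mean_raw_1 >= config$expr_floor
  tab$retained_2 <- tab$differential | tab$mean_raw_2 >= config$expr_floor
  rownames(tab) <- NULL
  g1 <- igraph::induced_subgraph(subnet$graph, tab$gene[tab$retained_1])
  g2 <- igraph::induced_subgraph(subnet$graph, tab$gene[tab$retained_2])
  for (nm in c("g1", "g2")) {
    g <- get(nm)
    idx <- match(igraph::V(g)$name, tab$gene)
    igraph::V(g)$mean_z_1 <- tab$mean_z_1[idx]
    igraph::V(g)$mean_z_2 <- tab$mean_z_2[idx]
    igraph::V(g)$dz <- tab$dz[idx]
    igraph::V(g)$differential <- tab$differential[idx]
    assign(nm, g)
  }
  structure(list(nodes = tab, graphs = list(cluster1 = g1, cluster2 = g2)),
            class = "differential_network")
}

#' Export differential networks and the dendrogram
#'
#' Writes one GraphML per cluster network (node attributes: per-cluster mean
#' z, differential flag, |dz|) and the clustering dendrogram as a Newick
#' string.
#'
#' @param dn a \code{differential_network}.
#' @param clusters the \code{cluster_assignment} used.
#' @param prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
export_differential <- function(dn, clusters, prefix) {
  p1 <- paste0(prefix, "_cluster1.graphml")
  p2 <- paste0(prefix, "_cluster2.graphml")
  igraph::write_graph(dn$graphs$cluster1, p1, format = "graphml")
  igraph::write_graph(dn$graphs$cluster2, p2, format = "graphml")
  nwk <- paste0(prefix, "_dendrogram.nwk")
  ape::write.tree(ape::as.phylo(clusters$tree), file = nwk)
  invisible(c(p1, p2, nwk))
}
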