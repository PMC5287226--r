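# Independent brute-force oracles used to check the package's analytical
# routines. Deliberately naive implementations: enumeration and direct
# definitions only, sharing no code with R/.

# Spearman rho from the rank definition plus an exact permutation p by full
# enumeration (use only for n <= 7).
oracle_spearman_perm <- function(x, y) {
  rho_of <- function(a, b) stats::cor(rank(a), rank(b))
  obs <- rho_of(x, y)
  perms <- combinat_perms(length(y))
  rhos <- vapply(perms, function(p) rho_of(x, y[p]), numeric(1))
  p <- mean(abs(rhos) >= abs(obs) - 1e-12)
  list(rho = obs, p = p)
}

combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# All-pairs shortest-path oracle on an adjacency matrix: enumerates every
# simple path between every unordered pair by DFS, keeps the shortest ones,
# and derives degree/closeness/stress/betweenness from first definitions.
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    res <- list()
    dfs <- function(v, visited, path) {
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return()
      }
      for (w in which(adj[v, ] == 1)) {
        if (!w %in% visited) dfs(w, c(visited, w), c(path, w))
      }
    }
    dfs(s, s, s)
    res
  }
  deg <- rowSums(adj)
  stress <- numeric(n)
  btw <- numeric(n)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, 0L) - 1L
      shortest <- paths[lens == min(lens)]
      dist[s, t] <- dist[t, s] <- min(lens)
      sigma <- length(shortest)
      for (v in setdiff(seq_len(n), c(s, t))) {
        on_v <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        stress[v] <- stress[v] + on_v
        btw[v] <- btw[v] + on_v / sigma
      }
    }
  }
  closeness <- vapply(seq_len(n), function(v) {
    d <- dist[v, -v]
    r <- sum(is.finite(d))
    if (r == 0) 0 else (r / (n - 1)) * (r / sum(d[is.finite(d)]))
  }, numeric(1))
  list(degree = deg, closeness = closeness, stress = stress, betweenness = btw)
}

# Exhaustive simple-path enumeration between two named nodes with a length
# bound, on an igraph, by plain DFS over the adjacency matrix.
oracle_simple_paths <- function(graph, from, to, max_len) {
  adj <- as.matrix(igraph::as_adjacency_matrix(graph))
  nm <- igraph::V(graph)$name
  s <- match(from, nm); t <- match(to, nm)
  res <- list()
  dfs <- function(v, visited, path) {
    if (length(path) - 1L > max_len) return()
    if (v == t) {
      res[[length(res) + 1L]] <<- nm[path]
      return()
    }
    for (w in which(adj[v, ] > 0)) {
      if (!w %in% visited) dfs(w, c(visited, w), c(path, w))
    }
  }
  if (!is.na(s) && !is.na(t)) dfs(s, s, s)
  res
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) draws (N <= 12 only).
oracle_hyper_enum <- function(k, N, K, n) {
  draws <- utils::combn(N, n, simplify = FALSE)
  succ <- seq_len(K)
  mean(vapply(draws, function(d) sum(d %in% succ) >= k, logical(1)))
}

# One forward-selection step by brute force: refit an lm() for every
# remaining candidate and return the column minimizing the RSS.
oracle_forward_step <- function(y, X, selected) {
  pool <- setdiff(colnames(X), selected)
  rss <- vapply(pool, function(g) {
    d <- data.frame(y = y, X[, c(selected, g), drop = FALSE])
    sum(stats::residuals(stats::lm(y ~ ., data = d))^2)
  }, numeric(1))
  pool[which.min(rss)]
}

# Random connected-ish undirected graph as adjacency matrix.
random_adj <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  on <- upper[stats::runif(length(upper)) < p]
  adj[on] <- 1L
  adj + t(adj)
}

adj_to_network <- function(adj, types = NULL) {
  n <- nrow(adj)
  nm <- paste0("N", seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- nm
  igraph::V(g)$type <- if (is.null(types)) rep("gene", n) else types
  igraph::E(g)$etype <- "interaction"
  structure(list(graph = g, tf_list = character(0)),
            class = "shape_gene_network")
}

# Build a shape_gene_network from explicit edge pairs and node types.
edges_to_network <- function(edge_pairs, types, tf_list = character(0)) {
  nodes <- names(types)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  igraph::V(g)$type <- unname(types)
  if (length(edge_pairs)) {
    g <- igraph::add_edges(g, unlist(edge_pairs), etype = "interaction")
  }
  structure(list(graph = g, tf_list = tf_list), class = "shape_gene_network")
}
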