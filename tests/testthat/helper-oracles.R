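# Independent brute-force oracles. These deliberately avoid the package's
# (and igraph's) code paths for the quantities they check: plain adjacency
# lists, naive loops, explicit enumeration.

# undirected graph from a 2-column character matrix of edges (+ isolates)
g_from <- function(edges, isolates = character(0)) {
  nodes <- sort(unique(c(as.vector(edges), isolates)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges) > 0L) g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::simplify(g)
}

adj_list <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (length(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      if (a == b) next
      if (!(b %in% adj[[a]])) adj[[a]] <- c(adj[[a]], b)
      if (!(a %in% adj[[b]])) adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# core numbers by iterative minimum-degree peeling
oracle_coreness <- function(nodes, edges) {
  adj <- adj_list(nodes, edges)
  core <- stats::setNames(rep(0L, length(nodes)), nodes)
  remaining <- nodes
  k <- 0L
  while (length(remaining) > 0L) {
    deg <- vapply(remaining,
                  function(v) length(intersect(adj[[v]], remaining)),
                  integer(1L))
    if (min(deg) <= k) {
      v <- remaining[which(deg <= k)[1]]
      core[v] <- k
      remaining <- setdiff(remaining, v)
    } else {
      k <- k + 1L
    }
  }
  core
}

# single-source BFS hop distances
oracle_bfs <- function(adj, s) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# union of nodes lying on at least one shortest s-t path, found by explicit
# DFS enumeration of every shortest path
oracle_shortest_path_nodes <- function(adj, s, t) {
  ds <- oracle_bfs(adj, s)
  dt <- oracle_bfs(adj, t)
  if (is.infinite(ds[t])) return(character(0))
  nodes <- character(0)
  walk <- function(v, path) {
    if (v == t) {
      nodes <<- union(nodes, path)
      return(invisible())
    }
    for (u in adj[[v]]) {
      if (ds[u] == ds[v] + 1 && dt[u] == dt[v] - 1) walk(u, c(path, u))
    }
  }
  walk(s, s)
  nodes
}

# B(x) by full shortest-path enumeration over all known pairs
oracle_linkage_B <- function(nodes, edges, known, module) {
  adj <- adj_list(nodes, edges)
  B <- stats::setNames(rep(0L, length(module)), module)
  kn <- sort(known)
  for (i in seq_len(length(kn) - 1L)) {
    for (j in seq(i + 1L, length(kn))) {
      on_path <- oracle_shortest_path_nodes(adj, kn[i], kn[j])
      hits <- setdiff(intersect(module, on_path), c(kn[i], kn[j]))
      B[hits] <- B[hits] + 1L
    }
  }
  B
}

# naive SAM q-values over an explicit list of label splits
oracle_sam_q <- function(X, idx1, idx2, splits, s0_quantile = 0.05) {
  d_stat <- function(i1, i2, s0) {
    vapply(seq_len(nrow(X)), function(g) {
      x1 <- X[g, i1]; x2 <- X[g, i2]
      ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
      s <- sqrt((1 / length(i1) + 1 / length(i2)) *
                  ss / (length(i1) + length(i2) - 2))
      den <- s + s0
      if (den == 0) den <- .Machine$double.eps
      (mean(x2) - mean(x1)) / den
    }, numeric(1L))
  }
  s_only <- vapply(seq_len(nrow(X)), function(g) {
    x1 <- X[g, idx1]; x2 <- X[g, idx2]
    ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
    sqrt((1 / length(idx1) + 1 / length(idx2)) *
           ss / (length(idx1) + length(idx2) - 2))
  }, numeric(1L))
  s0 <- unname(quantile(s_only, s0_quantile))
  d_obs <- abs(d_stat(idx1, idx2, s0))
  perm <- lapply(splits, function(i1) {
    abs(d_stat(i1, setdiff(c(idx1, idx2), i1), s0))
  })
  q <- vapply(seq_along(d_obs), function(g) {
    fp <- mean(vapply(perm, function(p) sum(p >= d_obs[g]), numeric(1L)))
    min(1, fp / sum(d_obs >= d_obs[g]))
  }, numeric(1L))
  ord <- order(d_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])
  q
}

# Erdos-Renyi edge matrix on named nodes (uses the ambient RNG)
random_edges <- function(nodes, p) {
  out <- NULL
  n <- length(nodes)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (runif(1) < p) out <- rbind(out, c(nodes[i], nodes[j]))
    }
  }
  if (is.null(out)) matrix(character(0), 0, 2) else out
}

# small two-state expression set; f(state, gene) supplies the values
toy_ds <- function(values_by_state, gene_ids) {
  states <- rep(names(values_by_state),
                vapply(values_by_state, ncol, integer(1L)))
  m <- do.call(cbind, values_by_state)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  rownames(m) <- gene_ids
  expr_set(m, stats::setNames(states, colnames(m)))
}
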