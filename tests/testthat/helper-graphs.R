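# small graph builders --------------------------------------------------

triangle_graph <- function() {
  as_spread_graph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
}

star_graph <- function(leaves = 3L) {
  as_spread_graph(data.frame(
    from = rep("hub", leaves),
    to = paste0("leaf", seq_len(leaves))
  ))
}

path_graph <- function(n) {
  as_spread_graph(data.frame(
    from = as.character(seq_len(n - 1L)),
    to = as.character(seq_len(n - 1L) + 1L)
  ))
}

single_edge_graph <- function() {
  as_spread_graph(data.frame(from = "a", to = "b"))
}

clique_graph <- function(n) {
  as_spread_graph(igraph::make_full_graph(n))
}

random_er_graph <- function(n, p, seed) {
  g <- synthetic_graph("er", n = n, p = p, seed = seed)
  # keep at least one edge so every index is defined
  if (igraph::ecount(g) == 0L) {
    g <- igraph::add_edges(g, c(1L, 2L))
  }
  g
}

scores_named <- function(tbl) {
  col <- if ("score" %in% names(tbl)) "score" else names(tbl)[2L]
  stats::setNames(tbl[[col]], tbl$node)
}

# independent oracles ----------------------------------------------------

# hop counts by hand-rolled queue BFS (no igraph machinery)
bfs_oracle <- function(g, source) {
  nms <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  n <- length(nms)
  dist <- rep(NA_integer_, n)
  s <- match(source, nms)
  dist[s] <- 0L
  queue <- s
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  stats::setNames(dist, nms)
}

# H-index by sort-and-scan over neighbour degrees
h_index_oracle <- function(g) {
  nms <- igraph::V(g)$name
  k <- igraph::degree(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  vapply(seq_along(nms), function(i) {
    ds <- sort(k[as.integer(adj[[i]])], decreasing = TRUE)
    h <- 0L
    for (hh in seq_along(ds)) {
      if (sum(ds >= hh) >= hh) h <- hh
    }
    h
  }, 0L)
}

# Burt constraint from the raw z_ij adjacency-indicator definition
constraint_z_oracle <- function(g) {
  nms <- igraph::V(g)$name
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  p <- a / pmax(rowSums(a), 1)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) == 0L) return(1)
    sum(vapply(nb, function(j) {
      common <- which(a[i, ] == 1 & a[j, ] == 1)
      (p[i, j] + sum(p[i, common] * p[common, j]))^2
    }, 0))
  }, 0)
}

# untruncated all-pairs double-loop gravity oracle
gravity_oracle <- function(g, mass_i, mass_j = mass_i, coupling = NULL) {
  nms <- igraph::V(g)$name
  d <- igraph::distances(g, mode = "all")
  n <- length(nms)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) {
        cij <- if (is.null(coupling)) 1 else coupling[i, j]
        out[i] <- out[i] + cij * mass_i[i] * mass_j[j] / d[i, j]^2
      }
    }
  }
  stats::setNames(out, nms)
}

# pair-enumeration Kendall tau with tied pairs dropped from the numerator
tau_enumeration_oracle <- function(x, y) {
  n <- length(x)
  npos <- 0L
  nneg <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx > 0 && dy > 0 || dx < 0 && dy < 0) npos <- npos + 1L
      if (dx > 0 && dy < 0 || dx < 0 && dy > 0) nneg <- nneg + 1L
    }
  }
  2 * (npos - nneg) / (n * (n - 1))
}
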