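#' @keywords internal
#' @noRd
score_tibble <- function(g, values, method, params = list()) {
  out <- tibble::tibble(node = node_names(g), score = unname(values))
  attr(out, "method") <- method
  attr(out, "params") <- params
  out
}

adj_index_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

#' Degree centrality
#'
#' The number of first-order neighbours of each node, \eqn{DC(i) = k(i)}.
#'
#' @param graph An igraph object or edge-list data frame.
#' @return A tibble with columns `node` and `score`.
#' @family node indices
#' @export
centrality_degree <- function(graph) {
  g <- as_spread_graph(graph)
  score_tibble(g, as.numeric(igraph::degree(g)), "DC")
}

h_index_of <- function(nbr_degrees) {
  if (length(nbr_degrees) == 0L) return(0L)
  ds <- sort(nbr_degrees, decreasing = TRUE)
  sum(ds >= seq_along(ds))
}

#' H-index centrality
#'
#' The H-index of a node: the largest integer \eqn{h} such that at least
#' \eqn{h} of its neighbours have degree at least \eqn{h}. Isolated nodes
#' score 0.
#'
#' @inheritParams centrality_degree
#' @return A tibble with columns `node` and `score` (integer-valued).
#' @family node indices
#' @export
centrality_h_index <- function(graph) {
  g <- as_spread_graph(graph)
  k <- igraph::degree(g)
  adj <- adj_index_list(g)
  h <- vapply(adj, function(nb) h_index_of(k[nb]), 1L)
  score_tibble(g, as.numeric(h), "H")
}

#' HV index: H-index-filtered neighbour degree mass
#'
#' For each node \eqn{i}, the sum of the degrees of its first-order
#' neighbours whose degree is at least the H-index of \eqn{i}:
#' \deqn{HV(i) = \sum_{j \in \Lambda_i} [\, k(j) \mid k(j) \ge H(i) \,].}
#' This measures the aggregate influence of the node's strong neighbours and
#' serves as the mass term of [hvgc()].
#'
#' @inheritParams centrality_degree
#' @return A tibble with columns `node` and `score`.
#' @family node indices
#' @export
centrality_hv <- function(graph) {
  g <- as_spread_graph(graph)
  k <- igraph::degree(g)
  adj <- adj_index_list(g)
  h <- vapply(adj, function(nb) h_index_of(k[nb]), 1L)
  hv <- vapply(seq_along(adj), function(i) {
    kn <- k[adj[[i]]]
    sum(kn[kn >= h[i]])
  }, 0)
  score_tibble(g, as.numeric(hv), "HV")
}

#' K-shell decomposition with removal bookkeeping
#'
#' Iteratively peels the graph: within shell \eqn{k}, each pass removes all
#' nodes of residual degree at most \eqn{k} simultaneously, until every
#' remaining node has residual degree above \eqn{k}. Besides the classic
#' shell index \eqn{k_s(i)}, the function records the 1-based pass \eqn{p(i)}
#' at which each node was removed, the total number of passes \eqn{q(k)} of
#' its shell, and the refined index
#' \deqn{k_s^*(i) = k_s(i) + p(i) / (q(k) + 1) \in [k_s(i),\, k_s(i) + 1),}
#' which breaks ties between nodes of the same shell by how long they
#' survived the peeling. Isolated nodes fall in shell 0.
#'
#' @inheritParams centrality_degree
#' @return A tibble with columns `node`, `shell` (\eqn{k_s}), `pass`
#'   (\eqn{p(i)}), `shell_passes` (\eqn{q(k)}), and `shell_refined`
#'   (\eqn{k_s^*}).
#' @family node indices
#' @export
k_shell <- function(graph) {
  g <- as_spread_graph(graph)
  n <- igraph::vcount(g)
  adj <- adj_index_list(g)
  resid <- as.integer(igraph::degree(g))
  alive <- rep(TRUE, n)
  shell <- integer(n)
  pass <- integer(n)
  q_shell <- integer(n) # filled per node once its shell completes
  while (any(alive)) {
    cur_k <- min(resid[alive])
    members <- integer(0)
    p <- 0L
    repeat {
      victims <- which(alive & resid <= cur_k)
      if (length(victims) == 0L) break
      p <- p + 1L
      shell[victims] <- cur_k
      pass[victims] <- p
      alive[victims] <- FALSE
      members <- c(members, victims)
      nb <- unlist(adj[victims], use.names = FALSE)
      nb <- nb[alive[nb]]
      if (length(nb) > 0L) {
        loss <- tabulate(nb, nbins = n)
        resid <- resid - loss
      }
    }
    q_shell[members] <- p
  }
  out <- tibble::tibble(
    node = node_names(g),
    shell = shell,
    pass = pass,
    shell_passes = q_shell,
    shell_refined = shell + pass / (q_shell + 1)
  )
  attr(out, "method") <- "KS"
  out
}

#' Local clustering coefficient
#'
#' \eqn{C_i = 2 n_i / (k_i (k_i - 1))} where \eqn{n_i} is the number of
#' edges among the neighbours of \eqn{i}; nodes of degree at most 1 score 0
#' by convention.
#'
#' @inheritParams centrality_degree
#' @return A tibble with columns `node` and `score` in \eqn{[0, 1]}.
#' @family node indices
#' @export
local_clustering <- function(graph) {
  g <- as_spread_graph(graph)
  cc <- igraph::transitivity(g, type = "local")
  cc[!is.finite(cc)] <- 0
  score_tibble(g, cc, "C")
}

#' Burt's structural-hole constraint coefficient
#'
#' On an unweighted graph the proportional tie strength reduces to
#' \eqn{p_{ij} = 1 / k(i)}, and the constraint of node \eqn{i} is
#' \deqn{c(i) = \sum_{j \in \Gamma(i)} \Big( p_{ij} +
#'   \sum_{w \in \Gamma(i) \cap \Gamma(j)} p_{iw} p_{wj} \Big)^2.}
#' A low \eqn{c(i)} marks a node bridging otherwise-unconnected parts of the
#' network (a structural hole occupant); a degree-1 node has \eqn{c(i) = 1}.
#' Isolated nodes are assigned \eqn{c(i) = 1} as a documented convention
#' (their gravity score is zero regardless).
#'
#' @inheritParams centrality_degree
#' @return A tibble with columns `node` and `score` (> 0).
#' @family node indices
#' @export
burt_constraint <- function(graph) {
  g <- as_spread_graph(graph)
  k <- igraph::degree(g)
  adj <- adj_index_list(g)
  cvals <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) return(1)
    pi <- 1 / k[i]
    terms <- vapply(nb, function(j) {
      common <- intersect(nb, adj[[j]])
      pi + sum(pi / k[common])
    }, 0)
    sum(terms^2)
  }, 0)
  score_tibble(g, cvals, "constraint")
}

#' Eigenvector centrality by power iteration
#'
#' Iterates \eqn{x \leftarrow (A + I) x} with unit-sum renormalisation from a
#' uniform positive start vector until successive iterates differ by less
#' than `tol` in the max norm. The identity shift leaves the eigenvectors of
#' the adjacency operator unchanged while guaranteeing convergence on
#' bipartite graphs, where the unshifted iteration oscillates. On a
#' disconnected graph the mass concentrates on the component with the
#' largest leading eigenvalue.
#'
#' @inheritParams centrality_degree
#' @param tol Convergence tolerance in the max norm (default `1e-12`).
#' @param max_iter Maximum number of iterations before failing.
#' @return A tibble with columns `node` and `score`, scores summing to 1.
#' @family node indices
#' @export
centrality_eigenvector <- function(graph, tol = 1e-12, max_iter = 10000L) {
  g <- as_spread_graph(graph)
  n <- igraph::vcount(g)
  adj <- adj_index_list(g)
  x <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    ax <- x + vapply(adj, function(nb) sum(x[nb]), 0)
    ax <- ax / sum(ax)
    if (max(abs(ax - x)) < tol) {
      return(score_tibble(g, ax, "eigenvector",
        params = list(tol = tol, iterations = iter)
      ))
    }
    x <- ax
  }
  abort(sprintf(
    "Eigenvector centrality did not converge in %d iterations (graph with %d nodes).",
    max_iter, n
  ))
}

#' Spreading-entropy mass
#'
#' The entropy-weighted degree used as mass by the SEGM gravity model:
#' \deqn{SE(i) = e^{E(i)} k(i), \quad
#'   E(i) = -\sum_{j \in \Gamma(i)} I(j) \ln I(j), \quad
#'   I(j) = \frac{k(j)}{\sum_{w \in \Gamma(j)} k(w)}.}
#' The importance \eqn{I(j)} is evaluated globally at node \eqn{j} (its own
#' neighbourhood in the denominator), not renormalised within
#' \eqn{\Gamma(i)}. Isolated nodes score 0.
#'
#' @inheritParams centrality_degree
#' @return A tibble with columns `node` and `score`.
#' @family node indices
#' @export
spreading_entropy <- function(graph) {
  g <- as_spread_graph(graph)
  k <- igraph::degree(g)
  adj <- adj_index_list(g)
  imp <- vapply(seq_along(adj), function(i) {
    if (k[i] == 0) return(0)
    k[i] / sum(k[adj[[i]]])
  }, 0)
  plogp <- function(p) ifelse(p > 0, p * log(p), 0)
  ent <- vapply(adj, function(nb) -sum(plogp(imp[nb])), 0)
  score_tibble(g, exp(ent) * k, "SE")
}

#' Clustering-penalised degree mass
#'
#' The mass term of the generalised gravity centrality:
#' \eqn{S_p(i) = e^{-\alpha C_i} k(i)} with local clustering \eqn{C_i}.
#' Nodes embedded in dense neighbourhoods are down-weighted; \eqn{S_p = k}
#' exactly when \eqn{C_i = 0}.
#'
#' @inheritParams centrality_degree
#' @param alpha Clustering penalty exponent; default 2.
#' @return A tibble with columns `node` and `score`.
#' @family node indices
#' @export
gg_mass <- function(graph, alpha = 2) {
  g <- as_spread_graph(graph)
  k <- igraph::degree(g)
  cc <- local_clustering(g)$score
  score_tibble(g, exp(-alpha * cc) * k, "S_p", params = list(alpha = alpha))
}

#' Export a centrality table
#'
#' Writes a two-column TSV (`node`, `score`) with the method id and any
#' parameters recorded as `#` header comment lines; scores are printed with
#' 6 significant digits.
#'
#' @param scores A tibble as returned by the centrality functions.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_centrality <- function(scores, file) {
  method <- attr(scores, "method") %||% "centrality"
  params <- attr(scores, "params") %||% list()
  hdr <- sprintf("# method: %s", method)
  if (length(params) > 0L) {
    hdr <- c(hdr, sprintf(
      "# %s: %s", names(params),
      vapply(params, function(p) paste(format(p), collapse = ","), "")
    ))
  }
  score_col <- if ("score" %in% names(scores)) "score" else names(scores)[2L]
  body <- paste(scores$node, signif(scores[[score_col]], 6L), sep = "\t")
  writeLines(c(hdr, "node\tscore", body), file)
  invisible(file)
}
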