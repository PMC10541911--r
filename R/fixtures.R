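toy_edges_table <- function() {
  tibble::tibble(
    from = c("3", "3", "3", "3", "5", "5", "5", "6", "7", "7", "8", "9"),
    to = c("1", "2", "4", "5", "6", "7", "8", "7", "8", "9", "9", "10")
  )
}

toy_expected_table <- function() {
  tibble::tibble(
    node = c("5", "7", "8", "3", "9", "6", "1", "2", "4", "10"),
    sc = c(3.28, 3.10, 2.83, 2.80, 2.65, 2.34, 1.80, 1.78, 1.75, 1.73),
    dc = c(4, 4, 3, 4, 3, 2, 1, 1, 1, 1),
    ks = c(2, 2, 2, 1, 2, 2, 1, 1, 1, 1),
    h_index = c(3, 3, 3, 1, 2, 2, 1, 1, 1, 1),
    hv = c(11, 10, 11, 7, 7, 8, 4, 4, 4, 3),
    hvgc = c(
      248.02, 208.09, 164.73, 125.38, 103.72, 76.91, 10.30, 10.30,
      10.30, 7.72
    )
  )
}

#' The ten-node worked-example network
#'
#' A 10-node, 12-edge network in which a low-shell hub (node 3) bridges a
#' peripheral star onto the dense core around nodes 5, 7, and 8 — the
#' configuration that separates HVGC from purely degree- or shell-based
#' gravity centralities. The fixture carries a reference table of per-node
#' values (simulated spreading capacity `sc`, degree `dc`, k-shell `ks`,
#' H-index, HV index, and HVGC at truncation radius 1). On every call a
#' self-check recomputes the four integer indices from the packaged topology
#' and fails loudly if any cell disagrees, guarding against accidental
#' edits.
#'
#' @return A list of class `spread_fixture` with elements `name`, `graph`
#'   (igraph), `edges` (tibble), and `expected` (tibble, rows in descending
#'   HVGC order).
#' @examples
#' toy <- toy_network()
#' toy$expected
#' @export
toy_network <- function() {
  edges <- toy_edges_table()
  g <- as_spread_graph(edges)
  expected <- toy_expected_table()
  got <- dplyr::left_join(
    dplyr::left_join(
      dplyr::rename(centrality_degree(g), dc = "score"),
      dplyr::select(k_shell(g), "node", ks = "shell"),
      by = "node"
    ),
    dplyr::left_join(
      dplyr::rename(centrality_h_index(g), h_index = "score"),
      dplyr::rename(centrality_hv(g), hv = "score"),
      by = "node"
    ),
    by = "node"
  )
  chk <- dplyr::left_join(
    expected[, c("node", "dc", "ks", "h_index", "hv")],
    got,
    by = "node", suffix = c("_ref", "_got")
  )
  for (col in c("dc", "ks", "h_index", "hv")) {
    ok <- chk[[paste0(col, "_ref")]] == chk[[paste0(col, "_got")]]
    if (!all(ok)) {
      abort(sprintf(
        "Worked-example self-check failed: %s mismatch at node(s) %s.",
        col, paste(chk$node[!ok], collapse = ", ")
      ))
    }
  }
  structure(
    list(name = "toy", graph = g, edges = edges, expected = expected),
    class = "spread_fixture"
  )
}

#' @export
print.spread_fixture <- function(x, ...) {
  cat(sprintf(
    "Fixture '%s': %d nodes, %d edges, %d reference columns\n",
    x$name, igraph::vcount(x$graph), igraph::ecount(x$graph),
    ncol(x$expected) - 1L
  ))
  invisible(x)
}

#' Synthetic graph generators for property testing
#'
#' Reproducible generators spanning the network classes relevant to
#' spreading studies: Erdős–Rényi (`"er"`), Barabási–Albert preferential
#' attachment with its heavy-tailed degrees (`"ba"`), Watts–Strogatz
#' small-world (`"ws"`), and a planted two-block community graph
#' (`"two-block"`): two dense blocks joined only through dedicated bridge
#' nodes, each attached by a single edge to one node of either block — so a
#' bridge always lands in the lowest k-shell despite its brokerage position.
#'
#' @param kind One of `"er"`, `"ba"`, `"ws"`, `"two-block"`.
#' @param n Number of nodes (er/ba/ws).
#' @param p Edge probability for `"er"`, in \eqn{[0, 1]}.
#' @param m Edges attached per step for `"ba"`; must satisfy `m < n`.
#' @param nei Neighbourhood half-width of the `"ws"` ring lattice.
#' @param rewire Rewiring probability for `"ws"`, in \eqn{[0, 1]}.
#' @param block_sizes Two block sizes for `"two-block"`.
#' @param p_within Within-block edge probability for `"two-block"`.
#' @param n_bridge Number of bridge nodes for `"two-block"`.
#' @param seed Optional integer RNG seed.
#' @return An undirected simple igraph with character vertex names.
#' @examples
#' g <- synthetic_graph("er", n = 20, p = 0.2, seed = 1)
#' @export
synthetic_graph <- function(kind = c("er", "ba", "ws", "two-block"),
                            n = 20L, p = 0.2, m = 2L, nei = 2L,
                            rewire = 0.1, block_sizes = c(10L, 10L),
                            p_within = 0.8, n_bridge = 1L, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(kind,
    "er" = {
      if (p < 0 || p > 1) abort("`p` must be in [0, 1].")
      igraph::sample_gnp(n, p)
    },
    "ba" = {
      if (m >= n) abort("`m` must be smaller than `n`.")
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    "ws" = {
      if (rewire < 0 || rewire > 1) abort("`rewire` must be in [0, 1].")
      igraph::simplify(igraph::sample_smallworld(1L, n, nei, rewire))
    },
    "two-block" = {
      if (length(block_sizes) != 2L || any(block_sizes < 2L)) {
        abort("`block_sizes` must be two sizes >= 2.")
      }
      if (p_within < 0 || p_within > 1) abort("`p_within` must be in [0, 1].")
      n1 <- block_sizes[1L]
      n2 <- block_sizes[2L]
      b1 <- igraph::sample_gnp(n1, p_within)
      b2 <- igraph::sample_gnp(n2, p_within)
      g <- igraph::disjoint_union(b1, b2)
      for (b in seq_len(n_bridge)) {
        g <- igraph::add_vertices(g, 1L)
        v <- igraph::vcount(g)
        # one single edge into each block: residual degree 2, shell 1
        a1 <- 1L + (b - 1L) %% n1
        a2 <- n1 + 1L + (b - 1L) %% n2
        g <- igraph::add_edges(g, c(v, a1, v, a2))
      }
      g
    }
  )
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  as_spread_graph(g)
}

method_scores <- function(g, method, radius, alpha = 2) {
  method <- toupper(method)
  if (method %in% gravity_methods()) {
    return(gravity_centrality(g, method, radius = radius, alpha = alpha))
  }
  switch(method,
    "DC" = centrality_degree(g),
    "KS" = {
      ks <- k_shell(g)
      out <- score_tibble(g, as.numeric(ks$shell), "KS")
      out
    },
    "H" = centrality_h_index(g),
    "HV" = centrality_hv(g),
    abort(sprintf("Unknown method '%s'.", method))
  )
}

#' Run a full ranking-evaluation experiment on one network
#'
#' For each infection probability in `beta`, simulates the spreading
#' capacity of every node once ([spreading_capacity()]), computes every
#' requested centrality once, and scores each method against the simulated
#' ranking with [compare_rankings()]. Deterministic for a fixed `seed`.
#'
#' @inheritParams centrality_degree
#' @param methods Character vector of method ids: any of
#'   [gravity_methods()] plus the classical baselines `"DC"`, `"KS"`,
#'   `"H"`, `"HV"`.
#' @param beta Numeric vector of infection probabilities, or `"auto"` for
#'   the epidemic threshold; values may also be given as multiples of the
#'   threshold via `beta_factor`.
#' @param beta_factor Optional numeric vector of multiples of the epidemic
#'   threshold (e.g. `seq(0.5, 1.5, 0.25)`); overrides `beta`.
#' @param runs SIR replicates per seed node.
#' @param seed Integer base RNG seed.
#' @param radius Truncation radius passed to the gravity models.
#' @param k_grid Top-k grid for the Jaccard curve.
#' @param network Label recorded in the output.
#' @return A tibble of class `spread_experiment` with one row per
#'   (method, beta): columns `network`, `method`, `beta`, `tau`, `tau_b`,
#'   `monotonicity`, and a list-column `jaccard` of `k`/`jaccard` tibbles.
#' @examples
#' toy <- toy_network()
#' experiment_harness(toy$graph,
#'   methods = c("HVGC", "DC"), runs = 20,
#'   seed = 7, radius = 1, network = "toy"
#' )
#' @export
experiment_harness <- function(graph, methods = gravity_methods(),
                               beta = "auto", beta_factor = NULL,
                               runs = 1000L, seed = 1L, radius = "auto",
                               k_grid = seq(5L, 100L, 5L),
                               network = "network") {
  g <- as_spread_graph(graph)
  if (!is.null(beta_factor)) {
    beta <- beta_factor * epidemic_threshold(g)
  } else if (identical(beta, "auto")) {
    beta <- epidemic_threshold(g)
  }
  scores <- purrr::map(
    setNames(methods, methods),
    function(m) method_scores(g, m, radius = radius)
  )
  rows <- purrr::map(seq_along(beta), function(bi) {
    sc <- spreading_capacity(g,
      beta = beta[bi], runs = runs,
      seed = derive_seed(seed, 0L, bi)
    )
    purrr::map(methods, function(m) {
      cmp <- compare_rankings(scores[[m]], sc, k_grid = k_grid)
      tibble::tibble(
        network = network, method = m, beta = beta[bi],
        tau = cmp$tau, tau_b = cmp$tau_b,
        monotonicity = cmp$monotonicity,
        jaccard = list(cmp$jaccard)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("spread_experiment", class(out))
  attr(out, "runs") <- runs
  attr(out, "seed") <- seed
  out
}

#' @rdname experiment_harness
#' @param x A `spread_experiment` tibble.
#' @param ... Unused.
#' @export
tidy.spread_experiment <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(
      tibble::as_tibble(x), "network", "method", "beta", "jaccard"
    ),
    "jaccard"
  )
}

#' @rdname experiment_harness
#' @export
glance.spread_experiment <- function(x, ...) {
  dplyr::select(
    tibble::as_tibble(x),
    "network", "method", "beta", "tau", "tau_b", "monotonicity"
  )
}

#' Export an experiment table as tidy TSV
#'
#' One row per (network, method, beta) with the Jaccard curve spread into
#' `jaccard_k<k>` columns.
#'
#' @param x A `spread_experiment` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_experiment <- function(x, file) {
  wide <- tidyr::pivot_wider(
    tidy.spread_experiment(x),
    names_from = "k", values_from = "jaccard", names_prefix = "jaccard_k"
  )
  out <- dplyr::left_join(
    glance.spread_experiment(x), wide,
    by = c("network", "method", "beta")
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
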