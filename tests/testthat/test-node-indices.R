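toy <- toy_network()
toy_scores <- function(fn, ...) scores_named(fn(toy$graph, ...))

test_that("degree centrality reproduces the worked-example values", {
  dc <- toy_scores(centrality_degree)
  expect_equal(dc[["5"]], 4)
  expect_equal(dc[["10"]], 1)
  expect_equal(unname(dc[toy$expected$node]), toy$expected$dc)
  iso <- as_spread_graph(igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b"),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "z"))
  ))
  expect_equal(scores_named(centrality_degree(iso))[["z"]], 0)
})

test_that("H-index matches worked example, closed forms and sort-scan oracle", {
  h <- toy_scores(centrality_h_index)
  expect_equal(unname(h[c("5", "7", "8")]), c(3, 3, 3))
  expect_equal(unname(h[c("6", "9")]), c(2, 2))
  expect_equal(unname(h[toy$expected$node]), toy$expected$h_index)

  expect_equal(scores_named(centrality_h_index(star_graph(5)))[["hub"]], 1)
  expect_equal(scores_named(centrality_h_index(triangle_graph()))[["a"]], 2)

  for (s in 1:20) {
    g <- random_er_graph(25L, 0.15, seed = s)
    h <- scores_named(centrality_h_index(g))
    k <- igraph::degree(g)
    expect_equal(unname(h), as.numeric(h_index_oracle(g)))
    expect_true(all(h <= k))
    expect_true(all((h == 0) == (k == 0)))
  }
})

test_that("HV index sums degrees of strong neighbours", {
  hv <- toy_scores(centrality_hv)
  expect_equal(hv[["6"]], 8)
  expect_equal(hv[["5"]], 11)
  expect_equal(hv[["9"]], 7)
  expect_equal(unname(hv[toy$expected$node]), toy$expected$hv)
  expect_equal(scores_named(centrality_hv(triangle_graph()))[["a"]], 4)
  # HV(i) >= H(i)^2 whenever the node has neighbours
  for (s in 1:10) {
    g <- random_er_graph(20L, 0.2, seed = s)
    hv <- scores_named(centrality_hv(g))
    h <- scores_named(centrality_h_index(g))
    k <- igraph::degree(g)
    expect_true(all(hv[k > 0] >= h[k > 0]^2))
  }
})

test_that("k-shell peeling matches coreness and records pass bookkeeping", {
  k4 <- k_shell(clique_graph(4))
  expect_equal(k4$shell, rep(3L, 4))
  expect_equal(k4$pass, rep(1L, 4))
  expect_equal(k4$shell_passes, rep(1L, 4))

  ks_toy <- k_shell(toy$graph)
  expect_equal(
    ks_toy$shell[match(toy$expected$node, ks_toy$node)],
    as.integer(toy$expected$ks)
  )

  p5 <- k_shell(path_graph(5))
  expect_equal(p5$shell, rep(1L, 5))
  # ends fall first, then the next pair, the centre last
  expect_equal(stats::setNames(p5$pass, p5$node),
    c("1" = 1L, "2" = 2L, "3" = 3L, "4" = 2L, "5" = 1L))
  expect_equal(p5$shell_passes, rep(3L, 5))

  for (s in 1:120) {
    g <- random_er_graph(18L, 0.08 + 0.02 * (s %% 14), seed = s)
    ks <- k_shell(g)
    expect_equal(ks$shell, unname(as.integer(igraph::coreness(g))))
    expect_true(max(ks$shell) <= max(igraph::degree(g)))
    expect_true(all(ks$shell_refined >= ks$shell))
    expect_true(all(ks$shell_refined < ks$shell + 1))
  }
})

test_that("local clustering handles degenerate degrees and the worked example", {
  expect_equal(scores_named(local_clustering(triangle_graph()))[["a"]], 1)
  expect_equal(scores_named(local_clustering(star_graph(4)))[["hub"]], 0)
  cc <- toy_scores(local_clustering)
  expect_equal(cc[["5"]], 1 / 3) # neighbours 3,6,7,8 share edges 6-7, 7-8
})

test_that("constraint matches hand evaluation, raw-z oracle and igraph", {
  cons <- toy_scores(burt_constraint)
  expect_equal(cons[["1"]], 1) # degree-1 node
  expect_equal(cons[["3"]], 0.25) # 4 neighbours, no common neighbours
  expect_equal(
    scores_named(burt_constraint(triangle_graph()))[["a"]], 1.125
  )
  for (s in 1:15) {
    g <- random_er_graph(20L, 0.2, seed = s)
    mine <- scores_named(burt_constraint(g))
    expect_equal(unname(mine), unname(constraint_z_oracle(g)))
    ig <- igraph::constraint(g)
    with_deg <- igraph::degree(g) > 0
    expect_equal(unname(mine[with_deg]), unname(ig[with_deg]),
      tolerance = 1e-10
    )
  }
})

test_that("constraint permutes with node labels", {
  g <- random_er_graph(15L, 0.25, seed = 8)
  nms <- igraph::V(g)$name
  set.seed(2)
  perm <- sample(nms)
  el <- edge_tibble(g)
  g2 <- as_spread_graph(data.frame(
    from = perm[match(el$from, nms)], to = perm[match(el$to, nms)]
  ))
  c1 <- scores_named(burt_constraint(g))
  c2 <- scores_named(burt_constraint(g2))
  expect_equal(unname(c2[perm]), unname(c1[nms]))
})

test_that("eigenvector centrality agrees with dense eigendecomposition", {
  ev_ring <- scores_named(centrality_eigenvector(
    as_spread_graph(igraph::make_ring(5))
  ))
  expect_equal(unname(ev_ring), rep(0.2, 5), tolerance = 1e-8)

  ev_star <- scores_named(centrality_eigenvector(star_graph(4)))
  expect_true(all(ev_star[["hub"]] > ev_star[paste0("leaf", 1:4)]))

  for (g in list(toy$graph, random_er_graph(15L, 0.3, seed = 4))) {
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    eig <- eigen(a, symmetric = TRUE)
    v <- abs(eig$vectors[, 1L])
    v <- v / sum(v)
    mine <- scores_named(centrality_eigenvector(g))
    expect_equal(unname(mine), v, tolerance = 1e-7)
  }
  expect_error(
    centrality_eigenvector(toy$graph, max_iter = 2L), "converge"
  )
})

test_that("spreading entropy follows the global-importance definition", {
  expect_equal(scores_named(spreading_entropy(triangle_graph()))[["a"]], 4)
  iso <- as_spread_graph(igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b"),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "z"))
  ))
  expect_equal(scores_named(spreading_entropy(iso))[["z"]], 0)
  # direct evaluation on a path end: I computed at each node globally
  g <- path_graph(3)
  k <- igraph::degree(g)
  imp <- c(
    "1" = 1 / 2, # k=1, neighbour degree 2
    "2" = 2 / 2, # k=2, neighbour degrees 1+1
    "3" = 1 / 2
  )
  e1 <- -(imp[["2"]] * log(imp[["2"]])) # single neighbour, I=1 -> E=0
  se <- scores_named(spreading_entropy(g))
  expect_equal(se[["1"]], exp(e1) * 1)
  e2 <- -2 * (imp[["1"]] * log(imp[["1"]]))
  expect_equal(se[["2"]], exp(e2) * 2)
})

test_that("clustering-penalised mass caps at the degree", {
  expect_equal(scores_named(gg_mass(star_graph(4)))[["hub"]], 4)
  expect_equal(
    scores_named(gg_mass(triangle_graph()))[["a"]], 2 * exp(-2)
  )
  expect_equal(toy_scores(gg_mass)[["5"]], 4 * exp(-2 / 3))
  g <- random_er_graph(20L, 0.3, seed = 11)
  sp <- scores_named(gg_mass(g))
  expect_true(all(sp <= igraph::degree(g) + 1e-12))
})

test_that("centrality export writes method metadata and 6 significant digits", {
  f <- withr::local_tempfile()
  write_centrality(hvgc(toy$graph, radius = 1), f)
  lines <- readLines(f)
  expect_match(lines[1L], "method: HVGC")
  expect_match(lines[2L], "radius: 1")
  body <- utils::read.delim(f, comment.char = "#")
  expect_equal(body$node[body$score == max(body$score)], 5L)
})
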