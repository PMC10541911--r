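test_that("edge-list parsing handles delimiters, comments, dedup, self-loops", {
  f <- withr::local_tempfile()
  writeLines(c("# header comment", "", "1 2", "2 3"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::V(g)$name, c("1", "2", "3"))

  writeLines(c("a b", "b a", "a a"), f)
  expect_message(g2 <- read_edge_list(f), "self-loop")
  expect_equal(igraph::vcount(g2), 2L)
  expect_equal(igraph::ecount(g2), 1L)

  writeLines(c("x,y", "y , z"), f)
  g3 <- read_edge_list(f)
  expect_equal(sort(igraph::V(g3)$name), c("x", "y", "z"))
  expect_equal(igraph::ecount(g3), 2L)
})

test_that("malformed or empty edge lists raise informative errors", {
  f <- withr::local_tempfile()
  writeLines(c("1 2", "solo"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines(c("# only a comment", ""), f)
  expect_error(read_edge_list(f), "empty")
})

test_that("packaged worked-example edge-list file parses to 10 nodes, 12 edges", {
  f <- system.file("extdata", "toy_network.tsv", package = "gravispread")
  skip_if(f == "", "fixture file not installed")
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 10L)
  expect_equal(igraph::ecount(g), 12L)
})

test_that("write/read round trip preserves the graph", {
  f <- withr::local_tempfile()
  canon <- function(g) {
    el <- edge_tibble(g)
    pairs <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
    sort(pairs)
  }
  for (s in 1:5) {
    g <- random_er_graph(15L, 0.25, seed = s)
    write_edge_list(g, f)
    g2 <- read_edge_list(f)
    expect_equal(canon(g2), canon(g))
    expect_equal(sort(igraph::V(g2)$name), sort(igraph::V(g)$name))
  }
})

test_that("shortest_hops matches hand BFS and omits unreachable nodes", {
  toy <- toy_network()
  d <- shortest_hops(toy$graph, "10")
  dd <- stats::setNames(d$distance, d$node)
  expect_equal(dd[["9"]], 1L)
  expect_equal(dd[["7"]], 2L)
  expect_equal(dd[["5"]], 3L)
  expect_equal(dd[["1"]], 5L)

  oracle <- bfs_oracle(toy$graph, "10")
  expect_equal(dd, oracle[names(dd)])

  expect_equal(shortest_hops(single_edge_graph(), "a")$node, "b")

  two_comp <- as_spread_graph(data.frame(
    from = c("a", "c"), to = c("b", "d")
  ))
  expect_equal(shortest_hops(two_comp, "a")$node, "b")
  expect_error(shortest_hops(two_comp, "zz"), "not in the graph")
})

test_that("radius-truncated hops equal the unlimited map filtered", {
  for (s in 1:10) {
    g <- random_er_graph(20L, 0.15, seed = s)
    src <- igraph::V(g)$name[1L]
    full <- shortest_hops(g, src)
    for (r in 1:4) {
      expect_equal(
        shortest_hops(g, src, radius = r),
        dplyr::filter(full, distance <= r)
      )
    }
  }
})

test_that("network descriptors match closed forms on regular and star graphs", {
  tri <- suppressMessages(network_stats(triangle_graph()))
  expect_equal(tri$k_mean, 2)
  expect_equal(tri$d_mean, 1)
  expect_equal(tri$C, 1)
  expect_equal(tri$H, 1)
  expect_equal(tri$beta_c, 1)

  st <- suppressMessages(network_stats(star_graph(3L)))
  expect_equal(st$k_mean, 1.5)
  expect_equal(st$C, 0)

  # beta_c of a k-regular graph is 1/(k-1)
  ring6 <- as_spread_graph(igraph::make_ring(6)) # 2-regular
  expect_equal(suppressMessages(network_stats(ring6))$beta_c, 1)
  expect_equal(suppressMessages(network_stats(clique_graph(4)))$beta_c, 1 / 2)
  expect_equal(suppressMessages(network_stats(clique_graph(6)))$beta_c, 1 / 4)
})

test_that("descriptors on the worked example match direct formula evaluation", {
  toy <- toy_network()
  st <- suppressMessages(network_stats(toy$graph))
  k <- igraph::degree(toy$graph)
  expect_equal(st$k_mean, 2.4)
  expect_equal(st$k_mean, 2 * st$M / st$N)
  expect_equal(st$H, mean(k^2) / mean(k)^2)
  # mean distance from the hand BFS oracle over all ordered pairs
  nms <- igraph::V(toy$graph)$name
  dsum <- 0
  for (v in nms) {
    dv <- bfs_oracle(toy$graph, v)
    dsum <- dsum + sum(dv[names(dv) != v])
  }
  expect_equal(st$d_mean, dsum / (10 * 9))
  # assortativity as the degree-degree Pearson correlation over edge ends
  el <- igraph::as_edgelist(toy$graph, names = TRUE)
  kx <- c(k[el[, 1]], k[el[, 2]])
  ky <- c(k[el[, 2]], k[el[, 1]])
  expect_equal(st$r, stats::cor(kx, ky))
})

test_that("descriptors are invariant under node relabeling", {
  g <- random_er_graph(18L, 0.2, seed = 3)
  nms <- igraph::V(g)$name
  set.seed(9)
  perm <- sample(nms)
  el <- edge_tibble(g)
  relabelled <- as_spread_graph(data.frame(
    from = perm[match(el$from, nms)],
    to = perm[match(el$to, nms)]
  ))
  s1 <- suppressMessages(network_stats(g))
  s2 <- suppressMessages(network_stats(relabelled))
  expect_equal(s1, s2)
})

test_that("disconnected graphs report excluded pairs and stats export works", {
  two_comp <- as_spread_graph(data.frame(
    from = c("a", "c"), to = c("b", "d")
  ))
  expect_message(st <- network_stats(two_comp), "unreachable")
  expect_equal(st$d_mean, 1)

  f <- withr::local_tempfile()
  write_network_stats(st, f, format = "tsv")
  re <- utils::read.delim(f)
  expect_equal(names(re), c("N", "M", "k_mean", "d_mean", "C", "r", "H", "beta_c"))
  write_network_stats(st, f, format = "json")
  expect_equal(jsonlite::read_json(f)$N, 4L)

  expect_error(network_stats(data.frame(from = "a", to = "a")[0, ]))
})
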