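#' Coerce to an undirected simple graph
#'
#' All user-facing functions in gravispread accept either an igraph object or
#' an edge-list data frame (first two columns: endpoint labels) and coerce it
#' with `as_spread_graph()`. The result is an undirected simple igraph with
#' vertex names preserved verbatim as character labels, ordered by first
#' appearance in the input. Self-loops and parallel edges are dropped with a
#' message stating how many of each were removed.
#'
#' @param x An igraph object or a data frame whose first two columns are edge
#'   endpoints (character or integer labels; coerced to character).
#' @return An undirected simple igraph object with named vertices.
#' @examples
#' g <- as_spread_graph(data.frame(from = c(1, 2), to = c(2, 3)))
#' igraph::vcount(g)
#' @export
as_spread_graph <- function(x) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) {
      g <- igraph::as_undirected(g, mode = "collapse")
    }
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    } else {
      igraph::V(g)$name <- as.character(igraph::V(g)$name)
    }
    n_loops <- sum(igraph::which_loop(g))
    n_multi <- sum(igraph::which_multiple(g))
    if (n_loops > 0L) inform(sprintf("Dropped %d self-loop(s).", n_loops))
    if (n_multi > 0L) inform(sprintf("Dropped %d duplicate edge(s).", n_multi))
    return(igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE))
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) {
      abort("An edge-list data frame needs at least two columns.")
    }
    from <- as.character(x[[1L]])
    to <- as.character(x[[2L]])
    if (anyNA(from) || anyNA(to)) abort("Edge endpoints must not be NA.")
    # first-appearance vertex order, reading each row left to right
    verts <- unique(as.vector(rbind(from, to)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = verts, stringsAsFactors = FALSE)
    )
    return(as_spread_graph(g))
  }
  abort("`x` must be an igraph object or an edge-list data frame.")
}

node_names <- function(g) igraph::V(g)$name

#' Read a plain-text edge list
#'
#' Parses one edge per line: two (or more; extras are ignored) labels
#' separated by whitespace or commas. Blank lines and lines starting with
#' `#` are skipped. The delimiter is auto-detected from the first data line
#' unless given. Duplicate edges and self-loops are removed; the number of
#' dropped self-loops is reported via a message.
#'
#' @param file Path to the edge-list file (or a connection).
#' @param delimiter `"auto"` (default), or an explicit delimiter string such
#'   as `","` or `" "`; whitespace delimiters split on any run of
#'   whitespace.
#' @return An undirected simple igraph object; vertex order follows first
#'   appearance in the file.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "1 2", "2 3"), f)
#' g <- read_edge_list(f)
#' igraph::ecount(g)
#' @seealso [write_edge_list()], [as_spread_graph()]
#' @export
read_edge_list <- function(file, delimiter = "auto") {
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) abort("Edge list is empty: no data lines found.")
  if (identical(delimiter, "auto")) {
    delimiter <- if (grepl(",", lines[idx[1L]])) "," else "ws"
  } else if (grepl("^\\s*$", delimiter)) {
    delimiter <- "ws"
  }
  split_one <- function(line) {
    if (delimiter == "ws") {
      toks <- strsplit(trimws(line), "\\s+")[[1L]]
    } else {
      toks <- trimws(strsplit(line, delimiter, fixed = TRUE)[[1L]])
      toks <- toks[nzchar(toks)]
    }
    toks
  }
  toks <- lapply(lines[idx], split_one)
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed edge list: line %d has fewer than 2 tokens.", idx[bad[1L]]
    ))
  }
  edges <- tibble::tibble(
    from = vapply(toks, `[[`, "", 1L),
    to = vapply(toks, `[[`, "", 2L)
  )
  as_spread_graph(edges)
}

#' Write a graph as a plain-text edge list
#'
#' @param graph An igraph object or edge-list data frame.
#' @param file Output path.
#' @param delimiter Separator between the two labels; tab by default.
#' @return `file`, invisibly.
#' @export
write_edge_list <- function(graph, file, delimiter = "\t") {
  g <- as_spread_graph(graph)
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = delimiter), file)
  invisible(file)
}

#' Edge list of a graph as a tibble
#'
#' @param graph An igraph object or edge-list data frame.
#' @return A tibble with columns `from` and `to` (character labels).
#' @export
edge_tibble <- function(graph) {
  g <- as_spread_graph(graph)
  el <- igraph::as_edgelist(g, names = TRUE)
  tibble::tibble(from = as.character(el[, 1L]), to = as.character(el[, 2L]))
}

#' Breadth-first hop counts from one node
#'
#' Shortest-path distances (in hops) from `source` to every other node no
#' farther than `radius`. Unreachable nodes, nodes beyond the radius, and the
#' source itself are omitted.
#'
#' @param graph An igraph object or edge-list data frame.
#' @param source Label of the source node.
#' @param radius Positive integer truncation radius, or `Inf` for no
#'   truncation.
#' @return A tibble with columns `node` (character) and `distance` (integer),
#'   in vertex order.
#' @examples
#' g <- as_spread_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' shortest_hops(g, "a")
#' @export
shortest_hops <- function(graph, source, radius = Inf) {
  g <- as_spread_graph(graph)
  source <- as.character(source)
  if (!source %in% node_names(g)) {
    abort(sprintf("Source node '%s' is not in the graph.", source))
  }
  if (!is.infinite(radius) && (radius < 1 || radius != round(radius))) {
    abort("`radius` must be a positive integer or Inf.")
  }
  d <- igraph::distances(g, v = source, mode = "all")[1L, ]
  keep <- is.finite(d) & d > 0 & d <= radius
  tibble::tibble(
    node = node_names(g)[keep],
    distance = as.integer(d[keep])
  )
}

#' Whole-network topological descriptors
#'
#' Computes the standard descriptor bundle for an undirected simple network:
#' node and edge counts, mean degree \eqn{\langle k \rangle = 2M/N}, mean
#' shortest-path distance \eqn{\langle d \rangle} (averaged over reachable
#' pairs only; the number of excluded disconnected pairs is reported via a
#' message), mean local clustering coefficient \eqn{C} (nodes of degree < 2
#' contribute 0), degree assortativity \eqn{r} (Pearson correlation of
#' degrees over edges), degree heterogeneity
#' \eqn{H = \langle k^2 \rangle / \langle k \rangle^2}, and the SIR epidemic
#' threshold estimate
#' \eqn{\beta_c \approx \langle k \rangle / (\langle k^2 \rangle - \langle k \rangle)}.
#'
#' @param graph An igraph object or edge-list data frame with at least two
#'   nodes and one edge.
#' @return A one-row tibble with columns `N`, `M`, `k_mean`, `d_mean`, `C`,
#'   `r`, `H`, `beta_c`. `r` is `NA` on degree-regular graphs (zero degree
#'   variance).
#' @examples
#' tri <- as_spread_graph(data.frame(c(1, 2, 3), c(2, 3, 1)))
#' network_stats(tri)
#' @export
network_stats <- function(graph) {
  g <- as_spread_graph(graph)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 2L) abort("Need at least 2 nodes.")
  if (m < 1L) abort("Need at least 1 edge (beta_c undefined otherwise).")
  k <- igraph::degree(g)
  k_mean <- mean(k)
  k2_mean <- mean(k^2)
  comp <- igraph::components(g)
  reachable_pairs <- sum(comp$csize * (comp$csize - 1) / 2)
  excluded <- n * (n - 1) / 2 - reachable_pairs
  if (excluded > 0) {
    inform(sprintf(
      "Graph is disconnected: %d unreachable pair(s) excluded from d_mean.",
      excluded
    ))
  }
  d_mean <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  r <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (!is.finite(r)) r <- NA_real_
  beta_c <- if (k2_mean > k_mean) k_mean / (k2_mean - k_mean) else NA_real_
  tibble::tibble(
    N = n, M = m,
    k_mean = k_mean,
    d_mean = d_mean,
    C = cc,
    r = r,
    H = k2_mean / k_mean^2,
    beta_c = beta_c
  )
}

#' Export network descriptors
#'
#' Writes the [network_stats()] row as TSV or JSON with fixed column order.
#'
#' @param stats A one-row tibble from [network_stats()].
#' @param file Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_network_stats <- function(stats, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  cols <- c("N", "M", "k_mean", "d_mean", "C", "r", "H", "beta_c")
  stats <- stats[, cols]
  if (format == "tsv") {
    utils::write.table(stats, file,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  } else {
    jsonlite::write_json(as.list(stats), file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
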