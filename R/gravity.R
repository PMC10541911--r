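as_mass <- function(g, m, what = "mass") {
  nms <- node_names(g)
  if (is.data.frame(m)) {
    score_col <- if ("score" %in% names(m)) "score" else names(m)[2L]
    m <- setNames(m[[score_col]], m$node)
  }
  if (!is.numeric(m)) abort(sprintf("`%s` must be numeric.", what))
  if (is.null(names(m))) {
    if (length(m) != length(nms)) {
      abort(sprintf("Unnamed `%s` must have one value per node.", what))
    }
    names(m) <- nms
  }
  if (!all(nms %in% names(m))) {
    abort(sprintf("`%s` must cover every node of the graph.", what))
  }
  m[nms]
}

#' Heuristic optimal truncation radius
#'
#' The truncation radius of a gravity centrality is taken as half the mean
#' shortest-path distance, \eqn{R^* \approx \langle d \rangle / 2}, rounded
#' half-up and floored at 1.
#'
#' @inheritParams centrality_degree
#' @return A positive integer.
#' @examples
#' optimal_radius(toy_network()$graph)
#' @export
optimal_radius <- function(graph) {
  g <- as_spread_graph(graph)
  d_mean <- suppressMessages(network_stats(g)$d_mean)
  max(1L, as.integer(floor(d_mean / 2 + 0.5)))
}

resolve_radius <- function(g, radius) {
  if (identical(radius, "auto")) {
    return(optimal_radius(g))
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1) {
    abort("`radius` must be \"auto\" or a number >= 1.")
  }
  radius
}

#' Distance-truncated gravity sum
#'
#' The shared template of all gravity centralities: each node accumulates
#' pairwise attraction from every other node within `radius` hops,
#' \deqn{score(i) = \sum_{1 \le d(i,j) \le R} coupling(i,j)\,
#'   \frac{m_i(i)\, m_j(j)}{d(i,j)^2},}
#' where \eqn{m_i} is the focal-side mass and \eqn{m_j} the attractor-side
#' mass. Unreachable pairs contribute nothing.
#'
#' @inheritParams centrality_degree
#' @param mass_i,mass_j Focal-side and attractor-side node masses: a tibble
#'   with columns `node`/`score`, or a (named) numeric vector over all nodes.
#'   `mass_j` defaults to `mass_i`.
#' @param coupling `NULL` for unit coupling, a per-focal-node numeric vector
#'   (multiplies every term of node \eqn{i}'s sum), or an \eqn{N \times N}
#'   matrix of pairwise factors aligned to vertex order.
#' @param radius Truncation radius \eqn{R \ge 1}; `Inf` sums over all
#'   reachable pairs.
#' @return A tibble with columns `node` and `score`.
#' @examples
#' g <- as_spread_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' gravity_sum(g, centrality_degree(g), radius = 2)
#' @export
gravity_sum <- function(graph, mass_i, mass_j = mass_i, coupling = NULL,
                        radius = Inf) {
  g <- as_spread_graph(graph)
  if (is.numeric(radius) && radius < 1) abort("`radius` must be >= 1.")
  mi <- as_mass(g, mass_i, "mass_i")
  mj <- as_mass(g, mass_j, "mass_j")
  d <- igraph::distances(g, mode = "all")
  w <- matrix(0, nrow(d), ncol(d))
  within <- is.finite(d) & d >= 1 & d <= radius
  w[within] <- 1 / d[within]^2
  amp <- outer(unname(mi), unname(mj)) * w
  if (!is.null(coupling)) {
    if (is.matrix(coupling)) {
      amp <- amp * coupling
    } else {
      amp <- amp * as_mass(g, coupling, "coupling")
    }
  }
  score_tibble(g, rowSums(amp), "gravity_sum", params = list(radius = radius))
}

neighbour_sum <- function(g, score) {
  adj <- adj_index_list(g)
  vapply(adj, function(nb) sum(score[nb]), 0)
}

#' H-index-based gravity centrality (HVGC)
#'
#' Ranks nodes by a truncated gravity sum whose mass is the HV index
#' ([centrality_hv()]) and whose coupling discounts nodes with redundant
#' ties through Burt's constraint coefficient ([burt_constraint()]):
#' \deqn{HVGC(i) = \sum_{d(i,j) \le R,\, j \ne i} e^{-c(i)}
#'   \frac{HV(i)\, HV(j)}{d(i,j)^2}.}
#' Only the focal node's constraint enters, so the attraction between a pair
#' is asymmetric: a node occupying a structural hole (low \eqn{c(i)}) is
#' penalised less and rises in the ranking even when its shell index or
#' degree is modest — the behaviour that distinguishes bridge nodes between
#' communities from nodes buried inside one dense cluster.
#'
#' @inheritParams centrality_degree
#' @param radius Truncation radius: a number \eqn{\ge 1} or `"auto"`
#'   (half the mean distance, see [optimal_radius()]).
#' @return A tibble with columns `node` and `score`; attributes `method` and
#'   `params` (with the resolved radius).
#' @examples
#' hvgc(toy_network()$graph, radius = 1)
#' @export
hvgc <- function(graph, radius = "auto") {
  g <- as_spread_graph(graph)
  r <- resolve_radius(g, radius)
  hv <- centrality_hv(g)
  cc <- burt_constraint(g)
  out <- gravity_sum(g, hv, hv, coupling = exp(-cc$score), radius = r)
  attr(out, "method") <- "HVGC"
  attr(out, "params") <- list(radius = r)
  out
}

#' Available gravity-model method identifiers
#'
#' @return Character vector of the method ids accepted by
#'   [gravity_centrality()].
#' @export
gravity_methods <- function() {
  c(
    "HVGC", "G", "G+", "IGC", "IGC+", "LGM", "GGC", "KSGC", "DKGM",
    "MCGM", "SEGM"
  )
}

#' Gravity-model centralities
#'
#' Dispatches over the gravity-centrality family. All methods share the
#' truncated gravity template of [gravity_sum()] and differ in their node
#' mass and coupling:
#' \describe{
#'   \item{G}{k-shell mass on both sides, summed over nodes within distance
#'     3 regardless of `radius`.}
#'   \item{G+}{first-order neighbour sum of G.}
#'   \item{IGC}{focal mass \eqn{k_s(i)}, attractor mass \eqn{k(j)}.}
#'   \item{IGC+}{first-order neighbour sum of IGC.}
#'   \item{LGM}{degree mass on both sides.}
#'   \item{GGC}{clustering-penalised degree \eqn{S_p} ([gg_mass()]) on both
#'     sides.}
#'   \item{KSGC}{degree masses with shell-difference coupling
#'     \eqn{c_{ij} = e^{(k_s(i) - k_s(j)) / (k_{s,max} - k_{s,min})}}; when
#'     all shells are equal the coupling is 1.}
#'   \item{DKGM}{mass \eqn{k(i) + k_s^*(i)} with the refined shell index of
#'     [k_shell()].}
#'   \item{MCGM}{mass \eqn{k/k_{max} + \alpha\, k_s/k_{s,max} + x/x_{max}}
#'     mixing degree, shell, and eigenvector centrality \eqn{x}, with
#'     \eqn{\alpha = \max(k_{mid}/k_{max},\, x_{mid}/x_{max}) /
#'     (k_{s,mid}/k_{s,max})} from the medians.}
#'   \item{SEGM}{spreading-entropy mass ([spreading_entropy()]).}
#'   \item{HVGC}{see [hvgc()].}
#' }
#'
#' @inheritParams hvgc
#' @param method One of [gravity_methods()] (case-insensitive).
#' @param alpha Clustering penalty for GGC; default 2.
#' @return A tibble with columns `node` and `score`; attributes `method` and
#'   `params` record the resolved radius and any model parameters.
#' @examples
#' gravity_centrality(toy_network()$graph, "LGM", radius = 2)
#' @export
gravity_centrality <- function(graph, method, radius = "auto", alpha = 2) {
  g <- as_spread_graph(graph)
  method <- toupper(method)
  if (!method %in% gravity_methods()) {
    abort(sprintf(
      "Unknown gravity method '%s'. Available: %s.",
      method, paste(gravity_methods(), collapse = ", ")
    ))
  }
  r <- resolve_radius(g, radius)
  k <- centrality_degree(g)
  out <- switch(method,
    "G" = {
      ks <- k_shell(g)$shell
      # neighbourhood fixed at distance <= 3 by definition, whatever R is
      gravity_sum(g, ks, ks, radius = 3)
    },
    "G+" = {
      base <- gravity_centrality(g, "G", radius = r)
      score_tibble(g, neighbour_sum(g, base$score), "G+")
    },
    "IGC" = gravity_sum(g, k_shell(g)$shell, k, radius = r),
    "IGC+" = {
      base <- gravity_centrality(g, "IGC", radius = r)
      score_tibble(g, neighbour_sum(g, base$score), "IGC+")
    },
    "LGM" = gravity_sum(g, k, k, radius = r),
    "GGC" = {
      sp <- gg_mass(g, alpha = alpha)
      gravity_sum(g, sp, sp, radius = r)
    },
    "KSGC" = {
      ks <- k_shell(g)$shell
      rng <- max(ks) - min(ks)
      cij <- if (rng == 0) {
        inform("All k-shell values equal; KSGC coupling set to 1.")
        NULL
      } else {
        outer(exp(ks / rng), exp(-ks / rng))
      }
      gravity_sum(g, k, k, coupling = cij, radius = r)
    },
    "DKGM" = {
      dk <- k$score + k_shell(g)$shell_refined
      gravity_sum(g, dk, dk, radius = r)
    },
    "MCGM" = {
      ks <- k_shell(g)$shell
      x <- centrality_eigenvector(g)$score
      kk <- k$score
      a <- max(median(kk) / max(kk), median(x) / max(x)) /
        (median(ks) / max(ks))
      m <- kk / max(kk) + a * ks / max(ks) + x / max(x)
      out <- gravity_sum(g, m, m, radius = r)
      attr(out, "params") <- list(radius = r, alpha = a)
      out
    },
    "SEGM" = {
      se <- spreading_entropy(g)
      gravity_sum(g, se, se, radius = r)
    },
    "HVGC" = hvgc(g, radius = r)
  )
  attr(out, "method") <- method
  if (is.null(attr(out, "params")$radius)) {
    attr(out, "params") <- c(attr(out, "params"), list(radius = r))
  }
  if (method == "GGC") attr(out, "params")$alpha <- alpha
  out
}
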