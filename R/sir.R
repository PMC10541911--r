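#' SIR epidemic threshold from degree moments
#'
#' The mean-field estimate of the infection probability above which an SIR
#' outbreak becomes macroscopic on a network with degree heterogeneity:
#' \deqn{\beta_c \approx \frac{\langle k \rangle}
#'   {\langle k^2 \rangle - \langle k \rangle}.}
#'
#' @inheritParams centrality_degree
#' @return A positive real number.
#' @examples
#' epidemic_threshold(toy_network()$graph)
#' @export
epidemic_threshold <- function(graph) {
  g <- as_spread_graph(graph)
  k <- igraph::degree(g)
  denom <- mean(k^2) - mean(k)
  if (denom <= 0) {
    abort("Epidemic threshold undefined: <k^2> <= <k> on this graph.")
  }
  mean(k) / denom
}

# derive a 32-bit seed for (node, replicate) from the base seed, so each
# replicate stream is independent of iteration order
derive_seed <- function(base_seed, node_idx, replicate) {
  s <- (as.numeric(base_seed) * 2654435761 +
    as.numeric(node_idx) * 40503 + as.numeric(replicate) * 9973)
  as.integer(s %% 2147483647)
}

sir_step_cascade <- function(adj, n, seed_idx, beta, lambda) {
  # status: 0 susceptible, 1 infected, 2 recovered
  status <- integer(n)
  status[seed_idx] <- 1L
  steps <- 0L
  infected <- seed_idx
  while (length(infected) > 0L) {
    steps <- steps + 1L
    newly <- integer(0)
    if (beta > 0) {
      targets <- unlist(adj[infected], use.names = FALSE)
      targets <- targets[status[targets] == 0L]
      if (length(targets) > 0L) {
        # a node attacked by c infected neighbours escapes with (1-beta)^c
        cnt <- tabulate(targets, nbins = n)
        cand <- which(cnt > 0L)
        hit <- runif(length(cand)) < 1 - (1 - beta)^cnt[cand]
        newly <- cand[hit]
      }
    }
    recov <- if (lambda >= 1) {
      infected
    } else {
      infected[runif(length(infected)) < lambda]
    }
    status[recov] <- 2L
    status[newly] <- 1L
    infected <- c(setdiff(infected, recov), newly)
  }
  list(recovered = sum(status == 2L), steps = steps)
}

#' Run one SIR realisation from a single seed node
#'
#' Discrete-time synchronous SIR dynamics: at each step every infected node
#' independently attempts to infect each of its currently susceptible
#' neighbours with probability `beta`, then recovers with probability
#' `lambda` (with the default `lambda = 1` an infected node transmits for
#' exactly one step). Nodes infected at step \eqn{t} start transmitting at
#' step \eqn{t + 1}. The process stops when no infected nodes remain.
#'
#' @inheritParams centrality_degree
#' @param seed_node Label of the initially infected node.
#' @param beta Infection probability per infected-neighbour contact, in
#'   \eqn{[0, 1]}.
#' @param lambda Recovery probability per step, in \eqn{[0, 1]}; default 1.
#' @param seed Optional integer RNG seed for this single run.
#' @return A list with `recovered` (final count, the seed included) and
#'   `steps` (epidemic duration).
#' @export
sir_run <- function(graph, seed_node, beta, lambda = 1, seed = NULL) {
  g <- as_spread_graph(graph)
  seed_node <- as.character(seed_node)
  if (!seed_node %in% node_names(g)) {
    abort(sprintf("Seed node '%s' is not in the graph.", seed_node))
  }
  if (beta < 0 || beta > 1) abort("`beta` must be in [0, 1].")
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  adj <- adj_index_list(g)
  sir_step_cascade(
    adj, igraph::vcount(g),
    match(seed_node, node_names(g)), beta, lambda
  )
}

#' Monte-Carlo spreading capacity of every node
#'
#' Estimates each node's spreading capacity
#' \eqn{F(i) = \langle N_r \rangle / N} — the mean final fraction of
#' recovered nodes over `runs` independent SIR realisations seeded at node
#' \eqn{i}. Each (node, replicate) pair draws from its own deterministically
#' derived RNG substream, so results do not depend on iteration order.
#'
#' @inheritParams sir_run
#' @param beta Infection probability, or `"auto"` for the epidemic threshold
#'   estimate of [epidemic_threshold()].
#' @param runs Number of replicates per seed node; default 1000.
#' @param seed Integer base seed; default 1.
#' @return A `sir_result` object: a tibble with columns `node`, `capacity`
#'   (mean \eqn{F(i)}), `mean_recovered`, and `runs`, with attributes
#'   `beta`, `lambda`, `seed`, and `mean_steps`.
#' @examples
#' sc <- spreading_capacity(toy_network()$graph, beta = 0.3, runs = 50)
#' head(sc)
#' @export
spreading_capacity <- function(graph, beta = "auto", lambda = 1,
                               runs = 1000L, seed = 1L) {
  g <- as_spread_graph(graph)
  if (identical(beta, "auto")) beta <- epidemic_threshold(g)
  if (beta < 0 || beta > 1) abort("`beta` must be in [0, 1].")
  if (runs < 1L) abort("`runs` must be >= 1.")
  n <- igraph::vcount(g)
  adj <- adj_index_list(g)
  mean_rec <- numeric(n)
  total_steps <- 0
  for (i in seq_len(n)) {
    rec <- numeric(runs)
    for (r in seq_len(runs)) {
      set.seed(derive_seed(seed, i, r))
      res <- sir_step_cascade(adj, n, i, beta, lambda)
      rec[r] <- res$recovered
      total_steps <- total_steps + res$steps
    }
    mean_rec[i] <- mean(rec)
  }
  out <- tibble::tibble(
    node = node_names(g),
    capacity = mean_rec / n,
    mean_recovered = mean_rec,
    runs = as.integer(runs)
  )
  structure(out,
    class = c("sir_result", class(out)),
    beta = beta, lambda = lambda, seed = seed,
    mean_steps = total_steps / (n * runs)
  )
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf(
    "SIR spreading capacity (beta = %.4g, lambda = %g, %d runs/node)\n",
    attr(x, "beta"), attr(x, "lambda"), x$runs[1L]
  ))
  NextMethod()
}
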