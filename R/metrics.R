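as_scores <- function(x, what = "scores") {
  if (is.data.frame(x)) {
    score_col <- if ("score" %in% names(x)) {
      "score"
    } else if ("capacity" %in% names(x)) {
      "capacity"
    } else {
      names(x)[2L]
    }
    return(setNames(as.numeric(x[[score_col]]), as.character(x$node)))
  }
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", what))
  as.numeric(x) -> v
  names(v) <- names(x)
  v
}

#' Kendall rank correlation between two score lists
#'
#' The default variant evaluates the literal definition
#' \eqn{\tau = 2(n_+ - n_-) / (N(N-1))}: over all unordered pairs, \eqn{n_+}
#' counts pairs strictly concordant in both lists and \eqn{n_-} pairs
#' strictly discordant; any pair tied in either list contributes to neither,
#' while the denominator stays the total pair count. `variant = "b"` gives
#' the tie-adjusted tau-b of `stats::cor` for cross-tool comparison.
#'
#' @param x,y Paired numeric score vectors (or two-column `node`/`score`
#'   tibbles over the same node set, paired by node).
#' @param variant `"ties-dropped"` (the literal definition, default) or
#'   `"b"`.
#' @return A number in \eqn{[-1, 1]}.
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
kendall_tau <- function(x, y, variant = c("ties-dropped", "b")) {
  variant <- match.arg(variant)
  x <- as_scores(x, "x")
  y <- as_scores(y, "y")
  if (!is.null(names(x)) && !is.null(names(y)) &&
    length(names(x)) > 0 && length(names(y)) > 0 &&
    all(nzchar(names(x))) && all(nzchar(names(y)))) {
    if (!setequal(names(x), names(y))) {
      abort("`x` and `y` must cover the same node set.")
    }
    y <- y[names(x)]
  }
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 2L) abort("Need at least 2 paired observations.")
  if (variant == "b") {
    return(suppressWarnings(cor(x, y, method = "kendall")))
  }
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  sum(sx * sy) / (n * (n - 1))
}

top_k_nodes <- function(scores, k, ties = c("stable", "all")) {
  ties <- match.arg(ties)
  nms <- names(scores)
  if (is.null(nms)) nms <- as.character(seq_along(scores))
  ord <- order(-scores) # stable: input order breaks ties
  if (ties == "all" && k < length(scores)) {
    thr <- scores[ord[k]]
    k <- sum(scores >= thr)
  }
  nms[ord[seq_len(k)]]
}

#' Jaccard similarity of the two top-k node sets
#'
#' Extracts the `k` highest-scoring nodes from each list (ties at the k-th
#' rank broken deterministically by node input order, or all boundary ties
#' kept with `ties = "all"`) and returns
#' \eqn{|X \cap Y| / |X \cup Y|}.
#'
#' @inheritParams kendall_tau
#' @param k Top-list size, \eqn{1 \le k \le N}.
#' @param ties `"stable"` (default) or `"all"` (include every node tied with
#'   the k-th score, which may enlarge the sets).
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' jaccard_top_k(c(a = 3, b = 2, c = 1), c(a = 3, b = 1, c = 2), k = 1)
#' @export
jaccard_top_k <- function(x, y, k, ties = c("stable", "all")) {
  x <- as_scores(x, "x")
  y <- as_scores(y, "y")
  if (k < 1 || k > length(x)) abort("`k` must be between 1 and N.")
  if (!is.null(names(x)) && !is.null(names(y)) &&
    setequal(names(x), names(y))) {
    y <- y[names(x)]
  }
  tx <- top_k_nodes(x, k, ties)
  ty <- top_k_nodes(y, k, ties)
  length(intersect(tx, ty)) / length(union(tx, ty))
}

#' Monotonicity (resolution) of a ranking
#'
#' Quantifies how well an index discriminates nodes:
#' \deqn{M(X) = \Big[ 1 - \frac{\sum_c N_c (N_c - 1)}{N (N - 1)} \Big]^2,}
#' where \eqn{N_c} is the number of nodes sharing the same score value.
#' \eqn{M = 1} when all scores are distinct and \eqn{M = 0} when all are
#' identical.
#'
#' @inheritParams kendall_tau
#' @param x A numeric score vector or `node`/`score` tibble.
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' monotonicity(c(1, 1, 2, 3))
#' @export
monotonicity <- function(x) {
  x <- as_scores(x, "x")
  n <- length(x)
  if (n < 2L) abort("Need at least 2 scores.")
  nc <- table(x)
  (1 - sum(nc * (nc - 1)) / (n * (n - 1)))^2
}

#' Compare a centrality ranking against a reference ranking
#'
#' Bundles the three ranking-quality measures for one method against a
#' reference (typically simulated spreading capacity): Kendall's tau in both
#' variants, the monotonicity of the method's scores, and the Jaccard
#' similarity of the top-k sets over a grid of k.
#'
#' @param scores Method scores: a `node`/`score` tibble or named vector.
#' @param reference Reference scores over the same node set (e.g. a
#'   [spreading_capacity()] result).
#' @param k_grid Integer vector of top-list sizes; defaults to
#'   5, 10, ..., 100 clipped to the node count (always including N if the
#'   grid would otherwise be empty).
#' @param ties Top-k tie handling, see [jaccard_top_k()].
#' @return A `ranking_comparison` object (list with `method`, `tau`,
#'   `tau_b`, `monotonicity`, and a `jaccard` tibble of columns
#'   `k`/`jaccard`). Use [tidy()] for the curve, [glance()] for the one-row
#'   summary, [autoplot()] to plot.
#' @examples
#' toy <- toy_network()
#' sc <- spreading_capacity(toy$graph, beta = 0.3, runs = 50)
#' compare_rankings(hvgc(toy$graph, radius = 1), sc)
#' @export
compare_rankings <- function(scores, reference, k_grid = seq(5L, 100L, 5L),
                             ties = c("stable", "all")) {
  ties <- match.arg(ties)
  x <- as_scores(scores, "scores")
  y <- as_scores(reference, "reference")
  if (!setequal(names(x), names(y))) {
    abort("`scores` and `reference` must cover the same node set.")
  }
  y <- y[names(x)]
  n <- length(x)
  k_grid <- sort(unique(k_grid[k_grid >= 1 & k_grid <= n]))
  if (length(k_grid) == 0L) k_grid <- n
  jac <- tibble::tibble(
    k = as.integer(k_grid),
    jaccard = vapply(k_grid, function(k) jaccard_top_k(x, y, k, ties), 0)
  )
  structure(
    list(
      method = attr(scores, "method") %||% "scores",
      tau = kendall_tau(x, y),
      tau_b = kendall_tau(x, y, variant = "b"),
      monotonicity = monotonicity(x),
      jaccard = jac
    ),
    class = "ranking_comparison"
  )
}

#' @export
print.ranking_comparison <- function(x, ...) {
  cat(sprintf(
    "Ranking comparison [%s]: tau = %.4f, tau_b = %.4f, M = %.4f\n",
    x$method, x$tau, x$tau_b, x$monotonicity
  ))
  cat(sprintf(
    "Jaccard(top-k) over %d value(s) of k: mean %.4f\n",
    nrow(x$jaccard), mean(x$jaccard$jaccard)
  ))
  invisible(x)
}

#' @rdname compare_rankings
#' @param x A `ranking_comparison` object.
#' @param ... Unused.
#' @export
tidy.ranking_comparison <- function(x, ...) {
  dplyr::mutate(x$jaccard, method = x$method, .before = 1L)
}

#' @rdname compare_rankings
#' @export
glance.ranking_comparison <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    tau = x$tau,
    tau_b = x$tau_b,
    monotonicity = x$monotonicity,
    jaccard_mean = mean(x$jaccard$jaccard)
  )
}
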