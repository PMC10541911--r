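#' Tidy and summarise SIR results
#'
#' `tidy()` returns the per-node capacity table; `glance()` a one-row
#' summary of the simulation settings and outcome.
#'
#' @param x A `sir_result` from [spreading_capacity()].
#' @param ... Unused.
#' @export
tidy.sir_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.sir_result
#' @export
glance.sir_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x),
    beta = attr(x, "beta"),
    lambda = attr(x, "lambda"),
    runs = x$runs[1L],
    mean_capacity = mean(x$capacity),
    mean_steps = attr(x, "mean_steps")
  )
}

#' @rdname tidy.sir_result
#' @param object A `sir_result`.
#' @export
autoplot.sir_result <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), dplyr::desc(.data$capacity))
  df$node <- factor(df$node, levels = df$node)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$capacity)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "seed node", y = "spreading capacity F(i)",
      title = sprintf(
        "SIR spreading capacity (beta = %.3g, %d runs/node)",
        attr(object, "beta"), object$runs[1L]
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname compare_rankings
#' @param object A `ranking_comparison`.
#' @export
autoplot.ranking_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$jaccard,
    ggplot2::aes(x = .data$k, y = .data$jaccard)
  ) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "top-k", y = "Jaccard similarity",
      title = sprintf("Top-k agreement [%s]", object$method),
      subtitle = sprintf(
        "tau = %.3f, tau_b = %.3f, M = %.3f",
        object$tau, object$tau_b, object$monotonicity
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname experiment_harness
#' @param object A `spread_experiment`.
#' @export
autoplot.spread_experiment <- function(object, ...) {
  df <- tidy.spread_experiment(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$k, y = .data$jaccard,
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~beta, labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "top-k", y = "Jaccard similarity") +
    ggplot2::theme_minimal()
}

#' Plot the largest centrality scores
#'
#' Lollipop chart of the `top_n` highest-scoring nodes of a centrality
#' table.
#'
#' @param scores A `node`/`score` tibble from any centrality function.
#' @param top_n How many nodes to show.
#' @return A ggplot object.
#' @export
plot_centrality <- function(scores, top_n = 20L) {
  df <- dplyr::slice_max(tibble::as_tibble(scores), .data$score,
    n = top_n, with_ties = FALSE
  )
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$node)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = .data$score, yend = .data$node),
      colour = "grey60"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = attr(scores, "method") %||% "score", y = NULL
    ) +
    ggplot2::theme_minimal()
}
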