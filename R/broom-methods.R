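# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted mixture: one row per gene and cluster
#'
#' @param x A `zinbmix_fit`.
#' @param ... Unused.
#' @return A tibble with `gene`, `cluster`, `beta`, `beta_star`, `pi`, `phi`
#'   and a `selected` flag (log-mean off the global mean beyond the shrinkage
#'   tolerance).
#' @export
tidy.zinbmix_fit <- function(x, ...) {
  J <- x$J; K <- x$K
  tibble::tibble(
    gene = rep(x$gene_ids, K),
    cluster = rep(seq_len(K), each = J),
    beta = as.vector(x$params$beta),
    beta_star = rep(x$params$beta_star, K),
    pi = as.vector(x$params$pi),
    phi = rep(x$params$phi, K),
    selected = abs(as.vector(x$params$beta) - rep(x$params$beta_star, K)) > 1e-6
  )
}

#' One-row model summary
#'
#' @param x A `zinbmix_fit`.
#' @param ... Unused.
#' @return A tibble with fit-level quantities including the BIC.
#' @export
glance.zinbmix_fit <- function(x, ...) {
  b <- zinbmix_bic(x)
  tibble::tibble(K = x$K, lambda = x$lambda, loglik = x$loglik,
                 bic = b$bic, q = b$q, d = b$d,
                 n_selected = length(x$selected_genes),
                 n_iter = x$n_iter, converged = x$converged)
}

#' Objective trace of a fit
#'
#' Plots the penalized objective across EM iterations; a (near-)monotone
#' increase is the expected generalized-EM behaviour.
#'
#' @param object A `zinbmix_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zinbmix_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace),
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "Penalized objective",
                  title = sprintf("K = %d, lambda = %g", object$K, object$lambda)) +
    ggplot2::theme_minimal()
}

#' Plot a BIC path from penalty selection
#'
#' @param records Tibble of BIC records from [select_lambda()] or [select_K()].
#' @param by `"lambda"` or `"K"` for the x axis.
#' @return A ggplot object.
#' @export
plot_bic_path <- function(records, by = c("lambda", "K")) {
  by <- match.arg(by)
  ggplot2::ggplot(records, ggplot2::aes(x = .data[[by]], y = .data$bic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = by, y = "BIC") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
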