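# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a profile clustering chain
#'
#' One row per covariate: posterior summaries of the selection probability
#' and the posterior probability of the point mass at zero.
#'
#' @param x A [dp_cluster()] result.
#' @param ... Unused.
#' @return A tibble with columns `covariate`, `rho_median`, `rho_mean`,
#'   `rho_q25`, `rho_q75`, `p_zero`.
#' @export
tidy.dp_chain <- function(x, ...) {
  tibble::tibble(
    covariate = colnames(x$rho),
    rho_median = apply(x$rho, 2, median),
    rho_mean = colMeans(x$rho),
    rho_q25 = apply(x$rho, 2, quantile, 0.25, names = FALSE),
    rho_q75 = apply(x$rho, 2, quantile, 0.75, names = FALSE),
    p_zero = colMeans(x$rho == 0))
}

#' @rdname tidy.dp_chain
#' @export
glance.dp_chain <- function(x, ...) {
  occ <- vapply(x$snapshots, function(s) length(s$ids), 0L)
  tibble::tibble(iterations = nrow(x$z), burnin = x$burnin,
                 subjects = x$n, covariates = length(x$spec),
                 mean_occupied = mean(occ),
                 alpha_mean = mean(x$alpha))
}

#' @export
autoplot.dp_chain <- function(object, ...) {
  d <- tibble::as_tibble(object$rho)
  d$.iteration <- seq_len(nrow(d))
  d <- tidyr::pivot_longer(d, -".iteration", names_to = "covariate",
                           values_to = "rho")
  ggplot2::ggplot(d, ggplot2::aes(.data$.iteration, .data$rho)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(x = "kept iteration", y = "selection probability") +
    ggplot2::theme_minimal()
}

#' Tidy an edge-evidence matrix
#'
#' @param x A [build_tgamma()] matrix.
#' @param ... Unused.
#' @return Long tibble with columns `from`, `to`, `evidence` (upper
#'   triangle).
#' @export
tidy.tgamma_matrix <- function(x, ...) {
  m <- unclass(as.matrix(x))
  up <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(from = rownames(m)[up[, 1]], to = colnames(m)[up[, 2]],
                 evidence = m[up])
}

#' @export
autoplot.tgamma_matrix <- function(object, ...) {
  d <- tidy.tgamma_matrix(object)
  labs <- rownames(object)
  d$from <- factor(d$from, labs)
  d$to <- factor(d$to, rev(labs))
  ggplot2::ggplot(d, ggplot2::aes(.data$from, .data$to,
                                  fill = .data$evidence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "evidence") +
    ggplot2::theme_minimal()
}

#' Tidy a reversible-jump model search
#'
#' @param x An [rj_search()] result.
#' @param ... Unused.
#' @return Tibble of visited models with visit counts and posterior
#'   frequencies.
#' @export
tidy.rj_chain <- function(x, ...) {
  x$models
}

#' @rdname tidy.rj_chain
#' @export
glance.rj_chain <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, iterations = x$iters,
                 burnin = x$burnin,
                 best = x$best, first_hit = x$first_hit,
                 best_posterior = x$models$posterior[x$models$model == x$best],
                 accept_rate_model = x$accept_rate_model,
                 accept_rate_param = x$accept_rate_param,
                 models_visited = nrow(x$models))
}

#' @export
autoplot.rj_chain <- function(object, top = 10, ...) {
  d <- head(object$models, top)
  d$model <- factor(d$model, rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(.data$posterior, .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "posterior visit frequency", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a within-model parameter fit
#'
#' @param x A [fit_within_model()] result.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: posterior mean, sd,
#'   2.5%/97.5% quantiles and the mode.
#' @export
tidy.llm_fit <- function(x, ...) {
  tibble::tibble(term = colnames(x$draws),
                 estimate = colMeans(x$draws),
                 std.error = apply(x$draws, 2, stats::sd),
                 conf.low = apply(x$draws, 2, quantile, 0.025, names = FALSE),
                 conf.high = apply(x$draws, 2, quantile, 0.975, names = FALSE),
                 mode = x$mode)
}

#' @rdname tidy.llm_fit
#' @export
glance.llm_fit <- function(x, ...) {
  tibble::tibble(parameters = ncol(x$draws), draws = nrow(x$draws),
                 log_marginal = x$log_marginal,
                 accept_rate = x$accept_rate, converged = x$converged)
}
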