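# Posterior computations for a single graphical log-linear model:
# Newton mode search, Laplace evidence, random-walk Metropolis sampling.

# Newton-Raphson for the log posterior (concave: Poisson loglik + Gaussian
# prior). Returns mode, Cholesky of the negative Hessian, and diagnostics.
map_fit <- function(X, y, n, tol = 1e-10, max_iter = 100) {
  k <- ncol(X)
  G <- crossprod(X)
  R <- tryCatch(chol(G), error = function(e) {
    abort("design is rank deficient: model not identifiable")
  })
  logdet_G <- 2 * sum(log(diag(R)))
  prior_prec <- G / n
  beta <- numeric(k)
  beta[1] <- log(max(mean(y), 0.5))  # start near the intercept-only mode
  logpost <- function(b, eta) {
    sum(y * eta - exp(eta) - lgamma(y + 1)) - 0.5 * sum((R %*% b)^2) / n
  }
  eta <- drop(X %*% beta)
  f <- logpost(beta, eta)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    mu <- exp(eta)
    grad <- drop(crossprod(X, y - mu)) - drop(prior_prec %*% beta)
    H <- crossprod(X * mu, X) + prior_prec
    RH <- chol(H)
    step <- backsolve(RH, forwardsolve(t(RH), grad))
    # damped update: halve until the objective does not decrease
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      eta_new <- drop(X %*% beta_new)
      f_new <- logpost(beta_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    moved <- f_new - f
    beta <- beta_new; eta <- eta_new; f <- f_new
    if (abs(moved) < tol && sqrt(sum(grad^2)) < 1e-6 * (1 + abs(f))) {
      converged <- TRUE
      break
    }
  }
  mu <- exp(eta)
  H <- crossprod(X * mu, X) + prior_prec
  RH <- chol(H)
  const <- -k / 2 * log(2 * pi) - 0.5 * (k * log(n) - logdet_G)
  log_prior_mode <- const - 0.5 * sum((R %*% beta)^2) / n
  log_lik_mode <- sum(y * eta - exp(eta) - lgamma(y + 1))
  # Laplace approximation to the log marginal likelihood
  log_marginal <- log_lik_mode + log_prior_mode + k / 2 * log(2 * pi) -
    sum(log(diag(RH)))
  list(beta = beta, chol_hess = RH, log_lik = log_lik_mode,
       log_prior = log_prior_mode, log_marginal = log_marginal,
       converged = converged, G = G, chol_G = R, logdet_G = logdet_G, k = k)
}

#' Sample the parameters of one graphical log-linear model
#'
#' Random-walk Metropolis for the coefficients of a fixed graphical model
#' under the Poisson likelihood and unit-information prior. The posterior
#' mode is located by Newton iterations; the proposal covariance is the
#' inverse curvature at the mode scaled by `2.38^2/k`. Also returns the
#' Laplace approximation to the log marginal likelihood, used as the
#' small-space enumeration oracle.
#'
#' @param table A `contingency_tbl` (see [contingency_table()]).
#' @param g An [llgraph()]; its labels must match the table's factors.
#' @param iterations Number of Metropolis draws kept (no thinning).
#' @param burnin Draws discarded before recording.
#' @param seed Optional integer seed.
#' @param likelihood If `FALSE`, the likelihood is switched off and the
#'   sampler explores the prior (used to validate the sampler).
#' @return Object of class `llm_fit`: list with `draws` (iterations x k
#'   matrix), `mode`, `log_marginal`, `accept_rate`, `converged`, `design`.
#' @export
fit_within_model <- function(table, g, iterations = 2000, burnin = 500,
                             seed = NULL, likelihood = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  spec <- table_spec(table)
  design <- build_design(g, spec)
  X <- design$X
  y <- cell_counts(table)
  n <- max(sum(y), 1)
  if (likelihood) {
    fit <- map_fit(X, y, n)
  } else {
    fit <- map_fit(X, numeric(length(y)) , n)  # prior-ish curvature
    fit$beta <- numeric(ncol(X))
    fit$chol_hess <- fit$chol_G / sqrt(n)
  }
  if (!fit$converged && likelihood) {
    warn("mode search did not converge; results flagged")
  }
  k <- ncol(X)
  scale <- 2.38 / sqrt(k)
  beta <- fit$beta
  lp <- function(b) {
    pr <- -0.5 * sum((fit$chol_G %*% b)^2) / n
    if (!likelihood) return(pr)
    eta <- drop(X %*% b)
    sum(y * eta - exp(eta)) + pr
  }
  f <- lp(beta)
  draws <- matrix(NA_real_, iterations, k)
  acc <- 0L
  total <- iterations + burnin
  for (it in seq_len(total)) {
    prop <- beta + scale * backsolve(fit$chol_hess, rnorm(k))
    f_prop <- lp(prop)
    if (log(runif(1)) < f_prop - f) {
      beta <- prop; f <- f_prop; acc <- acc + 1L
    }
    if (it > burnin) draws[it - burnin, ] <- beta
  }
  colnames(draws) <- colnames(X)
  structure(list(draws = draws, mode = fit$beta,
                 log_marginal = fit$log_marginal,
                 accept_rate = acc / total, converged = fit$converged,
                 design = design),
            class = "llm_fit")
}

#' @export
print.llm_fit <- function(x, ...) {
  cat("<llm_fit> ", ncol(x$draws), " parameters, ", nrow(x$draws),
      " draws, log marginal (Laplace) = ", round(x$log_marginal, 2),
      if (!x$converged) " [mode search NOT converged]", "\n", sep = "")
  invisible(x)
}

#' Enumerate all graphical models on a small factor set
#'
#' Computes the Laplace-approximate log marginal likelihood of every graph
#' (all `2^(P(P-1)/2)` edge subsets) and the normalized posterior model
#' probabilities under a uniform prior on graphs. Feasible for `P <= 5`.
#'
#' @param table A `contingency_tbl`.
#' @param max_edges Safety cap on `P(P-1)/2` (default 10, i.e. `P = 5`).
#' @return Tibble with columns `model`, `edges`, `log_marginal`, `posterior`,
#'   sorted by posterior.
#' @export
enumerate_models <- function(table, max_edges = 10) {
  spec <- table_spec(table)
  P <- length(spec)
  H <- P * (P - 1) / 2
  if (H > max_edges) abort("model space too large to enumerate")
  y <- cell_counts(table)
  n <- max(sum(y), 1)
  ap <- all_pairs(P)
  subsets <- seq_len(2^H) - 1L
  lm_vals <- numeric(length(subsets))
  labs <- character(length(subsets))
  for (i in seq_along(subsets)) {
    sel <- as.logical(bitwAnd(subsets[i], 2^(seq_len(H) - 1L)) > 0)
    g <- llgraph(names(spec), ap[sel, , drop = FALSE])
    d <- build_design(g, spec)
    lm_vals[i] <- map_fit(d$X, y, n)$log_marginal
    labs[i] <- format_model(g)
  }
  w <- exp(lm_vals - max(lm_vals))
  tibble::tibble(model = labs, edges = vapply(subsets, function(s) sum(bitwAnd(s, 2^(seq_len(H) - 1L)) > 0), 0),
                 log_marginal = lm_vals, posterior = w / sum(w)) |>
    dplyr::arrange(dplyr::desc(.data$posterior))
}
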