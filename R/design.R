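#' Design matrix of a graphical log-linear model
#'
#' Builds the cell-by-parameter design matrix: an intercept column of ones
#' plus one column block per interaction term (complete subset of the graph),
#' using sum-to-zero contrasts for every factor so the unit-information prior
#' is exchangeable over level relabelling. Cells follow the canonical order of
#' [cell_grid()] (last factor fastest); term blocks are ordered by term size
#' then lexicographically.
#'
#' @param g An [llgraph()] (the graphical model).
#' @param spec A [factor_spec()] matching the graph's vertex labels.
#' @return An object of class `design_matrix`: list with elements `X` (the
#'   matrix), `terms` (named list of integer vectors), `term_cols` (named list
#'   mapping each term, and `"(Intercept)"`, to its column indices), and
#'   `spec`.
#' @examples
#' build_design(parse_model("AB", LETTERS[1:2]), factor_spec(LETTERS[1:2], 2))
#' @export
build_design <- function(g, spec) {
  stopifnot(is_factor_spec(spec))
  if (!identical(g$labels, names(spec))) {
    abort("graph labels and factor spec do not match")
  }
  grid <- cell_grid(spec)
  ncells <- nrow(grid)
  contr <- lapply(as.integer(spec), stats::contr.sum)
  terms <- complete_subsets(g)
  blocks <- vector("list", length(terms) + 1L)
  blocks[[1]] <- matrix(1, ncells, 1)
  term_cols <- vector("list", length(terms) + 1L)
  names(term_cols) <- c("(Intercept)", names(terms))
  term_cols[[1]] <- 1L
  at <- 2L
  for (k in seq_along(terms)) {
    B <- matrix(1, ncells, 1)
    for (p in terms[[k]]) {
      Cp <- contr[[p]]
      lev <- grid[[p]] + 1L
      nb <- ncol(B)
      B <- B[, rep(seq_len(nb), each = ncol(Cp)), drop = FALSE] *
        Cp[lev, rep(seq_len(ncol(Cp)), times = nb), drop = FALSE]
    }
    blocks[[k + 1L]] <- B
    term_cols[[k + 1L]] <- seq.int(at, length.out = ncol(B))
    at <- at + ncol(B)
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- unlist(lapply(seq_along(term_cols), function(i) {
    nm <- names(term_cols)[i]
    k <- length(term_cols[[i]])
    if (k == 1) nm else paste0(nm, seq_len(k))
  }))
  structure(list(X = X, terms = terms, term_cols = term_cols, spec = spec,
                 graph = g),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " cells x ", ncol(x$X), " columns, ",
      length(x$terms), " terms\n", sep = "")
  invisible(x)
}

design_X <- function(design) {
  if (inherits(design, "design_matrix")) design$X else as.matrix(design)
}

#' Poisson log-likelihood of a log-linear model
#'
#' `sum(y * eta - exp(eta) - log(y!))` with `eta = X beta`; the `log(y!)`
#' term is retained so values are comparable across implementations.
#'
#' @param beta Coefficient vector (log scale), one per design column.
#' @param counts Cell counts: a `contingency_tbl` or bare numeric vector in
#'   canonical cell order.
#' @param design A [build_design()] result or bare matrix.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(beta, counts, design) {
  if (any(!is.finite(beta))) abort("`beta` must be finite")
  X <- design_X(design)
  y <- if (inherits(counts, "contingency_tbl")) cell_counts(counts) else as.numeric(counts)
  if (length(y) != nrow(X) || length(beta) != ncol(X)) abort("dimension mismatch")
  eta <- drop(X %*% beta)
  sum(y * eta - exp(eta) - lgamma(y + 1))
}

#' Unit-information prior log-density
#'
#' Multivariate normal with mean zero and covariance `n * (X'X)^-1` over all
#' columns including the intercept: the prior carries roughly the information
#' of a single observation.
#'
#' @inheritParams log_likelihood
#' @param n Total count of the table (prior sample-size calibration).
#' @return Scalar log-density.
#' @export
log_prior <- function(beta, design, n) {
  X <- design_X(design)
  k <- ncol(X)
  if (length(beta) != k) abort("dimension mismatch")
  G <- crossprod(X)
  R <- tryCatch(chol(G), error = function(e) {
    abort("design is rank deficient: model not identifiable")
  })
  logdet_G <- 2 * sum(log(diag(R)))
  quad <- sum((R %*% beta)^2) / n
  -k / 2 * log(2 * pi) - 0.5 * (k * log(n) - logdet_G) - 0.5 * quad
}
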