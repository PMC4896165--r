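# Synthetic-data generators: populations drawn from mixtures of graphical
# log-linear models, and finite mixtures of product multinomials with known
# cluster structure.

#' Default generating coefficients for a graphical model
#'
#' Main effects are zero; each two-way interaction inside a clique receives
#' the projection of the agreement pattern `kappa * 1(level_p == level_q)`
#' onto its contrast columns, so that within-clique pairwise (conditional)
#' log-odds ratios between adjacent levels are about `2 * kappa` (exactly 1
#' for binary factors at the default `kappa = 0.5`). Higher-order
#' coefficients are zero; the generating *graph* is unchanged by that choice
#' since graphical models are indexed by their graphs.
#'
#' @param design A [build_design()] result.
#' @param kappa Strength of the pairwise agreement pattern.
#' @return Numeric coefficient vector matching the design columns.
#' @export
gen_coefficients <- function(design, kappa = 0.5) {
  grid <- cell_grid(design$spec)
  beta <- numeric(ncol(design$X))
  for (k in seq_along(design$terms)) {
    tm <- design$terms[[k]]
    if (length(tm) != 2) next
    cols <- design$term_cols[[k + 1L]]
    B <- design$X[, cols, drop = FALSE]
    target <- kappa * as.numeric(grid[[tm[1]]] == grid[[tm[2]]])
    beta[cols] <- solve(crossprod(B), crossprod(B, target))
  }
  beta
}

#' Draw subjects from a graphical log-linear model
#'
#' Cell probabilities are proportional to `exp(X beta)` (stabilized by
#' subtracting the maximum linear predictor, which only shifts the
#' intercept); `n` subjects are allocated to cells by a single multinomial
#' draw and expanded back to subject-level rows.
#'
#' @param g An [llgraph()] (the generating graph).
#' @param spec A [factor_spec()].
#' @param n Number of subjects.
#' @param beta Coefficients for the design of `g`; default
#'   [gen_coefficients()].
#' @param kappa Passed to [gen_coefficients()] when `beta` is `NULL`.
#' @param seed Optional integer seed.
#' @param max_cells Tables with more cells than this are never materialized:
#'   the joint distribution factorizes over the connected components of the
#'   graph, so each component (and each isolated vertex) is sampled
#'   separately and only `data` is returned.
#' @return List with `data` (n x P tibble of integer levels), `table`
#'   (`contingency_tbl`), `probs` (cell probabilities), `beta`, `design`;
#'   the last four are `NULL` on the factorized path.
#' @export
sample_loglinear <- function(g, spec, n, beta = NULL, kappa = 0.5,
                             seed = NULL, max_cells = 2^20) {
  if (!is.null(seed)) set.seed(seed)
  if (count_cells(spec) > max_cells) {
    if (!is.null(beta)) {
      abort("explicit `beta` is not supported for tables this large; use `kappa`")
    }
    return(sample_loglinear_factorized(g, spec, n, kappa))
  }
  design <- build_design(g, spec)
  if (is.null(beta)) beta <- gen_coefficients(design, kappa)
  if (length(beta) != ncol(design$X)) abort("beta does not match the design")
  eta <- drop(design$X %*% beta)
  eta <- eta - max(eta)
  probs <- exp(eta) / sum(exp(eta))
  counts <- drop(rmultinom(1, n, probs))
  grid <- cell_grid(spec)
  data <- grid[rep.int(seq_len(nrow(grid)), counts), , drop = FALSE]
  data <- data[sample.int(nrow(data)), , drop = FALSE]
  tab <- grid
  tab$count <- as.numeric(counts)
  tab <- structure(tab, spec = spec, class = c("contingency_tbl", class(tab)))
  list(data = tibble::as_tibble(data), table = tab, probs = probs,
       beta = beta, design = design)
}

# component-wise sampling for graphs whose full table would be enormous;
# valid because with component-local terms the cell probabilities factorize
# over connected components (isolated vertices with zero main effects are
# uniform)
sample_loglinear_factorized <- function(g, spec, n, kappa) {
  P <- length(spec)
  ig <- igraph::make_empty_graph(n = P, directed = FALSE)
  if (nrow(g$edges) > 0) ig <- igraph::add_edges(ig, t(g$edges))
  memb <- igraph::components(ig)$membership
  out <- vector("list", P)
  for (cid in unique(memb)) {
    v <- which(memb == cid)
    if (length(v) == 1L) {
      out[[v]] <- sample.int(spec[[v]], n, replace = TRUE) - 1L
      next
    }
    sub_spec <- spec[v]
    sub_e <- g$edges[g$edges[, 1] %in% v, , drop = FALSE]
    sub_g <- llgraph(names(spec)[v], matrix(match(sub_e, v), ncol = 2))
    design <- build_design(sub_g, sub_spec)
    eta <- drop(design$X %*% gen_coefficients(design, kappa))
    pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
    grid <- cell_grid(sub_spec)
    idx <- sample.int(nrow(grid), n, replace = TRUE, prob = pr)
    for (j in seq_along(v)) out[[v[j]]] <- grid[[j]][idx]
  }
  names(out) <- names(spec)
  list(data = tibble::as_tibble(out), table = NULL, probs = NULL,
       beta = NULL, design = NULL)
}

#' Draw subjects from a mixture of graphical log-linear models
#'
#' Component sizes are multinomial in the mixture weights; each component
#' contributes a [sample_loglinear()] draw. Mixing several generating models
#' emulates the variability of real data while keeping the dominant
#' dependence structure that of the first component.
#'
#' @param graphs List of [llgraph()] components.
#' @param weights Mixture weights (sum to 1).
#' @param spec A [factor_spec()].
#' @param n Total number of subjects.
#' @param betas Optional list of coefficient vectors, one per component.
#' @param kappa Passed to [gen_coefficients()] for components without `beta`.
#' @param seed Optional integer seed.
#' @return List with `data` (tibble incl. `.component`), `table` (pooled
#'   `contingency_tbl`), `components` (per-component graph and beta), and
#'   `weights`.
#' @export
simulate_mixture <- function(graphs, weights, spec, n, betas = NULL,
                             kappa = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weights <- weights / sum(weights)
  if (length(graphs) != length(weights)) abort("one weight per component")
  sizes <- drop(rmultinom(1, n, weights))
  parts <- vector("list", length(graphs))
  comps <- vector("list", length(graphs))
  for (j in seq_along(graphs)) {
    s <- sample_loglinear(graphs[[j]], spec, sizes[j],
                          beta = betas[[j]] %||% NULL, kappa = kappa)
    d <- s$data
    d$.component <- j
    parts[[j]] <- d
    comps[[j]] <- list(graph = graphs[[j]], beta = s$beta)
  }
  data <- dplyr::bind_rows(parts)
  data <- data[sample.int(nrow(data)), , drop = FALSE]
  tab <- if (count_cells(spec) <= 2^20) {
    as_contingency(dplyr::select(data, -".component"), spec)
  }
  list(data = data, table = tab, components = comps, weights = weights)
}

#' Built-in simulation designs
#'
#' Five ready-made generator specifications spanning modest to sparse
#' contingency tables: three designs with 10 binary factors (two separated
#' cliques; two cliques sharing a vertex; three cliques), one with 20
#' three-level factors of which 6 interact, and one with 100 binary factors
#' of which 8 interact. Each design mixes a dominant generating model with
#' two thinned variants (an edge removed) to emulate real-data variability.
#'
#' @param id Design number 1 to 5, or `NULL` for the full catalog.
#' @return A list (or list of lists) with elements `name`, `n`, `spec`,
#'   `graphs` (3 components), `weights`, `kappa`, `important` (labels of
#'   covariates that form interactions).
#' @examples
#' preset_simulation(1)$important
#' @export
preset_simulation <- function(id = NULL) {
  mk <- function(name, n, spec, model1, drop2, drop3, weights) {
    g1 <- parse_model_any(model1, names(spec))
    list(name = name, n = n, spec = spec,
         graphs = list(g1,
                       remove_edge(g1, match(drop2, names(spec))),
                       remove_edge(g1, match(drop3, names(spec)))),
         weights = weights, kappa = 0.5,
         important = unique(names(spec)[sort(unique(as.vector(g1$edges)))]))
  }
  lab100 <- c(LETTERS[1:8], sprintf("V%02d", 9:100))
  cat <- list(
    mk("two separated cliques", 10000, factor_spec(LETTERS[1:10], 2),
       "ABCD+HIJ", c("A", "B"), c("I", "J"), c(0.8, 0.1, 0.1)),
    mk("two cliques sharing a vertex", 10000, factor_spec(LETTERS[1:10], 2),
       "ABCD+AFG", c("A", "B"), c("F", "G"), c(0.8, 0.1, 0.1)),
    mk("three cliques", 10000, factor_spec(LETTERS[1:10], 2),
       "ABCD+AFG+HIJ", c("A", "B"), c("I", "J"), c(0.8, 0.1, 0.1)),
    mk("sparse, 20 ternary factors", 5000, factor_spec(LETTERS[1:20], 3),
       "ABC+DEF", c("A", "B"), c("E", "F"), c(0.42, 0.29, 0.29)),
    mk("very sparse, 100 binary factors", 10000, factor_spec(lab100, 2),
       "ABCD+EFGH", c("A", "B"), c("G", "H"), c(0.8, 0.1, 0.1))
  )
  if (is.null(id)) return(cat)
  if (!id %in% 1:5) abort("preset id must be 1..5")
  cat[[id]]
}

# parse_model() for single-character labels; tolerate longer label sets by
# matching tokens against the first characters
parse_model_any <- function(text, labels) {
  short <- substr(labels, 1, 1)
  if (anyDuplicated(short[short %in% unlist(strsplit(gsub("\\+", "", text), ""))])) {
    abort("ambiguous single-character labels in model text")
  }
  toks <- strsplit(trimws(strsplit(text, "+", fixed = TRUE)[[1]]), "")
  cliques <- lapply(toks, function(ch) match(ch, short))
  graph_from_cliques(cliques, labels)
}

#' Simulate data from a built-in design
#'
#' @param id Design number 1 to 5.
#' @param n Number of subjects; defaults to the design's own size. Smaller
#'   values give scaled-down replicas for quick experiments.
#' @param seed Optional integer seed.
#' @return As [simulate_mixture()], plus elements `spec` and `important`.
#' @export
simulate_preset <- function(id, n = NULL, seed = NULL) {
  ps <- preset_simulation(id)
  out <- simulate_mixture(ps$graphs, ps$weights, ps$spec, n %||% ps$n,
                          kappa = ps$kappa, seed = seed)
  out$spec <- ps$spec
  out$important <- ps$important
  out$graph <- ps$graphs[[1]]
  out
}

#' Define a finite cluster population of product multinomials
#'
#' @param psi Cluster weights (simplex).
#' @param phi List over covariates; element `p` is a `C x M_p` matrix whose
#'   row `c` is the within-cluster level distribution of covariate `p`.
#' @param labels Covariate labels; defaults to `x1, x2, ...`.
#' @param gamma Optional `C x P` 0/1 matrix of selection switches. Covariates
#'   with `gamma = 0` in a cluster are drawn from the population marginal of
#'   their `phi` rows instead of the cluster-specific row (the two coincide
#'   when the rows are identical across clusters, the usual way to encode a
#'   non-contributing covariate). Default: all ones.
#' @return Object of class `cluster_population`.
#' @export
cluster_population <- function(psi, phi, labels = NULL, gamma = NULL) {
  psi <- as.numeric(psi)
  if (abs(sum(psi) - 1) > 1e-8 || any(psi < 0)) abort("psi must be a simplex")
  C <- length(psi)
  P <- length(phi)
  for (p in seq_len(P)) {
    phi[[p]] <- as.matrix(phi[[p]])
    if (nrow(phi[[p]]) != C) abort("each phi matrix needs one row per cluster")
    if (any(abs(rowSums(phi[[p]]) - 1) > 1e-8) || any(phi[[p]] < 0)) {
      abort("phi rows must be probability vectors")
    }
  }
  if (is.null(labels)) labels <- paste0("x", seq_len(P))
  if (is.null(gamma)) gamma <- matrix(1L, C, P)
  structure(list(psi = psi, phi = phi, labels = labels,
                 gamma = matrix(as.integer(gamma), C, P),
                 spec = factor_spec(labels, vapply(phi, ncol, 0L))),
            class = "cluster_population")
}

#' Closed-form covariate marginals of a cluster population
#'
#' `pi_p(x) = sum_c psi_c * phi_pc(x)^gamma_pc * pi_p(x)^(1 - gamma_pc)`
#' where the baseline for switched-off covariates is the psi-weighted mixture
#' of their `phi` rows.
#'
#' @param pop A [cluster_population()].
#' @return Tibble with columns `covariate`, `level`, `probability`.
#' @export
population_marginals <- function(pop) {
  P <- length(pop$phi)
  purrr::map_dfr(seq_len(P), function(p) {
    base <- drop(pop$psi %*% pop$phi[[p]])
    g <- pop$gamma[, p]
    m <- ncol(pop$phi[[p]])
    rows <- pop$phi[[p]] * g + matrix(base, length(pop$psi), m, byrow = TRUE) * (1 - g)
    tibble::tibble(covariate = pop$labels[p], level = 0:(m - 1L),
                   probability = drop(pop$psi %*% rows))
  })
}

#' Draw subjects from a cluster population
#'
#' @param pop A [cluster_population()].
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return Tibble of integer-coded covariates plus a `.cluster` column with
#'   the generating allocation.
#' @export
sample_population <- function(pop, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- length(pop$psi)
  z <- sample.int(C, n, replace = TRUE, prob = pop$psi)
  out <- vector("list", length(pop$phi))
  for (p in seq_along(pop$phi)) {
    m <- ncol(pop$phi[[p]])
    base <- drop(pop$psi %*% pop$phi[[p]])
    x <- integer(n)
    for (c in seq_len(C)) {
      i <- which(z == c)
      if (!length(i)) next
      pr <- if (pop$gamma[c, p] == 1L) pop$phi[[p]][c, ] else base
      x[i] <- sample.int(m, length(i), replace = TRUE, prob = pr) - 1L
    }
    out[[p]] <- x
  }
  names(out) <- pop$labels
  d <- tibble::as_tibble(out)
  d$.cluster <- z
  d
}

#' The three-cluster worked example population
#'
#' A small population of six three-level covariates and three clusters
#' (weights 0.3, 0.3, 0.4) in which the first four covariates drive the
#' clustering and the last two are identical across clusters, hence
#' uninformative. Its closed-form marginals include
#' `pi_1(0) = 0.3*0.01 + 0.3*0.01 + 0.4*0.29 = 0.122` and `pi_5(0) = 0.8`.
#'
#' @return A [cluster_population()].
#' @export
illustration_population <- function() {
  x1 <- rbind(c(0.01, 0.30, 0.69),
              c(0.01, 0.50, 0.49),
              c(0.29, 0.70, 0.01))
  x3 <- rbind(c(0.10, 0.10, 0.80),
              c(0.80, 0.10, 0.10),
              c(0.80, 0.10, 0.10))
  x5 <- rbind(c(0.80, 0.10, 0.10),
              c(0.80, 0.10, 0.10),
              c(0.80, 0.10, 0.10))
  gamma <- matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L), each = 3), 3, 6)
  cluster_population(psi = c(0.3, 0.3, 0.4),
                     phi = list(x1, x1, x3, x3, x5, x5),
                     labels = paste0("x", 1:6),
                     gamma = gamma)
}
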