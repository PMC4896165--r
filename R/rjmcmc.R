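# Reversible-jump MCMC over graphical log-linear models with uniform and
# evidence-informed edge proposals.
#
# Move mix per iteration: with probability 0.6 a within-model random-walk
# update of the coefficients; otherwise a jump attempting the addition,
# removal or replacement of one edge (equally likely). Edge selection is
# uniform, informed by the edge-evidence matrix, or a mixture, per strategy:
#   (a) uniform; (b) informed; (c) 30%/10% uniform/informed of iterations;
#   (d) 20%/20%.
# Trans-dimensional moves keep the coefficients of shared terms; birth
# coordinates are drawn from the cached Laplace approximation of the target
# model (posterior mode and mode curvature), whose density enters the
# acceptance ratio explicitly. The Jacobian is one.

strategy_weights <- function(strategy) {
  switch(strategy,
         a = c(1, 0), b = c(0, 1), c = c(0.75, 0.25), d = c(0.5, 0.5),
         abort("strategy must be one of 'a', 'b', 'c', 'd'"))
}

#' Informed edge-addition distribution
#'
#' Evidence values of pairs not currently joined by an edge, normalized to
#' sum to one; uniform over non-edges when all relevant evidence is zero.
#'
#' @param tgamma A [build_tgamma()] matrix.
#' @param g An [llgraph()].
#' @return Tibble with columns `from`, `to`, `prob` (empty for a complete
#'   graph).
#' @export
edge_add_distribution <- function(tgamma, g) {
  tgm <- tg_plain(tgamma, g)
  ne <- non_edges(g)
  p <- .add_probs(tgm, ne)
  tibble::tibble(from = g$labels[ne[, 1]], to = g$labels[ne[, 2]],
                 prob = p %||% numeric(0))
}

#' Informed edge-removal distribution
#'
#' Evidence values of current edges are normalized to sum to one and removal
#' uses the complementary probabilities (renormalized), so well-supported
#' edges are removed rarely. Uniform fallback for a single edge or constant
#' evidence.
#'
#' @inheritParams edge_add_distribution
#' @return Tibble with columns `from`, `to`, `prob` (empty for an edgeless
#'   graph).
#' @export
edge_remove_distribution <- function(tgamma, g) {
  tgm <- tg_plain(tgamma, g)
  p <- .rem_probs(tgm, g$edges)
  tibble::tibble(from = g$labels[g$edges[, 1]], to = g$labels[g$edges[, 2]],
                 prob = p %||% numeric(0))
}

tg_plain <- function(tgamma, g) {
  m <- unclass(as.matrix(tgamma))
  if (nrow(m) != length(g$labels)) abort("evidence matrix does not match graph")
  m[is.na(m)] <- 0
  m
}

.add_probs <- function(tgm, ne) {
  m <- nrow(ne)
  if (m == 0) return(NULL)
  tv <- tgm[ne]
  s <- sum(tv)
  if (s <= 0) rep(1 / m, m) else tv / s
}

.rem_probs <- function(tgm, ed) {
  m <- nrow(ed)
  if (m == 0) return(NULL)
  tv <- tgm[ed]
  s <- sum(tv)
  if (s <= 0) return(rep(1 / m, m))
  q <- 1 - tv / s
  sq <- sum(q)
  if (sq <= 0) rep(1 / m, m) else q / sq
}

# mixture edge densities: wu * uniform + wi * informed
.mix_add <- function(tgm, ne, w) {
  m <- nrow(ne)
  if (m == 0) return(NULL)
  pu <- rep(1 / m, m)
  if (w[2] == 0) return(list(p = pu, pinf = pu))
  pinf <- .add_probs(tgm, ne)
  list(p = w[1] * pu + w[2] * pinf, pinf = pinf)
}

.mix_rem <- function(tgm, ed, w) {
  m <- nrow(ed)
  if (m == 0) return(NULL)
  pu <- rep(1 / m, m)
  if (w[2] == 0) return(list(p = pu, pinf = pu))
  pinf <- .rem_probs(tgm, ed)
  list(p = w[1] * pu + w[2] * pinf, pinf = pinf)
}

match_pair <- function(pairs, e) {
  which(pairs[, 1] == e[1] & pairs[, 2] == e[2])
}

#' Prepare a table for reversible-jump model search
#'
#' Caches, per visited model: design matrix, prior Gram quantities, and the
#' posterior mode with its curvature (used both for within-model proposals
#' and as the Laplace evidence).
#'
#' @param table A `contingency_tbl`.
#' @return Object of class `rj_engine`.
#' @export
rj_engine <- function(table) {
  spec <- table_spec(table)
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$y <- cell_counts(table)
  e$n <- max(sum(e$y), 1)
  e$models <- new.env(parent = emptyenv())
  class(e) <- "rj_engine"
  e
}

#' @export
print.rj_engine <- function(x, ...) {
  cat("<rj_engine> ", length(x$spec), " factors, ", length(x$y),
      " cells, ", length(ls(x$models)), " models cached\n", sep = "")
  invisible(x)
}

.rj_entry <- function(engine, g, key = graph_key(g)) {
  ent <- engine$models[[key]]
  if (!is.null(ent)) return(ent)
  design <- build_design(g, engine$spec)
  fit <- map_fit(design$X, engine$y, engine$n)
  ent <- list(key = key, graph = g, X = design$X,
              term_cols = design$term_cols, k = ncol(design$X),
              G = fit$G, chol_G = fit$chol_G, logdet_G = fit$logdet_G,
              chol_H = fit$chol_hess, Hinv = chol2inv(fit$chol_hess),
              beta_map = fit$beta, log_marginal = fit$log_marginal)
  engine$models[[key]] <- ent
  ent
}

# log posterior kernel pieces (lgamma(y+1) omitted: constant per table)
.llq <- function(engine, ent, beta) {
  eta <- drop(ent$X %*% beta)
  sum(engine$y * eta - exp(eta))
}

.lpq <- function(engine, ent, beta) {
  -0.5 * sum((ent$chol_G %*% beta)^2) / engine$n
}

# full unit-information prior log density (normalizing constants matter in
# trans-dimensional ratios)
.lprior_full <- function(engine, ent, beta) {
  -ent$k / 2 * log(2 * pi) -
    0.5 * (ent$k * log(engine$n) - ent$logdet_G) +
    .lpq(engine, ent, beta)
}

# birth proposal for a coordinate subset: Gaussian centred at the model's
# posterior mode with the mode-curvature covariance, mildly inflated
.birth_scale2 <- 1.5^2

.birth_draw <- function(ent, idx) {
  S <- .birth_scale2 * ent$Hinv[idx, idx, drop = FALSE]
  R <- chol(S)
  u <- ent$beta_map[idx] + drop(crossprod(R, rnorm(length(idx))))
  list(u = u, logq = .dmvn(u - ent$beta_map[idx], R))
}

.birth_logq <- function(ent, idx, u) {
  S <- .birth_scale2 * ent$Hinv[idx, idx, drop = FALSE]
  .dmvn(u - ent$beta_map[idx], chol(S))
}

.dmvn <- function(centered, R) {
  z <- forwardsolve(t(R), centered)
  -length(centered) / 2 * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

shared_term_idx <- function(ent_a, ent_b) {
  shared <- intersect(names(ent_a$term_cols), names(ent_b$term_cols))
  list(a = unlist(ent_a$term_cols[shared], use.names = FALSE),
       b = unlist(ent_b$term_cols[shared], use.names = FALSE))
}

#' Current position of a reversible-jump chain
#'
#' @param engine An [rj_engine()].
#' @param g Starting graph; default edgeless (main effects only).
#' @param beta Starting coefficients; default the posterior mode.
#' @return Object of class `rj_state`.
#' @export
rj_state <- function(engine, g = NULL, beta = NULL) {
  g <- g %||% llgraph(names(engine$spec))
  ent <- .rj_entry(engine, g)
  beta <- beta %||% ent$beta_map
  if (length(beta) != ent$k) abort("beta does not match the model")
  structure(list(engine = engine, graph = g, key = ent$key, beta = beta),
            class = "rj_state")
}

# one proposal; cur = list(ent, beta); returns NULL for an impossible move
.move_propose <- function(engine, cur, w, tgm, param_scale = 2.38) {
  mtype <- sample.int(3L, 1L)
  informed <- w[2] > 0 && runif(1) < w[2]
  g <- cur$ent$graph
  if (mtype == 1L) {                                    # add
    ne <- non_edges(g)
    mix <- .mix_add(tgm, ne, w)
    if (is.null(mix)) {
      return(list(type = "add", possible = FALSE, informed = informed))
    }
    i <- sample.int(nrow(ne), 1L,
                    prob = if (informed) mix$pinf else rep(1, nrow(ne)))
    e <- ne[i, ]
    g2 <- add_edge(g, e)
    ent2 <- .rj_entry(engine, g2)
    mix_rev <- .mix_rem(tgm, g2$edges, w)
    lq <- log(mix_rev$p[match_pair(g2$edges, e)]) - log(mix$p[i])
    list(type = "add", possible = TRUE, ent = ent2, informed = informed,
         edge_in = e, log_q_edge = lq)
  } else if (mtype == 2L) {                             # remove
    ed <- g$edges
    mix <- .mix_rem(tgm, ed, w)
    if (is.null(mix)) {
      return(list(type = "remove", possible = FALSE, informed = informed))
    }
    i <- sample.int(nrow(ed), 1L,
                    prob = if (informed) mix$pinf else rep(1, nrow(ed)))
    e <- ed[i, ]
    g2 <- remove_edge(g, e)
    ent2 <- .rj_entry(engine, g2)
    ne2 <- non_edges(g2)
    mix_rev <- .mix_add(tgm, ne2, w)
    lq <- log(mix_rev$p[match_pair(ne2, e)]) - log(mix$p[i])
    list(type = "remove", possible = TRUE, ent = ent2, informed = informed,
         edge_out = e, log_q_edge = lq)
  } else {                                              # swap
    ed <- g$edges
    if (nrow(ed) == 0) {
      return(list(type = "swap", possible = FALSE, informed = informed))
    }
    mix_r <- .mix_rem(tgm, ed, w)
    i <- sample.int(nrow(ed), 1L,
                    prob = if (informed) mix_r$pinf else rep(1, nrow(ed)))
    e1 <- ed[i, ]
    g_mid <- remove_edge(g, e1)
    ne_mid <- non_edges(g_mid)
    mix_a <- .mix_add(tgm, ne_mid, w)
    j <- sample.int(nrow(ne_mid), 1L,
                    prob = if (informed) mix_a$pinf else rep(1, nrow(ne_mid)))
    e2 <- ne_mid[j, ]
    g2 <- add_edge(g_mid, e2)
    ent2 <- .rj_entry(engine, g2)
    # reverse: remove e2 from g2, then add e1 to g2 - e2 (= g_mid)
    mix_r2 <- .mix_rem(tgm, g2$edges, w)
    i_rev <- match_pair(g2$edges, e2)
    j_rev <- match_pair(ne_mid, e1)
    # coupled mixture density over the (remove, add) pair
    qf <- w[1] / (nrow(ed) * nrow(ne_mid)) +
      w[2] * mix_r$pinf[i] * mix_a$pinf[j]
    qr <- w[1] / (nrow(g2$edges) * nrow(ne_mid)) +
      w[2] * mix_r2$pinf[i_rev] * mix_a$pinf[j_rev]
    if (w[2] == 0) { qf <- 1 / (nrow(ed) * nrow(ne_mid)); qr <- qf }
    list(type = "swap", possible = TRUE, ent = ent2, informed = informed,
         edge_out = e1, edge_in = e2, log_q_edge = log(qr) - log(qf))
  }
}

# complete a trans-dimensional proposal with parameter values and its log
# acceptance ratio: shared-term coefficients are carried over, new
# coordinates drawn from the target model's Laplace proposal, and dropped
# coordinates would be re-proposed the same way on the reverse move
.move_complete <- function(engine, cur, prop) {
  ent2 <- prop$ent
  si <- shared_term_idx(cur$ent, ent2)
  idx_new <- setdiff(seq_len(ent2$k), si$b)
  idx_drop <- setdiff(seq_len(cur$ent$k), si$a)
  beta2 <- numeric(ent2$k)
  beta2[si$b] <- cur$beta[si$a]
  logq_fwd <- 0
  if (length(idx_new)) {
    bd <- .birth_draw(ent2, idx_new)
    beta2[idx_new] <- bd$u
    logq_fwd <- bd$logq
  }
  logq_rev <- if (length(idx_drop)) {
    .birth_logq(cur$ent, idx_drop, cur$beta[idx_drop])
  } else 0
  logA <- .llq(engine, ent2, beta2) + .lprior_full(engine, ent2, beta2) -
    .llq(engine, cur$ent, cur$beta) -
    .lprior_full(engine, cur$ent, cur$beta) +
    logq_rev - logq_fwd + prop$log_q_edge
  list(beta = beta2, logA = logA)
}

#' Propose one reversible-jump move
#'
#' Draws the move type from the 60/40 parameter/model mix, then either
#' perturbs the coefficients within the current model or proposes an edge
#' addition, removal or swap with edge selection per strategy.
#'
#' @param state An [rj_state()].
#' @param strategy One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param tgamma Edge-evidence matrix; required for strategies b, c, d.
#' @param param_prob Probability of a within-model parameter move
#'   (default 0.6).
#' @return Object of class `rj_proposal`: list with `type` (`"parameter"`,
#'   `"add"`, `"remove"`, `"swap"`), `possible`, proposed `graph` and
#'   `beta`, the edge(s) involved, `informed`, and `log_ratio` (the log
#'   acceptance ratio; `-Inf` for impossible moves).
#' @export
propose_move <- function(state, strategy = "d", tgamma = NULL,
                         param_prob = 0.6) {
  engine <- state$engine
  w <- strategy_weights(strategy)
  if (w[2] > 0 && is.null(tgamma)) {
    abort("strategies 'b', 'c', 'd' need an edge-evidence matrix")
  }
  tgm <- if (is.null(tgamma)) NULL else tg_plain(tgamma, state$graph)
  cur <- list(ent = .rj_entry(engine, state$graph), beta = state$beta)
  if (runif(1) < param_prob) {
    k <- cur$ent$k
    beta2 <- cur$beta + 2.38 / sqrt(k) *
      backsolve(cur$ent$chol_H, rnorm(k))
    logA <- .llq(engine, cur$ent, beta2) + .lpq(engine, cur$ent, beta2) -
      .llq(engine, cur$ent, cur$beta) - .lpq(engine, cur$ent, cur$beta)
    return(structure(list(type = "parameter", possible = TRUE,
                          graph = state$graph, beta = beta2,
                          informed = FALSE, log_ratio = logA),
                     class = "rj_proposal"))
  }
  prop <- .move_propose(engine, cur, w, tgm)
  if (!prop$possible) {
    return(structure(list(type = prop$type, possible = FALSE,
                          graph = state$graph, beta = state$beta,
                          informed = prop$informed, log_ratio = -Inf),
                     class = "rj_proposal"))
  }
  cmp <- .move_complete(engine, cur, prop)
  structure(list(type = prop$type, possible = TRUE,
                 graph = prop$ent$graph, beta = cmp$beta,
                 edge_in = prop$edge_in, edge_out = prop$edge_out,
                 informed = prop$informed, log_ratio = cmp$logA),
            class = "rj_proposal")
}

#' Log acceptance ratio of a proposal
#'
#' The full reversible-jump ratio: likelihood ratio, prior ratio (with the
#' dimension-dependent normalizing constants), parameter-proposal density
#' ratio for born/dropped coordinates (drawn from the target model's Laplace
#' approximation; Jacobian one), and the edge-proposal ratio required by the
#' asymmetric informed proposals. A proposal identical to the current state
#' has ratio 0.
#'
#' @param proposal An [propose_move()] result.
#' @param state The [rj_state()] it was proposed from.
#' @return Scalar log acceptance ratio.
#' @export
acceptance_log_ratio <- function(proposal, state) {
  proposal$log_ratio
}

#' Reversible-jump search over graphical log-linear models
#'
#' @param table A `contingency_tbl`.
#' @param strategy Edge-selection strategy `"a"` (uniform), `"b"`
#'   (evidence-informed), `"c"` (30/10 mix), `"d"` (20/20 mix, default).
#' @param tgamma Edge-evidence matrix from [build_tgamma()]; required for
#'   strategies b, c, d.
#' @param iters Total iterations (including burn-in).
#' @param burnin Iterations excluded from the visit frequencies.
#' @param seed Integer seed.
#' @param init Starting [llgraph()]; default edgeless.
#' @param param_prob Probability of a within-model parameter move (0.6).
#' @return Object of class `rj_chain`: list with `models` (tibble of visited
#'   models with posterior visit frequencies), `best` (highest-frequency
#'   model string), `first_hit` (first iteration visiting it), acceptance
#'   rates, and per-iteration traces (`model_id`, `move`, `accepted`,
#'   `informed`).
#' @examples
#' sim <- sample_loglinear(parse_model("AB", LETTERS[1:2]),
#'                         factor_spec(LETTERS[1:2], 2), 500, seed = 1)
#' rj_search(sim$table, strategy = "a", iters = 500, burnin = 100, seed = 1)
#' @export
rj_search <- function(table, strategy = "d", tgamma = NULL, iters = 10000,
                      burnin = 1000, seed = NULL, init = NULL,
                      param_prob = 0.6) {
  if (!is.null(seed)) set.seed(seed)
  w <- strategy_weights(strategy)
  if (w[2] > 0 && is.null(tgamma)) {
    abort("strategies 'b', 'c', 'd' need an edge-evidence matrix")
  }
  if (burnin >= iters) abort("`iters` must exceed `burnin`")
  engine <- rj_engine(table)
  g0 <- init %||% llgraph(names(engine$spec))
  tgm <- if (is.null(tgamma)) NULL else tg_plain(tgamma, g0)
  ent <- .rj_entry(engine, g0)
  cur <- list(ent = ent, beta = ent$beta_map)
  llq <- .llq(engine, ent, cur$beta)
  lpq <- .lpq(engine, ent, cur$beta)
  # model registry: key -> integer id
  reg <- new.env(parent = emptyenv())
  keys <- character(64); n_models <- 0L
  get_id <- function(key) {
    id <- reg[[key]]
    if (!is.null(id)) return(id)
    n_models <<- n_models + 1L
    if (n_models > length(keys)) keys <<- c(keys, character(length(keys)))
    keys[n_models] <<- key
    reg[[key]] <- n_models
    n_models
  }
  ids <- integer(iters); moves <- integer(iters)
  accepted <- logical(iters); informed <- logical(iters)
  n_model_att <- 0L; n_model_acc <- 0L; n_param_att <- 0L; n_param_acc <- 0L
  for (it in seq_len(iters)) {
    if (runif(1) < param_prob) {
      moves[it] <- 0L
      n_param_att <- n_param_att + 1L
      k <- cur$ent$k
      beta2 <- cur$beta + 2.38 / sqrt(k) * backsolve(cur$ent$chol_H, rnorm(k))
      llq2 <- .llq(engine, cur$ent, beta2)
      lpq2 <- .lpq(engine, cur$ent, beta2)
      if (log(runif(1)) < llq2 + lpq2 - llq - lpq) {
        cur$beta <- beta2; llq <- llq2; lpq <- lpq2
        accepted[it] <- TRUE; n_param_acc <- n_param_acc + 1L
      }
    } else {
      n_model_att <- n_model_att + 1L
      prop <- .move_propose(engine, cur, w, tgm)
      moves[it] <- match(prop$type, c("add", "remove", "swap"))
      informed[it] <- prop$informed
      if (prop$possible) {
        cmp <- .move_complete(engine, cur, prop)
        if (log(runif(1)) < cmp$logA) {
          cur <- list(ent = prop$ent, beta = cmp$beta)
          llq <- .llq(engine, cur$ent, cur$beta)
          lpq <- .lpq(engine, cur$ent, cur$beta)
          accepted[it] <- TRUE; n_model_acc <- n_model_acc + 1L
        }
      }
    }
    ids[it] <- get_id(cur$ent$key)
  }
  post <- ids[(burnin + 1):iters]
  freq <- tabulate(post, n_models)
  best_id <- which.max(freq)
  first_hit <- match(best_id, ids)
  labs <- vapply(seq_len(n_models), function(i) {
    format_model(engine$models[[keys[i]]]$graph)
  }, "")
  models <- tibble::tibble(model = labs, visits = freq,
                           posterior = freq / length(post)) |>
    dplyr::arrange(dplyr::desc(.data$posterior))
  structure(list(models = models, best = labs[best_id],
                 first_hit = first_hit,
                 accept_rate_model = if (n_model_att) n_model_acc / n_model_att else NA_real_,
                 accept_rate_param = if (n_param_att) n_param_acc / n_param_att else NA_real_,
                 model_id = ids, model_key = keys[seq_len(n_models)],
                 move = moves, accepted = accepted, informed = informed,
                 strategy = strategy, iters = iters, burnin = burnin,
                 spec = engine$spec),
            class = "rj_chain")
}

#' @export
print.rj_chain <- function(x, ...) {
  cat("<rj_chain> strategy (", x$strategy, "), ", x$iters, " iterations\n",
      "best model: ", x$best, "  (posterior ",
      round(x$models$posterior[x$models$model == x$best], 3),
      ", first hit at iteration ", x$first_hit, ")\n",
      "model-move acceptance: ",
      round(100 * x$accept_rate_model, 1), "%\n", sep = "")
  print(head(x$models, 5))
  invisible(x)
}
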