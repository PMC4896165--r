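# Truncated blocked Gibbs sampler for the stick-breaking Dirichlet-process
# mixture of product multinomials with cluster-specific variable-selection
# switches.
#
# Subject i with profile x_i = (x_i1, ..., x_iP) has, given allocation z_i = c,
#   P(x_.p = x | z_i = c) = phi_pc(x)^gamma_pc * pi_p(x)^(1 - gamma_pc),
# where gamma_pc = 1 flags covariate p as driving cluster c and pi_p is the
# sample-wide marginal, held fixed at the observed frequencies. Selection
# probabilities rho_p carry a sparsity prior with an atom at zero:
#   rho_p ~ 1{w_p = 0} delta_0 + 1{w_p = 1} Beta(a_rho, b_rho), w_p ~ Bern(0.5).

#' Hyperparameters and sampler settings for the profile clustering model
#'
#' @param lambda Symmetric Dirichlet parameter for the within-cluster level
#'   probabilities (default 0.5).
#' @param a_rho,b_rho Beta hyperparameters of the slab part of the
#'   selection-probability prior (defaults 1, 1).
#' @param alpha_shape,alpha_rate Gamma prior for the concentration parameter
#'   (defaults 2, 1).
#' @param alpha_fixed Optional numeric: hold the concentration parameter
#'   fixed at this value instead of sampling it.
#' @param k_init Number of groups for the random initial allocation
#'   (default 10).
#' @param trunc_init,trunc_max,trunc_grow Truncation level of the blocked
#'   sampler: initial number of sticks, hard cap, and growth increment used
#'   whenever the last stick is occupied.
#' @return A list of class `dp_options`.
#' @export
dp_options <- function(lambda = 0.5, a_rho = 1, b_rho = 1,
                       alpha_shape = 2, alpha_rate = 1, alpha_fixed = NULL,
                       k_init = 10, trunc_init = 25, trunc_max = 50,
                       trunc_grow = 5) {
  stopifnot(lambda > 0, a_rho > 0, b_rho > 0, k_init >= 1,
            trunc_init >= 2, trunc_max >= trunc_init, trunc_grow >= 1)
  structure(list(lambda = lambda, a_rho = a_rho, b_rho = b_rho,
                 alpha_shape = alpha_shape, alpha_rate = alpha_rate,
                 alpha_fixed = alpha_fixed, k_init = k_init,
                 trunc_init = trunc_init, trunc_max = trunc_max,
                 trunc_grow = trunc_grow),
            class = "dp_options")
}

#' Prepare covariate data for the profile clustering sampler
#'
#' Validates integer coding, fixes the marginal level frequencies `pi_p` at
#' their observed values, and precomputes the sparse subject-by-level
#' indicator used by the blocked allocation update.
#'
#' @param data Data frame of integer-coded covariates (levels from 0); any
#'   column whose name starts with `.` is dropped.
#' @param spec Optional [factor_spec()]; inferred when `NULL`.
#' @return Object of class `dp_data`.
#' @export
dp_data <- function(data, spec = NULL) {
  data <- tibble::as_tibble(data)
  data <- data[!startsWith(names(data), ".")]
  if (is.null(spec)) spec <- infer_spec(data) else check_levels(data, spec)
  data <- data[names(spec)]
  n <- nrow(data)
  P <- length(spec)
  M <- as.integer(spec)
  off <- c(0L, cumsum(M))[seq_len(P)]
  L <- sum(M)
  X <- matrix(0L, n, P)
  for (p in seq_len(P)) X[, p] <- as.integer(data[[p]])
  jmat <- sweep(X, 2, off, "+") + 1L  # stacked level index per subject/covariate
  B <- Matrix::sparseMatrix(i = rep(seq_len(n), times = P),
                            j = as.vector(jmat), x = 1, dims = c(n, L))
  pi <- tabulate(as.vector(jmat), L) / n
  rowp <- rep(seq_len(P), times = M)
  structure(list(X = X, jmat = jmat, B = B, pi = pi, rowp = rowp,
                 spec = spec, n = n, P = P, L = L, M = M, off = off),
            class = "dp_data")
}

#' @export
print.dp_data <- function(x, ...) {
  cat("<dp_data> ", x$n, " subjects x ", x$P, " covariates\n", sep = "")
  invisible(x)
}

#' Initialize the sampler state
#'
#' Subjects are allocated at random to `k_init` groups; all switches start
#' at 1, selection probabilities at 0.5, sticks at their prior draws.
#'
#' @param prep A [dp_data()] object.
#' @param options A [dp_options()] list.
#' @return Object of class `dp_state`.
#' @export
dp_state_init <- function(prep, options = dp_options()) {
  C <- options$trunc_init
  P <- prep$P
  alpha <- options$alpha_fixed %||%
    (options$alpha_shape / options$alpha_rate)
  z <- sample.int(min(options$k_init, C), prep$n, replace = TRUE)
  V <- c(rbeta(C - 1, 1, alpha), 1)
  state <- list(z = z, C = C, V = V, psi = sticks_to_psi(V),
                alpha = alpha,
                phi = prior_phi_draw(prep, C, options$lambda),
                gamma = matrix(1L, P, C),
                rho = rep(0.5, P), w = rep(1L, P),
                opts = options)
  class(state) <- "dp_state"
  state
}

sticks_to_psi <- function(V) {
  V * c(1, cumprod(1 - V[-length(V)]))
}

prior_phi_draw <- function(prep, C, lambda) {
  g <- matrix(rgamma(prep$L * C, shape = lambda), prep$L, C)
  g <- pmax(g, 1e-12)
  g / rowsum(g, prep$rowp)[prep$rowp, , drop = FALSE]
}

# effective log level-probabilities per (stacked level, cluster):
# log phi where the switch is on, log pi otherwise
effective_logprob <- function(state, prep) {
  E <- matrix(log(pmax(prep$pi, 1e-300)), prep$L, state$C)
  sel <- state$gamma[prep$rowp, , drop = FALSE] == 1L
  lp <- log(state$phi)
  E[sel] <- lp[sel]
  E
}

# level counts per (stacked level, cluster) under the current allocation
level_counts <- function(state, prep) {
  flat <- as.vector(prep$jmat + (state$z - 1L) * prep$L)
  matrix(tabulate(flat, prep$L * state$C), prep$L, state$C)
}

#' Likelihood of one subject's profile in one cluster
#'
#' Evaluates `prod_p phi_pc(x_p)^gamma_pc * pi_p(x_p)^(1-gamma_pc)` for the
#' current state.
#'
#' @param x Integer level vector (coded from 0), one entry per covariate.
#' @param c Cluster index.
#' @param state A `dp_state`.
#' @param prep The matching [dp_data()] object.
#' @return Scalar probability.
#' @export
subject_likelihood <- function(x, c, state, prep) {
  if (length(x) != prep$P) abort("profile length does not match the data")
  j <- prep$off + as.integer(x) + 1L
  g <- state$gamma[, c]
  if (any(prep$pi[j] == 0 & g == 0L)) {
    abort("invalid state: marginal probability zero for an observed level")
  }
  prod(ifelse(g == 1L, state$phi[j, c], prep$pi[j]))
}

#' Gibbs update of the cluster allocations
#'
#' Each subject is reallocated with `P(z_i = c)` proportional to
#' `psi_c * P(x_i | cluster c)` over the truncated stick set.
#'
#' @inheritParams subject_likelihood
#' @return The updated state.
#' @export
update_allocations <- function(state, prep) {
  E <- effective_logprob(state, prep)
  lw <- as.matrix(prep$B %*% E)
  lw <- lw + matrix(log(state$psi), prep$n, state$C, byrow = TRUE)
  m <- lw[cbind(seq_len(prep$n), max.col(lw, "first"))]
  w <- exp(lw - m)
  cw <- w %*% upper.tri(diag(state$C), diag = TRUE)
  u <- runif(prep$n) * cw[, state$C]
  state$z <- state$C + 1L - rowSums(cw >= u)
  state
}

#' Gibbs update of the within-cluster level probabilities
#'
#' Conjugate Dirichlet draws: level counts of a cluster's members enter the
#' posterior only where the selection switch is on; otherwise (and for empty
#' clusters) the conditional is the `Dirichlet(lambda)` prior.
#'
#' @inheritParams subject_likelihood
#' @return The updated state.
#' @export
update_phi <- function(state, prep) {
  cnt <- level_counts(state, prep)
  shape <- state$opts$lambda +
    cnt * (state$gamma[prep$rowp, , drop = FALSE] == 1L)
  g <- matrix(rgamma(length(shape), shape = shape), prep$L, state$C)
  g <- pmax(g, 1e-12)
  state$phi <- g / rowsum(g, prep$rowp)[prep$rowp, , drop = FALSE]
  state
}

#' Gibbs update of the selection switches
#'
#' `gamma_pc` is Bernoulli with odds
#' `rho_p * prod_i phi_pc(x_ip) : (1 - rho_p) * prod_i pi_p(x_ip)` over the
#' cluster's members; empty clusters reduce to the `Bernoulli(rho_p)` prior.
#'
#' @inheritParams subject_likelihood
#' @return The updated state.
#' @export
update_gamma <- function(state, prep) {
  cnt <- level_counts(state, prep)
  d <- log(state$phi) - log(pmax(prep$pi, 1e-300))
  d[cnt == 0] <- 0          # avoid 0 * -Inf for unobserved levels
  S <- rowsum(cnt * d, prep$rowp)
  p1 <- plogis(qlogis(state$rho) + S)
  state$gamma <- matrix(as.integer(runif(length(p1)) < p1), prep$P, state$C)
  state
}

#' Collapsed update of the selection switches with the level probabilities
#'
#' A blocked Gibbs move drawing `(gamma_pc, phi_pc)` jointly given the
#' allocations: the switch is sampled with `phi` integrated out, using the
#' Dirichlet-multinomial marginal of the cluster's level counts against the
#' fixed-marginal alternative,
#' `odds = rho_p * DirMult(counts; lambda) : (1 - rho_p) * prod pi_p(x)`,
#' and `phi` is then redrawn from its conditional. The marginalization
#' carries the automatic complexity penalty of the Dirichlet prior, so
#' switches of non-contributing covariates are not held on by level
#' probabilities that have drifted towards a cluster's sampling noise; the
#' chain mixes far better over the spike-and-slab than with the
#' fixed-`phi` conditional alone.
#'
#' @inheritParams subject_likelihood
#' @return The updated state (both `gamma` and `phi` refreshed).
#' @export
update_gamma_phi <- function(state, prep) {
  cnt <- level_counts(state, prep)
  lam <- state$opts$lambda
  # log Dirichlet-multinomial marginal, per covariate and cluster
  A <- rowsum(lgamma(lam + cnt) - lgamma(lam), prep$rowp)
  nc <- tabulate(state$z, state$C)
  Mlam <- prep$M * lam
  occam <- lgamma(Mlam) - lgamma(outer(Mlam, nc, "+"))
  base <- rowsum(cnt * log(pmax(prep$pi, 1e-300)), prep$rowp)
  log_bf <- A + occam - base
  p1 <- plogis(qlogis(state$rho) + log_bf)
  state$gamma <- matrix(as.integer(runif(length(p1)) < p1),
                        prep$P, state$C)
  update_phi(state, prep)
}

#' Gibbs update of the selection probabilities and their point mass
#'
#' Joint update of `(w_p, rho_p)`: any active switch among occupied clusters
#' forces the slab (`w_p = 1`); otherwise `w_p` is drawn from its conditional
#' with the Beta marginal likelihood of the all-zero switch vector. Given the
#' slab, `rho_p ~ Beta(a + S_p, b + C_occ - S_p)`. Empty clusters' switches
#' are marginalized out of this update (their likelihood contribution is
#' flat) and redrawn from `Bernoulli(rho_p)` afterwards, which makes the
#' occupied-cluster counting an exact partially collapsed Gibbs step.
#'
#' @inheritParams subject_likelihood
#' @return The updated state.
#' @export
update_rho <- function(state, prep) {
  occ <- which(tabulate(state$z, state$C) > 0L)
  Cocc <- length(occ)
  S <- rowSums(state$gamma[, occ, drop = FALSE])
  a <- state$opts$a_rho; b <- state$opts$b_rho
  w <- rep(1L, prep$P)
  rho <- numeric(prep$P)
  zero <- S == 0L
  if (any(zero)) {
    log_m1 <- lbeta(a, b + Cocc) - lbeta(a, b)
    p1 <- exp(log_m1) / (1 + exp(log_m1))
    w[zero] <- rbinom(sum(zero), 1L, p1)
  }
  slab <- w == 1L
  rho[slab] <- rbeta(sum(slab), a + S[slab], b + Cocc - S[slab])
  state$w <- w
  state$rho <- rho
  empty <- setdiff(seq_len(state$C), occ)
  if (length(empty)) {
    state$gamma[, empty] <- matrix(rbinom(prep$P * length(empty), 1L, rho),
                                   prep$P, length(empty))
  }
  state
}

#' Gibbs update of the stick-breaking weights and concentration parameter
#'
#' `V_c ~ Beta(1 + n_c, alpha + sum_{l>c} n_l)` with the last stick fixed at
#' one; the concentration parameter gets its conjugate Gamma update given the
#' sticks. If the last stick is occupied and the cap allows, the truncation
#' level grows and the new clusters receive prior draws.
#'
#' @inheritParams subject_likelihood
#' @return The updated state.
#' @export
update_sticks_alpha <- function(state, prep) {
  C <- state$C
  nc <- tabulate(state$z, C)
  after <- sum(nc) - cumsum(nc)
  V <- c(rbeta(C - 1, 1 + nc[-C], state$alpha + after[-C]), 1)
  V[-C] <- pmin(V[-C], 1 - 1e-12)
  if (is.null(state$opts$alpha_fixed)) {
    state$alpha <- rgamma(1, shape = state$opts$alpha_shape + C - 1,
                          rate = state$opts$alpha_rate - sum(log1p(-V[-C])))
  }
  state$V <- V
  state$psi <- sticks_to_psi(V)
  if (nc[C] > 0L && C < state$opts$trunc_max) {
    grow <- min(state$opts$trunc_grow, state$opts$trunc_max - C)
    newC <- C + grow
    V <- c(V[-C], rbeta(grow, 1, state$alpha), 1)[seq_len(newC)]
    V[-newC] <- pmin(V[-newC], 1 - 1e-12)
    state$V <- V
    state$psi <- sticks_to_psi(V)
    state$phi <- cbind(state$phi, prior_phi_draw(prep, grow, state$opts$lambda))
    state$gamma <- cbind(state$gamma,
                         matrix(rbinom(prep$P * grow, 1L, state$rho),
                                prep$P, grow))
    state$C <- newC
  }
  state
}

#' Fit the profile clustering model
#'
#' Runs the truncated blocked Gibbs sampler with a fixed sweep order:
#' allocations, level probabilities, switches, a collapsed switch/level
#' refresh (see [update_gamma_phi()]), selection probabilities, then sticks
#' and concentration. Marginal frequencies `pi_p` stay fixed at the observed
#' values throughout.
#'
#' @param data Data frame of integer-coded covariates (one row per subject),
#'   or a [dp_data()] object. Columns whose names start with `.` are ignored.
#' @param burnin Iterations discarded.
#' @param iter Iterations kept after burn-in.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param options A [dp_options()] list.
#' @param seed Integer seed (recommended: runs are reproducible given the
#'   seed).
#' @param spec Optional [factor_spec()] when `data` is a data frame.
#' @return Object of class `dp_chain`: list with `z` (kept iterations x n
#'   allocation matrix), `rho` (iterations x P), `alpha`, `snapshots` (per
#'   iteration: occupied cluster ids, sizes, switch matrix, level
#'   probabilities), `pi`, `spec`, `options`.
#' @examples
#' pop <- illustration_population()
#' d <- sample_population(pop, 200, seed = 1)
#' ch <- dp_cluster(d, burnin = 50, iter = 100, seed = 1)
#' tidy(ch)
#' @export
dp_cluster <- function(data, burnin = 500, iter = 1000, thin = 1,
                       options = dp_options(), seed = NULL, spec = NULL) {
  if (burnin < 0 || iter < 1 || thin < 1) abort("invalid chain lengths")
  if (!is.null(seed)) set.seed(seed)
  prep <- if (inherits(data, "dp_data")) data else dp_data(data, spec)
  state <- dp_state_init(prep, options)
  kept <- 0L
  z_out <- matrix(NA_integer_, iter, prep$n)
  rho_out <- matrix(NA_real_, iter, prep$P,
                    dimnames = list(NULL, names(prep$spec)))
  alpha_out <- numeric(iter)
  snaps <- vector("list", iter)
  total <- burnin + iter * thin
  for (it in seq_len(total)) {
    state <- update_allocations(state, prep)
    state <- update_phi(state, prep)
    state <- update_gamma(state, prep)
    state <- update_gamma_phi(state, prep)
    state <- update_rho(state, prep)
    state <- update_sticks_alpha(state, prep)
    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      z_out[kept, ] <- state$z
      rho_out[kept, ] <- state$rho
      alpha_out[kept] <- state$alpha
      sizes <- tabulate(state$z, state$C)
      occ <- which(sizes > 0L)
      snaps[[kept]] <- list(ids = occ, sizes = sizes[occ],
                            gamma = state$gamma[, occ, drop = FALSE],
                            phi = state$phi[, occ, drop = FALSE])
    }
  }
  structure(list(z = z_out, rho = rho_out, alpha = alpha_out,
                 snapshots = snaps, pi = prep$pi, rowp = prep$rowp,
                 spec = prep$spec, options = options, n = prep$n,
                 burnin = burnin, thin = thin),
            class = "dp_chain")
}

#' @export
print.dp_chain <- function(x, ...) {
  occ <- vapply(x$snapshots, function(s) length(s$ids), 0L)
  cat("<dp_chain> ", nrow(x$z), " kept iterations, ", x$n, " subjects, ",
      length(x$spec), " covariates; mean occupied clusters ",
      round(mean(occ), 1), "\n", sep = "")
  cat("posterior median selection probabilities:\n")
  print(round(apply(x$rho, 2, median), 3))
  invisible(x)
}

#' Posterior median selection probabilities
#' @param chain A [dp_cluster()] result.
#' @return Named numeric vector of per-covariate posterior medians of `rho`.
#' @export
rho_medians <- function(chain) {
  apply(chain$rho, 2, median)
}
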