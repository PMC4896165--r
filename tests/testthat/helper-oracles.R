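# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Exact posterior of (z1, z2, switches of occupied clusters) for two
# subjects, one binary covariate, truncation at two sticks and a fixed
# concentration parameter; empty-cluster switches are summed out. Everything
# is enumerated from the model's closed-form marginals (Beta/Dirichlet
# conjugacy), independently of the sampler.
toy_posterior_exact <- function(x, lambda = 0.5, a = 1, b = 1, alpha = 1) {
  n <- length(x)
  pi <- tabulate(x + 1, 2) / n
  fS <- function(S) {
    0.5 * (S == 0) + 0.5 * exp(lbeta(a + S, b + 2 - S) - lbeta(a, b))
  }
  lik_c <- function(mem, g) {
    if (g == 1) {
      cnt <- tabulate(mem + 1, 2)
      exp(lgamma(2 * lambda) - 2 * lgamma(lambda) +
            sum(lgamma(lambda + cnt)) - lgamma(2 * lambda + length(mem)))
    } else {
      prod(pi[mem + 1])
    }
  }
  val <- numeric(0)
  for (z1 in 1:2) for (z2 in 1:2) {
    z <- c(z1, z2)
    n1 <- sum(z == 1)
    pz <- exp(lbeta(1 + n1, alpha + (n - n1)) - lbeta(1, alpha))
    occ <- sort(unique(z))
    gcfg <- expand.grid(rep(list(0:1), length(occ)))
    for (r in seq_len(nrow(gcfg))) {
      g <- as.integer(gcfg[r, ])
      lik <- prod(vapply(seq_along(occ),
                         function(i) lik_c(x[z == occ[i]], g[i]), 0))
      S <- sum(g)
      pg <- if (length(occ) == 2) fS(S) else fS(S) + fS(S + 1)
      key <- paste(c(z, paste0("c", occ, "=", g)), collapse = "|")
      val <- c(val, setNames(pz * lik * pg, key))
    }
  }
  val / sum(val)
}

# state key of a kept clustering iteration, matching toy_posterior_exact
toy_state_key <- function(chain, t) {
  sn <- chain$snapshots[[t]]
  paste(c(chain$z[t, ], paste0("c", sn$ids, "=", sn$gamma[1, ])),
        collapse = "|")
}

# Cramer's V between two integer-coded vectors, from the chi-square statistic
cramers_v <- function(x, y) {
  tab <- table(x, y)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

# adjusted Rand index (closed form on the contingency table of the two
# partitions)
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(sum(tab), 2)
  exp_ij <- sum_a * sum_b / tot
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}

# minimal hand-built clustering-chain object for post-processing tests
fake_chain <- function(z, gammas, sizes = NULL, phis = NULL, rho = NULL,
                       spec = NULL, pi = NULL) {
  iters <- nrow(z)
  n <- ncol(z)
  P <- nrow(gammas[[1]])
  spec <- spec %||% factor_spec(paste0("x", seq_len(P)), 2)
  M <- as.integer(spec)
  L <- sum(M)
  rowp <- rep(seq_along(M), times = M)
  pi <- pi %||% rep(1 / M[1], L)
  snaps <- lapply(seq_len(iters), function(t) {
    sz <- tabulate(z[t, ], max(z[t, ]))
    ids <- which(sz > 0)
    list(ids = ids, sizes = if (is.null(sizes)) sz[ids] else sizes[[t]],
         gamma = gammas[[t]][, ids, drop = FALSE],
         phi = if (is.null(phis)) {
           matrix(rep(1 / M[rowp], length(ids)), L, length(ids))
         } else {
           phis[[t]][, ids, drop = FALSE]
         })
  })
  structure(list(z = z,
                 rho = if (is.null(rho)) matrix(0.5, iters, P,
                                                dimnames = list(NULL, names(spec)))
                       else rho,
                 alpha = rep(1, iters), snapshots = snaps, pi = pi,
                 rowp = rowp, spec = spec, options = dp_options(),
                 n = n, burnin = 0, thin = 1),
            class = "dp_chain")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
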