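# direct checks of the Gibbs conditionals against closed forms, plus chain
# level contracts; the joint-correctness enumeration check lives with the
# acceptance suite.

make_state <- function(d, options = dp_options(), seed = 1) {
  set.seed(seed)
  prep <- dp_data(d)
  list(prep = prep, state = dp_state_init(prep, options))
}

test_that("subject likelihood follows the switch structure", {
  pop <- illustration_population()
  d <- sample_population(pop, 50, seed = 1)
  ms <- make_state(d)
  st <- ms$state; prep <- ms$prep

  # all switches off: product of marginals, identical across clusters
  st0 <- st; st0$gamma[] <- 0L
  x <- as.integer(d[1, 1:6])
  l1 <- subject_likelihood(x, 1, st0, prep)
  l2 <- subject_likelihood(x, 2, st0, prep)
  expect_equal(l1, prod(prep$pi[prep$off + x + 1]))
  expect_equal(l1, l2)

  # all switches on: product of cluster-specific probabilities
  st1 <- st; st1$gamma[] <- 1L
  j <- prep$off + x + 1
  expect_equal(subject_likelihood(x, 3, st1, prep), prod(st1$phi[j, 3]))

  # worked-example parameters: subject with all levels 0 in cluster 3
  stw <- st1
  phi_rows <- do.call(rbind, lapply(pop$phi, function(m) t(m)))
  # stack phi for cluster 3 into the state layout
  stw$phi[, 3] <- unlist(lapply(pop$phi, function(m) m[3, ]))
  expect_equal(subject_likelihood(rep(0L, 6), 3, stw, prep),
               0.29 * 0.29 * 0.8 * 0.8 * 0.8 * 0.8)
})

test_that("allocation update follows psi when likelihoods are flat", {
  pop <- illustration_population()
  d <- sample_population(pop, 400, seed = 2)
  ms <- make_state(d, dp_options(trunc_init = 4, trunc_max = 4, k_init = 4))
  st <- ms$state; prep <- ms$prep
  # identical phi across clusters, all switches on -> allocation ~ psi
  st$gamma[] <- 1L
  st$phi <- matrix(st$phi[, 1], prep$L, st$C)
  st$psi <- c(0.5, 0.3, 0.15, 0.05)
  st$V <- c(0.5, 0.6, 0.75, 1)  # consistent sticks
  set.seed(3)
  zs <- unlist(lapply(1:40, function(i) update_allocations(st, prep)$z))
  freq <- as.numeric(table(factor(zs, 1:4))) / length(zs)
  expect_equal(freq, st$psi, tolerance = 0.02)

  # degenerate weights: everyone lands in cluster 1
  st$psi <- c(1, 0, 0, 0)
  expect_true(all(update_allocations(st, prep)$z == 1))
})

test_that("allocation frequencies match exact enumeration on a tiny problem", {
  # 1 subject, 1 binary covariate, 2 clusters with known parameters:
  # P(z = c) proportional to psi_c * phi_c(x)
  d <- tibble::tibble(x1 = c(0L, 1L))
  ms <- make_state(d, dp_options(trunc_init = 2, trunc_max = 2, k_init = 2))
  st <- ms$state; prep <- ms$prep
  st$gamma[] <- 1L
  st$phi[, 1] <- c(0.9, 0.1)
  st$phi[, 2] <- c(0.3, 0.7)
  st$psi <- c(0.6, 0.4)
  exact_subj1 <- c(0.6 * 0.9, 0.4 * 0.3)
  exact_subj1 <- exact_subj1 / sum(exact_subj1)
  set.seed(4)
  z1 <- replicate(4000, update_allocations(st, prep)$z[1])
  expect_equal(mean(z1 == 1), exact_subj1[1], tolerance = 0.025)
})

test_that("phi update draws from the correct Dirichlet conditionals", {
  # cluster 1 holds ten zeros, cluster 2 the two ones, cluster 3 is empty
  d <- tibble::tibble(x1 = rep(c(0L, 1L), c(10, 2)))
  ms <- make_state(d, dp_options(trunc_init = 3, trunc_max = 3, k_init = 1,
                                 lambda = 0.5))
  st <- ms$state; prep <- ms$prep
  st$z <- rep(c(1L, 2L), c(10, 2))
  st$gamma[] <- 1L
  set.seed(5)
  draws <- replicate(4000, update_phi(st, prep)$phi[1, ])
  # occupied cluster with level counts (10, 0), lambda = 0.5 -> mean 10.5 / 11
  expect_equal(mean(draws[1, ]), 10.5 / 11, tolerance = 0.01)
  # empty cluster -> prior mean 0.5
  expect_equal(mean(draws[3, ]), 0.5, tolerance = 0.02)

  # switched off: prior draw regardless of data
  st0 <- st; st0$gamma[] <- 0L
  set.seed(6)
  draws0 <- replicate(4000, update_phi(st0, prep)$phi[1, 1])
  expect_equal(mean(draws0), 0.5, tolerance = 0.02)
})

test_that("switch update reduces to the prior when phi equals the marginal", {
  d <- tibble::tibble(x1 = rep(0:1, each = 20))
  ms <- make_state(d, dp_options(trunc_init = 2, trunc_max = 2, k_init = 2))
  st <- ms$state; prep <- ms$prep
  st$phi[] <- 0.5  # equals pi on every level
  st$rho <- 0.3
  set.seed(7)
  g <- replicate(4000, update_gamma(st, prep)$gamma[1, 1])
  expect_equal(mean(g), 0.3, tolerance = 0.025)

  st$rho <- 0
  expect_true(all(update_gamma(st, prep)$gamma == 0L))
})

test_that("selection-probability update uses occupied-cluster conjugacy", {
  d <- tibble::tibble(x1 = rep(0:1, each = 10))
  ms <- make_state(d, dp_options(trunc_init = 6, trunc_max = 6, k_init = 5))
  st <- ms$state; prep <- ms$prep
  st$z <- rep(1:5, each = 4)  # clusters 1..5 occupied, 6 empty
  st$gamma[] <- 1L
  set.seed(8)
  rhos <- replicate(4000, update_rho(st, prep)$rho[1])
  # Beta(1 + 5, 1 + 0): mean 6/7
  expect_equal(mean(rhos), 6 / 7, tolerance = 0.01)
  expect_equal(stats::sd(rhos), sqrt(6 / (7^2 * 8)), tolerance = 0.05)

  # all switches off: two-term Bayes formula for P(w = 1)
  st$gamma[] <- 0L
  st$z <- rep(1:3, length.out = 20)  # 3 occupied clusters
  m1 <- exp(lbeta(1, 1 + 3) - lbeta(1, 1))
  p1_exact <- m1 / (1 + m1)
  set.seed(9)
  ws <- replicate(4000, update_rho(st, prep)$w[1])
  expect_lt(abs(mean(ws) - p1_exact), 0.025)
  # and the point mass really pins rho at zero
  st_w0 <- update_rho(st, prep)
  expect_true(all(st_w0$rho[st_w0$w == 0] == 0))
})

test_that("stick updates follow Beta conjugacy and alpha its Gamma update", {
  d <- tibble::tibble(x1 = rep(0:1, each = 25))
  opts <- dp_options(trunc_init = 3, trunc_max = 3, k_init = 1,
                     alpha_fixed = 2)
  ms <- make_state(d, opts)
  st <- ms$state; prep <- ms$prep
  st$z <- rep(1L, 50)
  set.seed(10)
  v1 <- replicate(3000, update_sticks_alpha(st, prep)$V[1])
  expect_equal(mean(v1), 51 / 53, tolerance = 0.005)  # Beta(1+50, 2+0)

  # with no data-free sticks the last stick is one and psi sums to one
  st2 <- update_sticks_alpha(st, prep)
  expect_equal(st2$V[st2$C], 1)
  expect_equal(sum(st2$psi), 1)
  expect_equal(sum(st2$psi), 1 - prod(1 - st2$V))

  # conjugate Gamma update for alpha given the sticks
  opts2 <- dp_options(trunc_init = 3, trunc_max = 3, k_init = 1,
                      alpha_shape = 2, alpha_rate = 1)
  ms2 <- make_state(d, opts2)
  stf <- ms2$state
  stf$z <- rep(1L, 50)
  set.seed(11)
  alphas <- vapply(1:3000, function(i) {
    update_sticks_alpha(stf, ms2$prep)$alpha
  }, 0)
  # average the exact conditional mean over the stick draws by rerunning
  set.seed(11)
  means <- vapply(1:3000, function(i) {
    s <- update_sticks_alpha(stf, ms2$prep)
    (2 + s$C - 1) / (1 - sum(log1p(-s$V[-s$C])))
  }, 0)
  expect_equal(mean(alphas), mean(means), tolerance = 0.05)
})

test_that("stick weights satisfy the truncation identity for any sticks", {
  set.seed(12)
  for (rep in 1:10) {
    V <- runif(8)
    psi <- catdep:::sticks_to_psi(V)
    expect_true(all(psi >= 0 & psi <= 1))
    expect_equal(sum(psi), 1 - prod(1 - V))
  }
})

test_that("chains are reproducible and respect their dimensions", {
  pop <- illustration_population()
  d <- sample_population(pop, 120, seed = 13)
  ch1 <- dp_cluster(d, burnin = 30, iter = 60, seed = 14)
  ch2 <- dp_cluster(d, burnin = 30, iter = 60, seed = 14)
  expect_identical(ch1$z, ch2$z)
  expect_identical(ch1$rho, ch2$rho)
  expect_identical(ch1$snapshots, ch2$snapshots)
  expect_equal(dim(ch1$z), c(60, 120))
  # cluster sizes in every snapshot account for every subject
  expect_true(all(vapply(ch1$snapshots, function(s) sum(s$sizes), 0) == 120))
  # thinning keeps the requested number of iterations
  ch3 <- dp_cluster(d, burnin = 10, iter = 20, thin = 3, seed = 15)
  expect_equal(nrow(ch3$z), 20)
  expect_error(dp_cluster(d, burnin = -1, iter = 10), "chain lengths")
})

test_that("a duplicated covariate earns a near-identical selection profile", {
  pop <- illustration_population()
  d <- sample_population(pop, 600, seed = 16)
  d2 <- dplyr::select(d, x1, x3, x5)
  d2$x1copy <- d2$x1
  ch <- dp_cluster(d2, burnin = 200, iter = 400, seed = 17)
  med <- rho_medians(ch)
  expect_lt(abs(med[["x1"]] - med[["x1copy"]]), 0.15)
  expect_gt(mean(ch$rho[, "x1"] > 0), 0.9)
})
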