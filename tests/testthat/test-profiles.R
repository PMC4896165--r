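test_that("similarity fractions are exact for hand-built chains", {
  # single iteration, everyone together
  ch <- fake_chain(z = matrix(1L, 1, 3),
                   gammas = list(matrix(1L, 2, 1)))
  expect_true(all(similarity(ch) == 1))

  # two iterations, disjoint pairings -> entries in {0, 0.5, 1}
  z <- rbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  ch2 <- fake_chain(z = z, gammas = list(matrix(1L, 2, 2), matrix(1L, 2, 2)))
  S <- similarity(ch2)
  expect_true(all(S %in% c(0, 0.5, 1)))
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[1, 4], 0)
  expect_equal(diag(S), rep(1, 4))

  # three subjects, hand-tallied fractions over three iterations
  z3 <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L), c(1L, 1L, 1L))
  ch3 <- fake_chain(z = z3, gammas = rep(list(matrix(1L, 2, 2)), 3))
  S3 <- similarity(ch3)
  expect_equal(S3[1, 2], 2 / 3)
  expect_equal(S3[1, 3], 1 / 3)
  expect_equal(S3[2, 3], 2 / 3)
})

test_that("representative partition recovers block structure", {
  # two perfect blocks: exact recovery at zero criterion
  g_true <- rep(1:2, each = 5)
  S <- outer(g_true, g_true, "==") * 1
  part <- representative_partition(S, 1:4)
  expect_equal(part$criterion, 0)
  expect_equal(ari(part$cluster, g_true), 1)

  # all ones: a single cluster
  S1 <- matrix(1, 6, 6)
  expect_equal(representative_partition(S1, 1:3)$k, 1)

  # noisy three-block similarity: near-perfect recovery
  set.seed(21)
  g3 <- rep(1:3, each = 20)
  B <- outer(g3, g3, "==") * 1
  flip <- matrix(runif(60 * 60) < 0.1, 60, 60)
  flip[lower.tri(flip)] <- t(flip)[lower.tri(flip)]
  S3 <- abs(B - flip)
  diag(S3) <- 1
  part3 <- representative_partition(S3, 1:6)
  expect_gte(ari(part3$cluster, g3), 0.9)
})

test_that("profile symbols reflect the switch structure", {
  spec <- factor_spec(c("x1", "x2"), 2)
  # covariate 2 switched off in every iteration -> its symbols are all '0'
  phis <- lapply(1:5, function(t) {
    m <- matrix(0.5, 4, 2)
    m[1:2, 1] <- c(0.9, 0.1); m[1:2, 2] <- c(0.1, 0.9)
    m
  })
  gammas <- lapply(1:5, function(t) rbind(c(1L, 1L), c(0L, 0L)))
  z <- matrix(rep(rep(1:2, each = 4), 5), 5, 8, byrow = TRUE)
  ch <- fake_chain(z = z, gammas = gammas, phis = phis, spec = spec,
                   pi = c(0.5, 0.5, 0.5, 0.5))
  prof <- summarize_profiles(ch, rep(1:2, each = 4))
  x2 <- dplyr::filter(prof, covariate == "x2")
  expect_true(all(x2$symbol == "0"))
  expect_true(all(x2$estimate == 0))
  x1c1 <- dplyr::filter(prof, covariate == "x1", cluster == 1)
  expect_equal(x1c1$symbol, c(">", "<"))

  # single iteration: degenerate interval at the point difference
  ch1 <- fake_chain(z = z[1, , drop = FALSE], gammas = gammas[1],
                    phis = phis[1], spec = spec, pi = rep(0.5, 4))
  prof1 <- summarize_profiles(ch1, rep(1:2, each = 4))
  expect_equal(prof1$conf.low, prof1$conf.high)
  expect_equal(prof1$conf.low, prof1$estimate)
})

test_that("profile symbols are invariant to chain cluster relabelling", {
  spec <- factor_spec(c("x1", "x2"), 2)
  phis <- lapply(1:4, function(t) {
    m <- matrix(0.5, 4, 2)
    m[1:2, 1] <- c(0.85, 0.15); m[1:2, 2] <- c(0.2, 0.8)
    m[3:4, 1] <- c(0.3, 0.7); m[3:4, 2] <- c(0.7, 0.3)
    m
  })
  gammas <- lapply(1:4, function(t) matrix(1L, 2, 2))
  z <- matrix(rep(rep(1:2, each = 3), 4), 4, 6, byrow = TRUE)
  ch <- fake_chain(z = z, gammas = gammas, phis = phis, spec = spec,
                   pi = rep(0.5, 4))
  prof <- summarize_profiles(ch, rep(1:2, each = 3))

  # relabel clusters 1 <-> 2 in every iteration (and swap phi columns)
  z_swap <- 3L - z
  phis_swap <- lapply(phis, function(m) m[, 2:1])
  ch_swap <- fake_chain(z = z_swap, gammas = gammas, phis = phis_swap,
                        spec = spec, pi = rep(0.5, 4))
  prof_swap <- summarize_profiles(ch_swap, rep(1:2, each = 3))
  expect_identical(prof$symbol, prof_swap$symbol)
  expect_equal(prof$estimate, prof_swap$estimate)
})

test_that("profile layout mirrors the published table format", {
  pop <- illustration_population()
  d <- sample_population(pop, 150, seed = 22)
  ch <- dp_cluster(d, burnin = 40, iter = 80, seed = 23)
  part <- representative_partition(similarity(ch), 1:5)
  prof <- summarize_profiles(ch, part)
  codes <- profile_codes(prof)
  expect_true(all(paste0("x", 1:6) %in% names(codes)))
  # first row carries the rho medians, then one row per cluster
  expect_equal(nrow(codes), part$k + 1)
  expect_true(all(nchar(unlist(codes[-1, -(1:2)])) == 3))
})
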