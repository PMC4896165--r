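spec2 <- factor_spec(LETTERS[1:2], 2)

test_that("design matrices have the right shape, rank and coding", {
  # saturated model on one binary factor: 2 x 2, full rank
  d1 <- build_design(llgraph("A"), factor_spec("A", 2))
  expect_equal(dim(d1$X), c(2, 2))
  expect_equal(qr(d1$X)$rank, 2)
  expect_true(all(d1$X[, 1] == 1))

  # two binary factors joined by an edge: 4 columns, full rank
  d <- build_design(parse_model("AB", LETTERS[1:2]), spec2)
  expect_equal(ncol(d$X), 4)
  expect_equal(qr(d$X)$rank, 4)
  # sum-to-zero coding: every non-intercept column sums to zero
  expect_true(all(abs(colSums(d$X[, -1, drop = FALSE])) < 1e-12))
})

test_that("saturated designs are square and full rank for mixed level counts", {
  set.seed(3)
  for (rep in 1:5) {
    P <- sample(2:4, 1)
    spec <- factor_spec(LETTERS[1:P], sample(2:4, P, replace = TRUE))
    g <- llgraph(LETTERS[1:P], t(combn(P, 2)))
    X <- build_design(g, spec)$X
    expect_equal(nrow(X), count_cells(spec))
    expect_equal(ncol(X), count_cells(spec))
    expect_equal(qr(X)$rank, ncol(X))
  }
})

test_that("term blocks are ordered by size then lexicographically", {
  d <- build_design(parse_model("ABC", LETTERS[1:3]), factor_spec(LETTERS[1:3], 2))
  expect_identical(names(d$term_cols),
                   c("(Intercept)", "A", "B", "C", "A:B", "A:C", "B:C", "A:B:C"))
})

test_that("cell order puts the last factor fastest", {
  g <- cell_grid(factor_spec(c("A", "B"), c(2, 3)))
  expect_equal(g$B, rep(0:2, 2))
  expect_equal(g$A, rep(0:1, each = 3))
})

test_that("Poisson log-likelihood matches direct evaluation and an optimizer", {
  # all counts zero at beta = 0: each cell contributes -1
  d <- build_design(llgraph(LETTERS[1:2]), spec2)
  expect_equal(log_likelihood(numeric(3), rep(0, 4), d), -4)
  # one cell, eta = 0, y = 1
  expect_equal(log_likelihood(0, 1, matrix(1, 1, 1)), -1)
  expect_error(log_likelihood(c(0, Inf, 0), rep(0, 4), d), "finite")

  # 2x2 table under the saturated model: value at the MLE equals the
  # closed-form saturated likelihood, and an independent optimizer agrees
  y <- c(1, 2, 3, 4)
  ds <- build_design(parse_model("AB", LETTERS[1:2]), spec2)
  closed <- sum(y * log(y) - y - lgamma(y + 1))
  opt <- optim(numeric(4), function(b) -log_likelihood(b, y, ds),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_equal(-opt$value, closed, tolerance = 1e-6)

  # concavity: numerical Hessian negative definite at random points
  set.seed(11)
  for (rep in 1:5) {
    b <- rnorm(4, sd = 0.5)
    eps <- 1e-4
    H <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      bpp <- b; bpp[i] <- bpp[i] + eps; bpp[j] <- bpp[j] + eps
      bpm <- b; bpm[i] <- bpm[i] + eps; bpm[j] <- bpm[j] - eps
      bmp <- b; bmp[i] <- bmp[i] - eps; bmp[j] <- bmp[j] + eps
      bmm <- b; bmm[i] <- bmm[i] - eps; bmm[j] <- bmm[j] - eps
      H[i, j] <- (log_likelihood(bpp, y, ds) - log_likelihood(bpm, y, ds) -
                    log_likelihood(bmp, y, ds) + log_likelihood(bmm, y, ds)) /
        (4 * eps^2)
    }
    expect_true(all(eigen(0.5 * (H + t(H)))$values < 0))
  }
})

test_that("unit-information prior is a proper multivariate normal", {
  d <- build_design(llgraph(LETTERS[1:2]), spec2)
  n <- 50
  # at beta = 0 only the normalizing constant remains
  G <- crossprod(d$X)
  const <- -ncol(d$X) / 2 * log(2 * pi) -
    0.5 * as.numeric(determinant(n * solve(G))$modulus)
  expect_equal(log_prior(numeric(3), d, n), const)

  # scalar case: intercept-only column over m cells has variance n/m
  X1 <- matrix(1, 4, 1)
  expect_equal(log_prior(0.3, X1, n), dnorm(0.3, 0, sqrt(n / 4), log = TRUE))

  # a 2-parameter prior integrates to 1 by quadrature
  d1 <- build_design(llgraph("A"), factor_spec("A", 2))
  h <- 0.25
  grid <- seq(-40, 40, by = h)
  dens <- outer(grid, grid, Vectorize(function(b0, b1)
    exp(log_prior(c(b0, b1), d1, 10))))
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-3)

  # rank-deficient design is rejected
  Xbad <- cbind(1, c(1, 1, -1, -1), c(2, 2, -2, -2))
  expect_error(log_prior(numeric(3), Xbad, n), "rank deficient")
})
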