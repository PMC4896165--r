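# evidence matrix from values in unordered-pair order AB, AC, AD, BC, BD, CD
tg4 <- function(vals) {
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m[t(combn(4, 2))] <- vals
  m <- m + t(m)
  diag(m) <- NA
  catdep:::new_tgamma(m)
}

test_that("informed addition probabilities normalize the open-pair evidence", {
  # pairs in order AB, AC, AD, BC, BD, CD
  tg <- tg4(c(0.8, 0.4, 0, 0.2, 0.1, 0.5))
  g <- llgraph(LETTERS[1:4])
  d <- edge_add_distribution(tg, g)
  expect_equal(d$prob, c(0.8, 0.4, 0, 0.2, 0.1, 0.5) / 2)
  expect_equal(sum(d$prob), 1)
  # a zero-evidence pair is never proposed
  expect_equal(d$prob[d$from == "A" & d$to == "D"], 0)

  # constant evidence reduces to the uniform choice
  du <- edge_add_distribution(tg4(rep(0.7, 6)), g)
  expect_true(all(abs(du$prob - 1 / 6) < 1e-12))

  # with an edge present, only open pairs are considered
  g2 <- add_edge(g, c(1L, 2L))
  d2 <- edge_add_distribution(tg, g2)
  expect_equal(nrow(d2), 5)
  expect_equal(sum(d2$prob), 1)
  expect_equal(d2$prob[d2$from == "C" & d2$to == "D"], 0.5 / 1.2)
})

test_that("removal uses complementary probabilities with uniform fallbacks", {
  tg <- tg4(c(0.9, 0.1, 0, 0, 0, 0))
  g <- llgraph(LETTERS[1:4], rbind(c(1L, 2L), c(1L, 3L)))
  d <- edge_remove_distribution(tg, g)
  # s = (0.9, 0.1) -> removal proportional to (0.1, 0.9)
  expect_equal(d$prob, c(0.1, 0.9))

  # equal evidence: uniform removal
  de <- edge_remove_distribution(tg4(rep(0.5, 6)), g)
  expect_equal(de$prob, c(0.5, 0.5))

  # single edge: probability one
  g1 <- llgraph(LETTERS[1:4], rbind(c(2L, 3L)))
  expect_equal(edge_remove_distribution(tg, g1)$prob, 1)
})

test_that("proposals follow the strategy move mix", {
  spec <- factor_spec(LETTERS[1:3], 2)
  sim <- sample_loglinear(parse_model("AB+C", LETTERS[1:3]), spec, 400,
                          seed = 41)
  tgu <- tg4(rep(0.5, 6))
  tgu3 <- catdep:::new_tgamma(unclass(tgu)[1:3, 1:3])
  eng <- rj_engine(sim$table)
  st <- rj_state(eng)
  set.seed(42)
  types <- replicate(3000, propose_move(st, "a")$type)
  expect_lt(abs(mean(types == "parameter") - 0.6), 0.03)
  for (tp in c("add", "remove", "swap")) {
    expect_lt(abs(mean(types == tp) - 0.4 / 3), 0.025)
  }

  # an impossible move is flagged and never accepted
  set.seed(43)
  rem <- NULL
  while (is.null(rem) || rem$type != "remove") rem <- propose_move(st, "a")
  expect_false(rem$possible)
  expect_equal(rem$log_ratio, -Inf)
  expect_equal(acceptance_log_ratio(rem, st), -Inf)

  # strategy (c): informed edge choice in about 10% of all iterations
  rj <- rj_search(sim$table, "c", tgamma = tgu3, iters = 6000, burnin = 500,
                  seed = 44)
  expect_lt(abs(mean(rj$informed) - 0.10), 0.015)
})

test_that("informed proposals with flat evidence behave like uniform ones", {
  # analytically: the mixture density collapses to the uniform density
  tg <- tg4(rep(0.3, 6))
  g <- llgraph(LETTERS[1:4], rbind(c(1L, 2L)))
  expect_true(all(abs(edge_add_distribution(tg, g)$prob - 1 / 5) < 1e-12))
  expect_equal(edge_remove_distribution(tg, g)$prob, 1)

  # statistically: first-hit iterations of (a) and (b with flat evidence)
  # are indistinguishable
  spec <- factor_spec(LETTERS[1:4], 2)
  sim <- sample_loglinear(parse_model("AB+CD", LETTERS[1:4]), spec, 800,
                          seed = 45)
  tgu <- tg4(rep(0.5, 6))
  fh <- vapply(1:8, function(s) {
    c(rj_search(sim$table, "a", iters = 1500, burnin = 300,
                seed = 500 + s)$first_hit,
      rj_search(sim$table, "b", tgamma = tgu, iters = 1500, burnin = 300,
                seed = 600 + s)$first_hit)
  }, numeric(2))
  expect_gt(stats::wilcox.test(fh[1, ], fh[2, ], exact = FALSE)$p.value, 0.01)
})

test_that("chains are reproducible and their bookkeeping adds up", {
  spec <- factor_spec(LETTERS[1:3], 2)
  sim <- sample_loglinear(parse_model("AB+C", LETTERS[1:3]), spec, 400,
                          seed = 46)
  r1 <- rj_search(sim$table, "a", iters = 2000, burnin = 200, seed = 47)
  r2 <- rj_search(sim$table, "a", iters = 2000, burnin = 200, seed = 47)
  expect_identical(r1$model_id, r2$model_id)
  expect_identical(r1$models, r2$models)
  expect_equal(sum(r1$models$visits), 2000 - 200)
  expect_equal(sum(r1$models$posterior), 1)
  # the first-hit iteration really is the first visit to the model with the
  # highest post-burn-in frequency
  bid <- r1$model_id[r1$first_hit]
  freq <- tabulate(r1$model_id[(r1$burnin + 1):r1$iters],
                   length(r1$model_key))
  expect_equal(bid, which.max(freq))
  expect_true(all(r1$model_id[seq_len(r1$first_hit - 1)] != bid))
  gl <- glance(r1)
  expect_equal(gl$best, r1$best)
})

test_that("detailed balance holds on a two-model space", {
  # single possible edge: the chain alternates between two models, and
  # empirical transition flows must balance
  spec <- factor_spec(LETTERS[1:2], 2)
  sim <- sample_loglinear(parse_model("AB", LETTERS[1:2]), spec, 200,
                          seed = 48)
  r <- rj_search(sim$table, "a", iters = 30000, burnin = 5000, seed = 49)
  ids <- r$model_id
  flows <- table(factor(head(ids, -1), 1:2), factor(ids[-1], 1:2))
  expect_equal(as.numeric(flows[1, 2]), as.numeric(flows[2, 1]),
               tolerance = 0.1)
  # and visit frequencies agree with the enumeration oracle
  en <- enumerate_models(sim$table)
  m <- dplyr::left_join(en, r$models, by = "model")
  m$posterior.y[is.na(m$posterior.y)] <- 0
  expect_lt(tv_dist(m$posterior.x, m$posterior.y), 0.05)
})

test_that("a zero-evidence edge is never proposed under the informed strategy", {
  spec <- factor_spec(LETTERS[1:3], 2)
  sim <- sample_loglinear(parse_model("AB+C", LETTERS[1:3]), spec, 400,
                          seed = 50)
  tg <- matrix(c(NA, 0.9, 0, 0.9, NA, 0.4, 0, 0.4, NA), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tg <- catdep:::new_tgamma(tg)
  r <- rj_search(sim$table, "b", tgamma = tg, iters = 4000, burnin = 400,
                 seed = 51)
  # A-C has zero evidence: no visited model may contain that edge
  expect_false(any(grepl("AC", r$models$model[r$models$visits > 0])))
  expect_false(any(grepl("ABC", r$models$model[r$models$visits > 0])))
})

test_that("informed strategies demand an evidence matrix", {
  spec <- factor_spec(LETTERS[1:2], 2)
  sim <- sample_loglinear(llgraph(LETTERS[1:2]), spec, 100, seed = 52)
  expect_error(rj_search(sim$table, "b", iters = 100, burnin = 10),
               "evidence")
  expect_error(rj_search(sim$table, "z", iters = 100, burnin = 10),
               "strategy")
})
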