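test_that("pair vectorization uses the canonical lower-triangle order", {
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- 1:6
  S <- S + t(S)
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- 1L
  A[3, 4] <- A[4, 3] <- 1L
  v <- vectorize_pairs(S, A)
  expect_length(v$scores, 6)
  expect_equal(sum(v$labels), 2)
  # row-major (i < j) order: (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  expect_equal(v$labels, c(1L, 0L, 0L, 0L, 0L, 1L))
  # symmetric input: transposing changes nothing
  v2 <- vectorize_pairs(t(S), t(A))
  expect_identical(v2, v)
  expect_error(vectorize_pairs(S, matrix(0L, 3, 3)), "mismatch")
})

test_that("PR curves handle perfect, inverted and fully tied rankings", {
  # perfect ranking
  c1 <- pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))
  expect_equal(aupr(c1), 1)
  # the curve passes through precision 1 at recall 1 and ends at prevalence
  expect_true(any(c1$points$recall == 1 & c1$points$precision == 1))
  expect_equal(c1$points$precision[nrow(c1$points)], 0.5)

  # worst ranking: precision at full recall is prevalence
  c2 <- pr_curve(c(0.6, 0.7, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(c2$points$precision[nrow(c2$points)], 0.5)
  expect_equal(aupr(c2), aupr_oracle(c(0.6, 0.7, 0.8, 0.9), c(1, 1, 0, 0)),
               tolerance = 1e-9)

  # all scores tied: a single operating point at (1, prevalence)
  c3 <- pr_curve(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(nrow(c3$points), 1)
  expect_equal(c3$points$recall, 1)
  expect_equal(c3$points$precision, 0.3)
  expect_equal(aupr(c3), 0.3, tolerance = 1e-12)

  expect_error(pr_curve(c(1, 2), c(1, 1)), "negative")
  expect_error(pr_curve(c(1, 2), c(0, 0)), "positive")
})

test_that("closed-form area matches the quadrature oracle on exhaustive small cases", {
  set.seed(81)
  for (rep in 1:60) {
    inst <- random_pr_instance(n_pairs = sample(4:10, 1),
                               n_levels = sample(2:4, 1))
    got <- aupr(pr_curve(inst$scores, inst$labels))
    want <- aupr_oracle(inst$scores, inst$labels)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("AUPR is invariant under strictly monotone score transforms", {
  set.seed(82)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.3)
  a0 <- aupr(pr_curve(scores, labels))
  for (f in list(function(x) 2 * x + 1, function(x) x^3, exp)) {
    expect_equal(aupr(pr_curve(f(scores), labels)), a0, tolerance = 1e-12)
  }
})

test_that("random scores attain prevalence-level AUPR on average", {
  set.seed(83)
  n_pairs <- 50 * 49 / 2
  labels <- c(rep(1, 50), rep(0, n_pairs - 50))
  vals <- replicate(200, aupr(pr_curve(runif(n_pairs), labels)))
  prevalence <- 50 / n_pairs
  expect_lt(abs(mean(vals) - prevalence), 0.01)
})

test_that("baseline correction follows the printed prevalence formula", {
  bc <- baseline_corrected_aupr(0.5, n = 50, m = 50)
  expect_equal(bc$aupr_rand, 2 / 49)
  expect_equal(bc$aupr_bc, (0.5 - 2 / 49) / (1 - 2 / 49))
  expect_equal(baseline_corrected_aupr(2 / 49, 50, 50)$aupr_bc, 0)
  expect_equal(baseline_corrected_aupr(1, 50, 50)$aupr_bc, 1)
  # worse-than-random values stay negative
  expect_lt(baseline_corrected_aupr(0.01, 50, 50)$aupr_bc, 0)
  expect_error(baseline_corrected_aupr(0.5, 50, 0), "baseline")
  expect_error(baseline_corrected_aupr(0.5, 4, 6), "baseline")
  # monotone in the observed value at fixed prevalence
  vals <- vapply(seq(0, 1, 0.1),
                 function(a) baseline_corrected_aupr(a, 50, 50)$aupr_bc,
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("aggregation reports exact per-cell means and SDs", {
  rec <- data.frame(method = rep(c("a", "b"), each = 2),
                    n = 50, k_avg = 2,
                    aupr_obs = c(0.2, 0.4, 0.3, 0.3),
                    aupr_bc = c(0.1, 0.3, 0.2, 0.2))
  s <- aggregate_iterations(rec)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_aupr_obs[s$method == "a"], 0.3)
  expect_equal(s$sd_aupr_obs[s$method == "b"], 0)
  expect_equal(s$n_iterations, c(2L, 2L))
})

test_that("method comparison reproduces the Welch statistic", {
  a <- c(0.2, 0.4); b <- c(0.2, 0.4)
  res <- compare_methods(a, b)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  expect_error(compare_methods(c(1, 1), c(2, 2)), "degenerate")

  # hand-computed Welch statistic for a fixed pair of groups
  g1 <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
          19.6, 19.0, 21.7, 21.4)
  g2 <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
          22.1, 22.9, 30.5, 24.3)
  se <- sqrt(var(g1) / 15 + var(g2) / 15)
  t_hand <- (mean(g1) - mean(g2)) / se
  res2 <- compare_methods(g1, g2)
  expect_equal(res2$t, t_hand, tolerance = 1e-12)
  expect_lt(res2$p_value, 0.05)

  jit <- c(0, 1e-9, -1e-9)
  sep <- compare_methods(c(0, 0, 0) + jit, c(1, 1, 1) + jit)
  expect_lt(sep$p_value, 1e-3)
})

test_that("trend correlation uses midranks and detects monotone trends", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(trend_correlation(x, -x)$rho, -1)
  expect_error(trend_correlation(rep(1, 5), x), "constant")

  # ties via midranks: compare against direct Pearson on midranks
  xt <- c(1, 1, 2, 2, 3, 3)
  yt <- c(2, 1, 4, 3, 5, 6)
  got <- trend_correlation(xt, yt)$rho
  want <- cor(rank(xt), rank(yt))
  expect_equal(got, want, tolerance = 1e-12)

  # null: independent vectors stay near zero
  set.seed(84)
  expect_lt(abs(trend_correlation(runif(1000), runif(1000))$rho), 0.08)
})
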