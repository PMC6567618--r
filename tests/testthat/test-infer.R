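make_table <- function(X, mode = "absolute") {
  # X: samples x species; a global location shift keeps abundances
  # non-negative without changing any correlation or MIC value
  if (min(X) < 0) X <- X - min(X) + 0.01
  abundance_table(t(X), mode = mode)
}

test_that("correlation scores recover linear and monotone relations", {
  x <- c(1, 2, 3, 4, 5, 6)
  tab <- make_table(cbind(x, 2 * x, exp(x)))
  pea <- correlation_scores(tab, "pearson")
  spe <- correlation_scores(tab, "spearman")
  expect_equal(pea$S[1, 2], 1)
  expect_equal(spe$S[1, 3], 1)
  expect_lt(pea$S[1, 3], 1)

  # hand-computed Spearman on a 4-sample toy pair
  tab2 <- make_table(cbind(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_equal(correlation_scores(tab2, "spearman")$S[1, 2], 0.8)
})

test_that("zero-variance species score zero with a warning", {
  X <- cbind(c(1, 2, 3, 4), c(0, 0, 0, 0), c(4, 3, 1, 2))
  expect_warning(sm <- correlation_scores(make_table(X), "pearson"),
                 "zero-variance")
  expect_equal(sm$S[2, ], c(0, 0, 0))
  expect_equal(sm$S[, 2], c(0, 0, 0))
  expect_gt(sm$S[1, 3], 0)
})

test_that("partial correlations expose conditional structure", {
  set.seed(51)
  n <- 400
  x <- rnorm(n); y <- rnorm(n); z <- x + y + rnorm(n, sd = 0.05)
  sm <- partial_correlation_scores(make_table(cbind(x, y, z)),
                                   "partial_pearson")
  expect_lt(abs(cor(x, y)), 0.2)   # marginally near-independent
  expect_gt(sm$S[1, 2], 0.9)       # strongly dependent given z

  # two variables: partial equals plain correlation
  tab2 <- make_table(cbind(x, x + rnorm(n)))
  expect_equal(partial_correlation_scores(tab2, "partial_pearson")$S[1, 2],
               correlation_scores(tab2, "pearson")$S[1, 2],
               tolerance = 1e-12)

  # independent variables: all partial correlations near zero
  sm0 <- partial_correlation_scores(
    make_table(matrix(rnorm(5 * n), n, 5)), "partial_pearson")
  expect_lt(max(sm0$S), 0.2)
})

test_that("rank-deficient designs fall back to the pseudoinverse with warning", {
  set.seed(52)
  X <- matrix(rnorm(10 * 20), 10, 20) # fewer samples than species
  expect_warning(sm <- partial_correlation_scores(make_table(X),
                                                  "partial_pearson"),
                 "pseudoinverse")
  expect_true(all(is.finite(sm$S)))
  expect_true(all(sm$S >= 0 & sm$S <= 1))
})

test_that("MIC detects functional relations and stays calibrated under the null", {
  set.seed(53)
  x <- runif(300)
  tab <- make_table(cbind(x, x, sin(8 * pi * x)))
  sm <- mic_scores(tab)
  expect_equal(sm$S[1, 2], 1)          # identity relation
  expect_gt(sm$S[1, 3], 0.6)           # non-monotone functional relation
  expect_identical(sm$S, t(sm$S))      # symmetry

  # null calibration: independent pairs stay low on average
  null_mics <- replicate(30, {
    coocbench:::.mic_pair_cpp(runif(300), runif(300), 0.6, 15)
  })
  expect_lt(mean(null_mics), 0.3)
})

test_that("clr transform centers, ignores scale and demands a pseudocount for zeros", {
  tab <- abundance_table(matrix(c(0.5, 0.25, 0.25), 3, 1), mode = "relative")
  z <- clr_transform(tab)
  expect_equal(colSums(z), 0, tolerance = 1e-12, ignore_attr = TRUE)

  flat <- abundance_table(matrix(1 / 4, 4, 2), mode = "relative")
  expect_equal(clr_transform(flat), matrix(0, 4, 2), tolerance = 1e-12)

  # scale invariance: clr of c * x equals clr of x
  x <- c(0.1, 0.2, 0.3, 0.4)
  t1 <- abundance_table(matrix(x, 4, 1), mode = "relative")
  t2 <- abundance_table(matrix(3 * x, 4, 1), mode = "absolute")
  expect_equal(clr_transform(t1), clr_transform(t2), tolerance = 1e-12)

  withz <- abundance_table(matrix(c(0, 0.5, 0.5), 3, 1), mode = "relative")
  expect_error(clr_transform(withz), "pseudocount")
  expect_silent(clr_transform(withz, pseudocount = 1e-6))
})

test_that("external score matrices are validated and round-trip stably", {
  set.seed(54)
  S <- matrix(runif(36), 6, 6)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  sm <- score_matrix(S, method = "demo")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sm, path)
  back <- read_scores(path)
  expect_equal(back$S, sm$S, tolerance = 1e-12)

  ext <- external_scores(path)
  expect_identical(ext$method, "external")

  # asymmetric input is rejected
  bad <- S; bad[1, 2] <- bad[1, 2] + 1e-3
  df <- data.frame(id = 1:6, bad)
  colnames(df) <- c("species_id", paste0("sp", 1:6))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(external_scores(path2), "symmetric")

  # identity matrix: all off-diagonal scores zero
  idm <- diag(6)
  df3 <- data.frame(id = 1:6, idm)
  colnames(df3) <- c("species_id", paste0("sp", 1:6))
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df3, path3, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(max(external_scores(path3)$S[lower.tri(idm)]), 0)
})

test_that("score matrices are equivariant under species relabeling", {
  set.seed(55)
  adj <- generate_network(network_spec(12, 2))
  im <- build_interactions(adj, "random")
  ds <- generate_dataset(im, 60)
  perm <- sample(12)
  tabp <- abundance_table(ds$relative$values[perm, ], mode = "relative")
  for (meth in c("pearson", "partial_pearson")) {
    s1 <- suppressWarnings(infer_scores(ds$relative, meth))
    s2 <- suppressWarnings(infer_scores(tabp, meth))
    expect_equal(s2$S, s1$S[perm, perm], tolerance = 1e-10)
  }
})
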