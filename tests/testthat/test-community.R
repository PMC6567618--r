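test_that("interaction matrices obey the sign law of every community type", {
  adj <- generate_network(network_spec(40, 4, seed = 2))
  pairs <- which(upper.tri(adj$A) & adj$A == 1L, arr.ind = TRUE)
  types <- list(random = NULL, mutualistic = NULL, competitive = NULL,
                predator_prey = NULL, mix_mut_comp = 0.3, mix_comp_pp = 0.7)
  for (ty in names(types)) {
    im <- build_interactions(adj, ty, s_max = 0.5, p_C = types[[ty]],
                             seed = 5)
    M <- im$M
    expect_identical(diag(M), rep(-1, 40))
    expect_true(all(M[adj$A == 0L & !diag(40)] == 0))
    a <- M[pairs]; b <- M[pairs[, c(2, 1)]]
    expect_true(all(abs(a) > 0 & abs(a) <= 0.5))
    expect_true(all(abs(b) > 0 & abs(b) <= 0.5))
    if (ty == "mutualistic") expect_true(all(a > 0 & b > 0))
    if (ty == "competitive") expect_true(all(a < 0 & b < 0))
    if (ty == "predator_prey") expect_true(all(a * b < 0))
    if (ty == "mix_mut_comp") expect_true(all(a * b > 0)) # no mixed-sign pairs
    census <- interaction_census(im, adj)
    expect_equal(sum(census), adj$edge_count)
  }
})

test_that("mixture boundaries collapse to the pure community laws", {
  adj <- generate_network(network_spec(100, 8, seed = 3)) # m = 400
  pp0 <- build_interactions(adj, "mix_comp_pp", p_C = 0, seed = 4)
  expect_equal(unname(interaction_census(pp0, adj)["predator_prey"]), 400L)
  comp1 <- build_interactions(adj, "mix_comp_pp", p_C = 1, seed = 4)
  expect_equal(unname(interaction_census(comp1, adj)["competitive"]), 400L)
  mut0 <- build_interactions(adj, "mix_mut_comp", p_C = 0, seed = 4)
  expect_equal(unname(interaction_census(mut0, adj)["mutualistic"]), 400L)

  # distributional equality of magnitudes at the boundary (KS)
  mags_mix <- abs(mut0$M[upper.tri(mut0$M) & adj$A == 1L])
  mut <- build_interactions(adj, "mutualistic", seed = 9)
  mags_pure <- abs(mut$M[upper.tri(mut$M) & adj$A == 1L])
  ks <- suppressWarnings(stats::ks.test(mags_mix, mags_pure))
  expect_gt(ks$p.value, 0.001)
})

test_that("random interactions occur in the 1:1:2 mutualism:competition:predation ratio", {
  # m = 1e4 edges on one large network
  adj <- generate_network(network_spec(200, 100, seed = 6))
  m <- adj$edge_count
  expect_equal(m, 10000L)
  im <- build_interactions(adj, "random", seed = 7)
  census <- interaction_census(im, adj)
  se_quarter <- sqrt(m * 0.25 * 0.75)
  se_half <- sqrt(m * 0.5 * 0.5)
  expect_lt(abs(census["mutualistic"] - m / 4), 3 * se_quarter)
  expect_lt(abs(census["competitive"] - m / 4), 3 * se_quarter)
  expect_lt(abs(census["predator_prey"] - m / 2), 3 * se_half)
})

test_that("mixture proportions follow p_C within binomial error", {
  adj <- generate_network(network_spec(200, 100, seed = 6)) # m = 1e4
  im <- build_interactions(adj, "mix_comp_pp", p_C = 0.5, seed = 8)
  census <- interaction_census(im, adj)
  frac <- census["competitive"] / sum(census)
  expect_lt(abs(frac - 0.5), 0.015) # 3 * sqrt(0.25 / 1e4)
})

test_that("census is invariant to shuffling magnitudes across edges", {
  adj <- generate_network(network_spec(60, 6, seed = 10))
  im <- build_interactions(adj, "random", seed = 11)
  pairs <- which(upper.tri(adj$A) & adj$A == 1L, arr.ind = TRUE)
  perm <- sample(nrow(pairs))
  M2 <- matrix(0, 60, 60); diag(M2) <- -1
  M2[pairs] <- im$M[pairs][perm]
  M2[pairs[, c(2, 1)]] <- im$M[pairs[, c(2, 1)]][perm]
  im2 <- structure(list(M = M2, s_max = 0.5, itype = "random",
                        p_C = NA_real_), class = "interaction_matrix")
  expect_identical(sort(interaction_census(im2, adj)),
                   sort(interaction_census(im, adj)))
})

test_that("expected false-negative ratio matches the closed form and simulation", {
  expect_identical(expected_false_negative_ratio(0.01, 0.5), 0.0004)
  expect_identical(expected_false_negative_ratio(0.5, 0.5), 1)
  expect_error(expected_false_negative_ratio(0.6, 0.5), "exceed")
  expect_error(expected_false_negative_ratio(0, 0.5), "positive")

  # census over >= 1e5 mutualistic edges at s_c = 0.05
  adj <- generate_network(network_spec(500, 400, seed = 12)) # m = 1e5
  im <- build_interactions(adj, "mutualistic", seed = 13)
  pairs <- which(upper.tri(adj$A) & adj$A == 1L, arr.ind = TRUE)
  a <- abs(im$M[pairs]); b <- abs(im$M[pairs[, c(2, 1)]])
  frac <- mean(a < 0.05 & b < 0.05)
  expected <- expected_false_negative_ratio(0.05, 0.5)
  expect_equal(expected, 0.01)
  expect_lt(abs(frac - expected),
            3 * sqrt(expected * (1 - expected) / nrow(pairs)))
})

test_that("p_C validation and interaction-matrix IO behave", {
  adj <- triangle_adjacency()
  expect_error(build_interactions(adj, "mix_comp_pp"), "p_C")
  expect_error(build_interactions(adj, "random", s_max = 0), "s_max")
  im <- build_interactions(adj, "competitive", seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(im, path)
  back <- read_interactions(path)
  expect_equal(back$M, im$M, tolerance = 1e-12)
  expect_identical(back$itype, "competitive")
})
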