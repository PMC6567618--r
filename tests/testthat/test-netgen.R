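test_that("generated networks satisfy structural invariants for every topology", {
  cases <- list(
    list(n = 30, k_avg = 2, topology = "random"),
    list(n = 51, k_avg = 3, topology = "random"),
    list(n = 30, k_avg = 4, topology = "small_world"),
    list(n = 41, k_avg = 6, topology = "small_world"),
    list(n = 30, k_avg = 4, topology = "scale_free"),
    list(n = 60, k_avg = 2, topology = "scale_free"))
  for (cs in cases) {
    spec <- do.call(network_spec, c(cs, list(seed = 7)))
    adj <- generate_network(spec)
    expect_silent(validate_adjacency(adj, spec$m))
    expect_equal(mean(colSums(adj$A)), 2 * spec$m / spec$n)
    # reproducibility: same spec and seed gives a bit-identical matrix
    adj2 <- generate_network(spec)
    expect_identical(adj$A, adj2$A)
  }
})

test_that("Erdos-Renyi networks have exact edge counts and Poisson-like degrees", {
  adj <- generate_er(network_spec(50, 2, seed = 1))
  expect_equal(adj$edge_count, 50L)

  # n = 3, k_avg = 2 admits only the complete triangle
  tri <- generate_er(network_spec(3, 2, seed = 1))
  expect_equal(tri$A, matrix(1L, 3, 3) - diag(3L), ignore_attr = TRUE)

  # impossible average degrees are rejected
  expect_error(network_spec(5, 4.5), "exceed")

  # pooled degrees approach the Poisson property (variance == mean) at
  # large n where the k/(n-1) binomial correction is negligible
  set.seed(42)
  degs <- unlist(lapply(1:300, function(i) {
    colSums(generate_er(network_spec(200, 4))$A)
  }))
  expect_equal(mean(degs), 4, tolerance = 0.01)
  expect_lt(abs(var(degs) / mean(degs) - 1), 0.05)
})

test_that("small-world generator rewires exactly floor(p_ws m + 0.5) lattice edges", {
  # p_ws = 0: pure ring lattice, clustering coefficient 3(k-2)/(4(k-1))
  lat <- generate_sw(network_spec(50, 4, topology = "small_world", p_ws = 0,
                                  seed = 3))
  g <- igraph::graph_from_adjacency_matrix(lat$A, mode = "undirected")
  expect_equal(igraph::transitivity(g, type = "global"), 0.5,
               tolerance = 1e-12)

  # p_ws = 0.05 on m = 100 edges rewires exactly 5
  sw <- generate_sw(network_spec(50, 4, topology = "small_world",
                                 p_ws = 0.05, seed = 3))
  expect_equal(sw$edge_count, 100L)
  removed <- sum(lat$A == 1L & sw$A == 0L) / 2
  expect_equal(removed, 5)

  # odd k_avg is rejected
  expect_error(network_spec(50, 3, topology = "small_world"), "even")

  # p_ws = 1 destroys the lattice clustering down to the random level
  set.seed(9)
  cl_sw1 <- replicate(30, {
    a <- generate_sw(network_spec(50, 4, topology = "small_world", p_ws = 1))
    igraph::transitivity(igraph::graph_from_adjacency_matrix(
      a$A, mode = "undirected"), type = "global")
  })
  cl_er <- replicate(30, {
    a <- generate_er(network_spec(50, 4))
    igraph::transitivity(igraph::graph_from_adjacency_matrix(
      a$A, mode = "undirected"), type = "global")
  })
  expect_lt(abs(mean(cl_sw1) - mean(cl_er)), 0.05)
})

test_that("small-world clustering exceeds the random level at matched size", {
  set.seed(5)
  cl <- replicate(50, {
    sw <- generate_sw(network_spec(100, 8, topology = "small_world",
                                   p_ws = 0.05))
    er <- generate_er(network_spec(100, 8))
    c(igraph::transitivity(igraph::graph_from_adjacency_matrix(
        sw$A, mode = "undirected"), type = "global"),
      igraph::transitivity(igraph::graph_from_adjacency_matrix(
        er$A, mode = "undirected"), type = "global"))
  })
  expect_gt(mean(cl[1, ]), mean(cl[2, ]))
})

test_that("scale-free generator yields simple graphs with a heavy degree tail", {
  adj <- generate_sf(network_spec(10, 2, topology = "scale_free", seed = 4))
  expect_silent(validate_adjacency(adj, 10L))
  expect_true(all(diag(adj$A) == 0L))

  expect_error(network_spec(50, 4, topology = "scale_free", gamma = 2),
               "gamma > 2")

  # heterogeneity: variance-to-mean degree ratio exceeds the paired ER value
  set.seed(12)
  vm <- replicate(20, {
    sf <- generate_sf(network_spec(200, 4, topology = "scale_free"))
    er <- generate_er(network_spec(200, 4))
    c(var(colSums(sf$A)) / mean(colSums(sf$A)),
      var(colSums(er$A)) / mean(colSums(er$A)))
  })
  expect_gt(mean(vm[1, ]), mean(vm[2, ]))

  # maximum-likelihood tail exponent of pooled degrees near the target 2.2
  set.seed(11)
  degs <- unlist(lapply(1:15, function(i) {
    colSums(generate_sf(network_spec(1000, 4, topology = "scale_free"))$A)
  }))
  kmin <- 3
  tail <- degs[degs >= kmin]
  gamma_hat <- 1 + length(tail) / sum(log(tail / (kmin - 0.5)))
  expect_gt(gamma_hat, 2.0)
  expect_lt(gamma_hat, 2.5)
})

test_that("edge lists round-trip through the TSV format", {
  adj <- generate_network(network_spec(25, 4, topology = "scale_free",
                                       seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(adj, path)
  expect_match(readLines(path, n = 1), "^# n=25$")
  back <- read_edges(path)
  expect_identical(back$A, adj$A)
})
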