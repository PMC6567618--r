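#' Specify a ground-truth network
#'
#' Collects and validates the parameters of one of the three network
#' generators: Erdos-Renyi random graphs, Watts-Strogatz small-world graphs,
#' and static-model scale-free graphs. The target edge count is
#' `m = round(n * k_avg / 2)`.
#'
#' @param n number of species (nodes).
#' @param k_avg target average degree; must satisfy `k_avg <= n - 1`. For
#'   `small_world` it must be an even integer (the ring lattice places
#'   `k_avg / 2` neighbours on each side).
#' @param topology one of `"random"`, `"small_world"`, `"scale_free"`.
#' @param p_ws rewiring ratio in `[0, 1]` (small-world only).
#' @param gamma degree-distribution exponent (scale-free only); must exceed 2.
#' @param i0 finite-size correction constant for the scale-free generator;
#'   `NULL` uses the built-in correction (see [generate_sf()]).
#' @param seed optional integer seed; when supplied the generator is
#'   bit-reproducible.
#' @return An object of class `network_spec`.
#' @export
#' @examples
#' network_spec(50, 2)
network_spec <- function(n, k_avg,
                         topology = c("random", "small_world", "scale_free"),
                         p_ws = 0.05, gamma = 2.2, i0 = NULL, seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(.is_count(n), is.numeric(k_avg), length(k_avg) == 1, k_avg > 0)
  m <- round(n * k_avg / 2)
  if (m < 1) stop("n * k_avg / 2 must round to at least one edge")
  if (k_avg > n - 1) stop("k_avg must not exceed n - 1")
  if (topology == "small_world") {
    if (k_avg != round(k_avg) || k_avg %% 2 != 0)
      stop("small_world requires an even integer k_avg")
    if (k_avg >= n) stop("small_world requires k_avg < n")
    if (p_ws < 0 || p_ws > 1) stop("p_ws must lie in [0, 1]")
  }
  if (topology == "scale_free" && gamma <= 2)
    stop("scale_free requires gamma > 2")
  structure(list(n = as.integer(n), k_avg = k_avg, m = as.integer(m),
                 topology = topology, p_ws = p_ws, gamma = gamma, i0 = i0,
                 seed = seed),
            class = "network_spec")
}

.new_adjacency <- function(A) {
  n <- nrow(A)
  dimnames(A) <- NULL
  storage.mode(A) <- "integer"
  structure(list(A = A, n = n, edge_count = as.integer(sum(A) / 2)),
            class = "adjacency")
}

#' Validate an adjacency object
#'
#' Checks the structural invariants every generated network must satisfy:
#' binary entries, symmetry, zero diagonal, and (optionally) an exact edge
#' count.
#'
#' @param adj an `adjacency` object.
#' @param m optional expected edge count.
#' @return `adj`, invisibly; errors on violation.
#' @export
validate_adjacency <- function(adj, m = NULL) {
  stopifnot(inherits(adj, "adjacency"))
  A <- adj$A
  if (!all(A %in% c(0L, 1L))) stop("adjacency entries must be 0/1")
  if (!identical(A, t(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0L)) stop("adjacency diagonal must be zero")
  if (sum(A) %% 2 != 0) stop("corrupt adjacency")
  if (!is.null(m) && sum(A) / 2 != m)
    stop(sprintf("expected %d edges, found %d", m, sum(A) / 2))
  invisible(adj)
}

#' Generate a network from a specification
#'
#' Dispatches on `spec$topology` to [generate_er()], [generate_sw()] or
#' [generate_sf()].
#'
#' @param spec a [network_spec()].
#' @return An `adjacency` object: binary symmetric matrix with zero diagonal
#'   and exactly `spec$m` edges.
#' @export
#' @examples
#' adj <- generate_network(network_spec(20, 4, seed = 1))
#' adj$edge_count
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  switch(spec$topology,
         random = generate_er(spec),
         small_world = generate_sw(spec),
         scale_free = generate_sf(spec))
}

#' Erdos-Renyi random network (G(n, m))
#'
#' Draws exactly `m` distinct edges uniformly at random from all node pairs,
#' so node degrees are approximately Poisson with mean `k_avg`.
#'
#' @inheritParams generate_network
#' @return An `adjacency` object.
#' @export
generate_er <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n; m <- spec$m
  if (m > n * (n - 1) / 2)
    stop("requested edge count exceeds n(n-1)/2")
  .maybe_seed(spec$seed)
  g <- igraph::sample_gnm(n, m, directed = FALSE, loops = FALSE)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  validate_adjacency(.new_adjacency(A), m)
}

#' Watts-Strogatz small-world network
#'
#' Starts from a one-dimensional ring lattice in which every node is joined
#' to its `k_avg / 2` nearest neighbours on each side, then rewires exactly
#' `floor(p_ws * m + 0.5)` randomly chosen edges: one endpoint is kept and
#' the other redrawn uniformly, rejecting self-loops and duplicate edges, so
#' the edge count is preserved.
#'
#' @inheritParams generate_network
#' @return An `adjacency` object.
#' @export
generate_sw <- function(spec) {
  stopifnot(inherits(spec, "network_spec"), spec$topology == "small_world")
  n <- spec$n; k <- spec$k_avg; m <- spec$m
  .maybe_seed(spec$seed)
  A <- matrix(0L, n, n)
  for (d in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i + d - 1L) %% n) + 1L
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  stopifnot(sum(A) / 2 == m)
  n_rewire <- floor(spec$p_ws * m + 0.5)
  if (n_rewire > 0) {
    edges <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
    pick <- sample.int(nrow(edges), n_rewire)
    for (e in pick) {
      a <- edges[e, 1]; b <- edges[e, 2]
      A[a, b] <- A[b, a] <- 0L
      budget <- 100L * m
      repeat {
        b2 <- sample.int(n, 1)
        if (b2 != a && A[a, b2] == 0L) break
        budget <- budget - 1L
        if (budget <= 0L) stop("rewiring retry budget exhausted")
      }
      A[a, b2] <- A[b2, a] <- 1L
    }
  }
  validate_adjacency(.new_adjacency(A), m)
}

#' Static-model scale-free network
#'
#' Samples `m` edges between nodes drawn with probability proportional to the
#' weight `(i + i0 - 1)^(-xi)` with `xi = 1 / (gamma - 1)`, rejecting
#' self-loops and duplicate edges, which yields a degree distribution with
#' power-law tail `P(k) ~ k^-gamma`. When `xi >= 1/sqrt(2)` a finite-size
#' correction constant `i0 = n^(1 - 1/(2 xi)) * (10 * sqrt(2) * (1 - xi))^(1/xi)`
#' suppresses the finite-size cutoff of the tail; otherwise `i0 = 1`.
#' Supply `spec$i0` to override.
#'
#' @inheritParams generate_network
#' @return An `adjacency` object.
#' @export
generate_sf <- function(spec) {
  stopifnot(inherits(spec, "network_spec"), spec$topology == "scale_free")
  n <- spec$n; m <- spec$m; gamma <- spec$gamma
  if (gamma <= 2) stop("scale_free requires gamma > 2")
  if (m > n * (n - 1) / 2)
    stop("requested edge count exceeds n(n-1)/2")
  .maybe_seed(spec$seed)
  xi <- 1 / (gamma - 1)
  i0 <- spec$i0
  if (is.null(i0)) {
    i0 <- if (xi >= 1 / sqrt(2)) {
      n^(1 - 1 / (2 * xi)) * (10 * sqrt(2) * (1 - xi))^(1 / xi)
    } else 1
  }
  w <- (seq_len(n) + i0 - 1)^(-xi)
  A <- matrix(0L, n, n)
  placed <- 0L
  budget <- 100L * m
  while (placed < m) {
    need <- m - placed
    a <- sample.int(n, 2L * need, replace = TRUE, prob = w)
    b <- sample.int(n, 2L * need, replace = TRUE, prob = w)
    for (t in seq_len(2L * need)) {
      if (a[t] == b[t] || A[a[t], b[t]] == 1L) {
        budget <- budget - 1L
        if (budget <= 0L)
          stop("edge rejection budget exhausted; graph too dense for weights")
        next
      }
      A[a[t], b[t]] <- A[b[t], a[t]] <- 1L
      placed <- placed + 1L
      if (placed == m) break
    }
  }
  validate_adjacency(.new_adjacency(A), m)
}

#' Write / read an edge list
#'
#' Two-column TSV of 1-based node indices, one undirected edge per line
#' (`i < j`), preceded by a single `# n=<n>` comment line carrying the
#' dimension.
#'
#' @param adj an `adjacency` object.
#' @param path file path.
#' @return `write_edges` returns `path` invisibly; `read_edges` returns an
#'   `adjacency` object.
#' @export
write_edges <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  edges <- which(upper.tri(adj$A) & adj$A == 1L, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d", adj$n), con)
  write.table(edges, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# n=\\d+$", first)) stop("missing '# n=<n>' header line")
  n <- as.integer(sub("^# n=", "", first))
  A <- matrix(0L, n, n)
  tab <- tryCatch(read.table(path, sep = "\t", comment.char = "#"),
                  error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0) {
    if (any(tab[, 1] < 1 | tab[, 2] > n)) stop("edge index out of range")
    A[cbind(tab[, 1], tab[, 2])] <- 1L
    A[cbind(tab[, 2], tab[, 1])] <- 1L
  }
  validate_adjacency(.new_adjacency(A))
}
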