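#' Build a signed interaction matrix from an adjacency
#'
#' Converts a binary interaction pattern into a signed generalized
#' Lotka-Volterra interaction matrix `M` of one of six community types.
#' Diagonal entries (self-regulation) are fixed at -1; off-diagonal entries
#' are non-zero exactly where the adjacency has an edge, with magnitudes
#' bounded by `s_max`.
#'
#' Sign laws per connected unordered pair (i, j):
#' \describe{
#'   \item{`random`}{`M_ij` and `M_ji` i.i.d. Uniform(-s_max, s_max); for
#'     large edge counts the pair types mutualistic : competitive :
#'     predator-prey occur in the ratio 1:1:2.}
#'   \item{`mutualistic`}{both entries i.i.d. Uniform(0, s_max].}
#'   \item{`competitive`}{both entries i.i.d. Uniform[-s_max, 0).}
#'   \item{`predator_prey`}{entries take opposite signs; which direction is
#'     positive is decided by a fair coin per pair.}
#'   \item{`mix_mut_comp`}{with probability `p_C` the pair is competitive,
#'     otherwise mutualistic (magnitudes always drawn independently).}
#'   \item{`mix_comp_pp`}{with probability `p_C` the pair is competitive,
#'     otherwise predator-prey.}
#' }
#'
#' @param adj an `adjacency` object (see [generate_network()]).
#' @param itype community type; one of `"random"`, `"mutualistic"`,
#'   `"competitive"`, `"predator_prey"`, `"mix_mut_comp"`, `"mix_comp_pp"`.
#' @param s_max interaction-strength bound (> 0).
#' @param p_C competitive fraction in `[0, 1]`; required for the two mixture
#'   types, ignored otherwise.
#' @param seed optional integer seed.
#' @return An object of class `interaction_matrix` with elements `M`
#'   (n x n numeric), `s_max`, `itype`, `p_C`.
#' @export
#' @examples
#' adj <- generate_network(network_spec(10, 2, seed = 1))
#' im <- build_interactions(adj, "competitive", seed = 2)
#' range(im$M[im$M != -1 & im$M != 0])
build_interactions <- function(adj,
                               itype = c("random", "mutualistic",
                                         "competitive", "predator_prey",
                                         "mix_mut_comp", "mix_comp_pp"),
                               s_max = 0.5, p_C = NULL, seed = NULL) {
  itype <- match.arg(itype)
  stopifnot(inherits(adj, "adjacency"))
  if (!is.numeric(s_max) || length(s_max) != 1 || s_max <= 0)
    stop("s_max must be a positive number")
  mixture <- itype %in% c("mix_mut_comp", "mix_comp_pp")
  if (mixture) {
    if (is.null(p_C)) stop("p_C is required for mixture community types")
    if (!is.numeric(p_C) || p_C < 0 || p_C > 1)
      stop("p_C must lie in [0, 1]")
  }
  .maybe_seed(seed)
  n <- adj$n
  pairs <- which(upper.tri(adj$A) & adj$A == 1L, arr.ind = TRUE)
  m <- nrow(pairs)
  M <- matrix(0, n, n)
  # open-interval uniform magnitudes: runif never returns the endpoints, and
  # exact zeros (probability-zero) are rejected to keep |M_ij| > 0 literally
  upos <- function(k) {
    x <- runif(k, 0, s_max)
    while (any(bad <- x == 0)) x[bad] <- runif(sum(bad), 0, s_max)
    x
  }
  usym <- function(k) {
    x <- runif(k, -s_max, s_max)
    while (any(bad <- x == 0)) x[bad] <- runif(sum(bad), -s_max, s_max)
    x
  }
  if (m > 0) {
    ij <- cbind(pairs[, 1], pairs[, 2])
    ji <- cbind(pairs[, 2], pairs[, 1])
    fill <- function(v_ij, v_ji) {
      M[ij] <<- v_ij
      M[ji] <<- v_ji
    }
    switch(itype,
      random = fill(usym(m), usym(m)),
      mutualistic = fill(upos(m), upos(m)),
      competitive = fill(-upos(m), -upos(m)),
      predator_prey = {
        flip <- runif(m) <= 0.5
        s <- ifelse(flip, -1, 1)
        fill(s * upos(m), -s * upos(m))
      },
      mix_mut_comp = {
        comp <- runif(m) <= p_C
        s <- ifelse(comp, -1, 1)
        fill(s * upos(m), s * upos(m))
      },
      mix_comp_pp = {
        comp <- runif(m) <= p_C
        flip <- runif(m) <= 0.5
        s_ij <- ifelse(comp, -1, ifelse(flip, -1, 1))
        s_ji <- ifelse(comp, -1, -s_ij)
        fill(s_ij * upos(m), s_ji * upos(m))
      })
  }
  diag(M) <- -1
  structure(list(M = M, s_max = s_max, itype = itype,
                 p_C = if (mixture) p_C else NA_real_),
            class = "interaction_matrix")
}

#' Census of pairwise interaction types
#'
#' Classifies every connected unordered pair by the signs of `(M_ij, M_ji)`:
#' (+,+) mutualistic, (-,-) competitive, opposite signs predator-prey.
#' The counts sum to the edge count of the adjacency.
#'
#' @param im an `interaction_matrix`.
#' @param adj the `adjacency` object `im` was built from.
#' @return Named integer vector with components `mutualistic`,
#'   `competitive`, `predator_prey`.
#' @export
interaction_census <- function(im, adj) {
  stopifnot(inherits(im, "interaction_matrix"), inherits(adj, "adjacency"))
  if (nrow(im$M) != adj$n) stop("dimension mismatch")
  pairs <- which(upper.tri(adj$A) & adj$A == 1L, arr.ind = TRUE)
  a <- im$M[pairs]
  b <- im$M[pairs[, c(2, 1), drop = FALSE]]
  if (any(a == 0 | b == 0))
    stop("connected pair with zero interaction entry")
  mut <- sum(a > 0 & b > 0)
  comp <- sum(a < 0 & b < 0)
  pp <- sum(a * b < 0)
  c(mutualistic = mut, competitive = comp, predator_prey = pp)
}

#' Expected false-negative edge ratio
#'
#' When both interaction magnitudes of an edge fall below a cutoff `s_c`
#' their effect on the dynamics is negligible and the edge behaves as absent.
#' Because the two magnitudes are independent Uniform(0, s_max] draws, the
#' expected fraction of such false-negative edges is `(s_c / s_max)^2`.
#'
#' @param s_c magnitude cutoff, `0 < s_c <= s_max`.
#' @param s_max interaction-strength bound.
#' @return The expected false-negative ratio (a number in (0, 1]).
#' @export
#' @examples
#' expected_false_negative_ratio(0.01, 0.5) # 4e-04, i.e. 0.04% of edges
expected_false_negative_ratio <- function(s_c, s_max) {
  stopifnot(is.numeric(s_c), is.numeric(s_max), length(s_c) == 1,
            length(s_max) == 1)
  if (s_c <= 0 || s_max <= 0) stop("s_c and s_max must be positive")
  if (s_c > s_max) stop("s_c must not exceed s_max")
  (s_c / s_max)^2
}

#' Write / read an interaction matrix
#'
#' Dense TSV with a header row and first column of 1-based species indices.
#'
#' @param im an `interaction_matrix`.
#' @param path file path.
#' @return `write_interactions` returns `path` invisibly; `read_interactions`
#'   returns an `interaction_matrix` (with `itype = "external"` metadata
#'   preserved from the comment header when present).
#' @export
write_interactions <- function(im, path) {
  stopifnot(inherits(im, "interaction_matrix"))
  n <- nrow(im$M)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# itype=%s s_max=%.15g p_C=%.15g", im$itype, im$s_max,
                     im$p_C), con)
  df <- data.frame(species = seq_len(n), im$M, check.names = FALSE)
  colnames(df) <- c("species", as.character(seq_len(n)))
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  first <- readLines(path, n = 1)
  meta <- list(itype = "random", s_max = NA_real_, p_C = NA_real_)
  if (grepl("^# itype=", first)) {
    toks <- strsplit(sub("^# ", "", first), " ")[[1]]
    kv <- strsplit(toks, "=")
    for (p in kv) meta[[p[1]]] <- p[2]
    meta$s_max <- suppressWarnings(as.numeric(meta$s_max))
    meta$p_C <- suppressWarnings(as.numeric(meta$p_C))
  }
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) stop("interaction matrix must be square")
  structure(list(M = M, s_max = meta$s_max, itype = meta$itype,
                 p_C = meta$p_C),
            class = "interaction_matrix")
}
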