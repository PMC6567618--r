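#' Construct a confidence score matrix
#'
#' Symmetric non-negative matrix of per-pair confidence scores produced by
#' one inference method. For correlation-type methods the scores are
#' absolute correlation coefficients in `[0, 1]`; for stability-selection
#' methods they are edge selection frequencies in `[0, 1]`. The diagonal is
#' ignored by evaluation.
#'
#' @param S symmetric numeric matrix of scores.
#' @param method method identifier.
#' @param score_kind `"abs_correlation"` or `"stability"`.
#' @param params list of method settings used (stored as metadata).
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(S, method,
                         score_kind = c("abs_correlation", "stability"),
                         params = list()) {
  score_kind <- match.arg(score_kind)
  stopifnot(is.matrix(S), is.numeric(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-9) stop("score matrix must be symmetric")
  S <- (S + t(S)) / 2
  off <- S[lower.tri(S)]
  if (any(off < -1e-12)) stop("scores must be non-negative")
  if (any(off > 1 + 1e-9)) stop("scores must not exceed 1")
  S[S < 0] <- 0
  S[S > 1] <- 1
  dimnames(S) <- NULL
  structure(list(S = S, method = method, score_kind = score_kind,
                 params = params),
            class = "score_matrix")
}

# samples x species matrix from an abundance table
.sample_matrix <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  t(tab$values)
}

# indices of zero-variance species, with a single warning
.constant_species <- function(X, method) {
  sds <- apply(X, 2, sd)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const))
    warning(sprintf("%s: %d zero-variance species scored 0 against all partners",
                    method, length(const)), call. = FALSE)
  const
}

#' Pairwise correlation confidence scores
#'
#' Absolute Pearson or Spearman correlation between species abundance
#' profiles. Species with zero variance across samples (e.g. globally
#' extinct) receive score 0 against all partners, with a warning.
#'
#' @param tab an `abundance_table` (absolute or relative).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `score_matrix` of kind `abs_correlation`.
#' @export
correlation_scores <- function(tab, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- .sample_matrix(tab)
  if (nrow(X) < 3) stop("at least 3 samples are required")
  p <- ncol(X)
  const <- .constant_species(X, method)
  S <- matrix(0, p, p)
  ok <- setdiff(seq_len(p), const)
  if (length(ok) >= 2)
    S[ok, ok] <- abs(cor(X[, ok, drop = FALSE], method = method))
  diag(S) <- 0
  score_matrix(S, method = method, score_kind = "abs_correlation")
}

#' Partial correlation confidence scores
#'
#' Absolute full-order partial correlations: for each species pair, the
#' correlation conditioned on all remaining species, computed from the
#' precision matrix `Omega` of the (rank-transformed, for Spearman)
#' correlation matrix as `-Omega_ij / sqrt(Omega_ii * Omega_jj)`. When the
#' correlation matrix is singular (e.g. fewer samples than species) the
#' Moore-Penrose pseudoinverse is used and a warning emitted.
#'
#' @param tab an `abundance_table`.
#' @param method `"partial_pearson"` or `"partial_spearman"`.
#' @return A `score_matrix` of kind `abs_correlation`.
#' @export
partial_correlation_scores <- function(tab,
                                       method = c("partial_pearson",
                                                  "partial_spearman")) {
  method <- match.arg(method)
  X <- .sample_matrix(tab)
  if (nrow(X) < 3) stop("at least 3 samples are required")
  p <- ncol(X)
  const <- .constant_species(X, method)
  ok <- setdiff(seq_len(p), const)
  S <- matrix(0, p, p)
  if (length(ok) >= 2) {
    base <- if (method == "partial_pearson") "pearson" else "spearman"
    R <- cor(X[, ok, drop = FALSE], method = base)
    Om <- if (nrow(X) > length(ok)) {
      tryCatch(solve(R), error = function(e) NULL)
    } else NULL # rank-deficient by construction: fall through to pseudoinverse
    if (is.null(Om)) {
      warning(method, ": singular or ill-posed correlation matrix; ",
              "using pseudoinverse", call. = FALSE)
      Om <- MASS::ginv(R)
    }
    d <- sqrt(diag(Om))
    pc <- -Om / tcrossprod(d)
    pc[!is.finite(pc)] <- 0
    pc <- pmin(pmax(pc, -1), 1)
    S[ok, ok] <- abs(pc)
  }
  diag(S) <- 0
  score_matrix(S, method = method, score_kind = "abs_correlation")
}

#' Maximal information coefficient confidence scores
#'
#' Pairwise MIC (maximal information coefficient) computed with the MINE
#' approximation: grid budget `B = n_samples^alpha`, clump count capped at
#' `c` times the number of x-axis bins, both axis orientations scored.
#' MIC detects general functional (including non-monotone) relationships and
#' equals 1 for any noiseless functional dependence.
#'
#' @param tab an `abundance_table`.
#' @param alpha grid-budget exponent in (0, 1], default 0.6.
#' @param c clump-budget factor (> 0), default 15.
#' @return A `score_matrix` of kind `abs_correlation` (MIC scores lie in
#'   `[0, 1]`).
#' @export
mic_scores <- function(tab, alpha = 0.6, c = 15) {
  stopifnot(alpha > 0, alpha <= 1, c > 0)
  X <- .sample_matrix(tab)
  if (nrow(X) < 4) stop("at least 4 samples are required for MIC")
  const <- .constant_species(X, "mic")
  S <- .mic_matrix_cpp(X, alpha, c)
  if (length(const)) {
    S[const, ] <- 0
    S[, const] <- 0
  }
  diag(S) <- 0
  score_matrix(S, method = "mic", score_kind = "abs_correlation",
               params = list(alpha = alpha, c = c))
}

#' Load externally computed confidence scores
#'
#' Adapter for methods run outside the package (e.g. REBACCA or CCLasso):
#' reads a dense square score matrix from TSV, checks symmetry within 1e-9,
#' and wraps it as a `score_matrix` tagged `"external"`.
#'
#' @param path TSV written by [write_scores()] (header row/column of ids).
#' @param score_kind `"abs_correlation"` or `"stability"`.
#' @return A `score_matrix`.
#' @export
external_scores <- function(path, score_kind = "abs_correlation") {
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE)
  S <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(S) <- NULL
  if (nrow(S) != ncol(S)) stop("external score matrix must be square")
  if (max(abs(S - t(S))) > 1e-9)
    stop("external score matrix must be symmetric within 1e-9")
  diag(S) <- 0
  score_matrix(abs(S), method = "external", score_kind = score_kind)
}

#' Write / read a confidence score matrix
#'
#' Dense TSV with a header row and first column of species identifiers;
#' values are written with 12 significant digits, so a round trip is stable
#' at that precision.
#'
#' @param sm a `score_matrix`.
#' @param path file path.
#' @param species_ids optional identifiers (defaults `sp1..spn`).
#' @return `write_scores` returns `path` invisibly; `read_scores` returns a
#'   `score_matrix`.
#' @export
write_scores <- function(sm, path, species_ids = NULL) {
  stopifnot(inherits(sm, "score_matrix"))
  n <- nrow(sm$S)
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s kind=%s", sm$method, sm$score_kind), con)
  vals <- format(sm$S, digits = 12, trim = TRUE, scientific = TRUE)
  df <- data.frame(species_id = species_ids, vals, check.names = FALSE)
  colnames(df) <- c("species_id", species_ids)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  first <- readLines(path, n = 1)
  method <- "external"; kind <- "abs_correlation"
  if (grepl("^# method=", first)) {
    toks <- strsplit(sub("^# ", "", first), " ")[[1]]
    kv <- strsplit(toks, "=")
    for (p in kv) {
      if (p[1] == "method") method <- p[2]
      if (p[1] == "kind") kind <- p[2]
    }
  }
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE)
  S <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(S) <- NULL
  score_matrix(S, method = method, score_kind = kind)
}
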