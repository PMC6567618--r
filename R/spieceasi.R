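#' Centered log-ratio transform
#'
#' Maps each sample composition to an unconstrained space:
#' `z_ij = log(x_ij + pc) - mean_i log(x_ij + pc)`, so every sample column
#' of the result sums to zero. The transform is invariant to rescaling a
#' sample's composition by a positive constant.
#'
#' @param tab an `abundance_table` (species x samples).
#' @param pseudocount added inside the log; must be positive when the table
#'   contains zeros.
#' @return Species x samples numeric matrix with zero column means.
#' @export
clr_transform <- function(tab, pseudocount = 0) {
  stopifnot(inherits(tab, "abundance_table"), pseudocount >= 0)
  x <- tab$values
  if (pseudocount == 0 && any(x == 0))
    stop("zero entries require a positive pseudocount")
  z <- log(x + pseudocount)
  sweep(z, 2, colMeans(z), "-")
}

#' Neighborhood-selection confidence scores with stability selection
#'
#' SPIEC-EASI-style pipeline: the relative abundances are rescaled to
#' pseudo-counts (known total `100 * n`), shifted by `pseudocount`, and
#' centered-log-ratio transformed; sparse neighborhood selection then
#' regresses each species' clr profile on all others with an L1 penalty
#' along a log-spaced path of `n_lambda` penalties from `lambda_max` (the
#' largest absolute pairwise correlation, above which all neighborhoods are
#' empty) down to `lambda_min_ratio * lambda_max`. An edge is present if
#' either direction selects it (the "or" rule). The penalty is chosen by
#' StARS: over `n_subsamples` random subsamples of
#' `floor(subsample_fraction * n_samples)` samples the path is refit, the
#' total edge-selection instability `mean(2 p (1 - p))` is monotonized from
#' the sparse end, and the densest penalty whose instability stays at or
#' below `beta` is selected. The per-edge selection frequency at the
#' selected penalty is the confidence score.
#'
#' Subsamples are keyed to sample identifiers (sorted before drawing), so
#' permuting the column order of the table does not change the scores for a
#' fixed seed.
#'
#' @param tab an `abundance_table`; relative abundances (absolute input is
#'   normalized internally).
#' @param n_lambda number of penalties on the path (default 20).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @param subsample_fraction fraction of samples per subsample (default 0.8).
#' @param n_subsamples number of subsamples (default 20).
#' @param beta StARS instability threshold (default 0.05).
#' @param pseudocount added to the rescaled counts before the log (default 1).
#' @param seed optional integer seed for the subsampling.
#' @return A `score_matrix` of kind `stability`.
#' @export
spieceasi_mb_scores <- function(tab, n_lambda = 20, lambda_min_ratio = 0.01,
                                subsample_fraction = 0.8, n_subsamples = 20,
                                beta = 0.05, pseudocount = 1, seed = NULL) {
  stopifnot(inherits(tab, "abundance_table"), .is_count(n_lambda),
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            subsample_fraction > 0, subsample_fraction < 1,
            .is_count(n_subsamples), beta > 0, beta < 1, pseudocount > 0)
  vals <- tab$values
  n <- nrow(vals)
  S <- ncol(vals)
  if (tab$mode == "absolute") vals <- sweep(vals, 2, colSums(vals), "/")
  counts <- vals * (100 * n) + pseudocount
  ztab <- abundance_table(counts / rep(colSums(counts), each = n),
                          mode = "relative", species_ids = tab$species_ids,
                          sample_ids = tab$sample_ids)
  Z <- t(clr_transform(ztab, pseudocount = 0)) # samples x species
  Z <- scale(Z)
  Z[, !is.finite(colSums(Z))] <- 0 # constant species contribute nothing
  b <- floor(subsample_fraction * S)
  if (b < 3) stop("too few samples per subsample")
  .maybe_seed(seed)
  ord <- order(tab$sample_ids)
  sub_rows <- lapply(seq_len(n_subsamples), function(i) ord[sample.int(S, b)])

  path <- .mb_lambda_path(Z, n_lambda, lambda_min_ratio)
  counts_sel <- .mb_stars_counts(Z, sub_rows, path)
  widened <- FALSE
  if (.mb_degenerate(counts_sel, n_subsamples)) {
    # widen the path once: extend both ends
    path <- .mb_lambda_path(Z, n_lambda, lambda_min_ratio / 10,
                            lambda_max_factor = 1.5)
    counts_sel <- .mb_stars_counts(Z, sub_rows, path)
    widened <- TRUE
    if (.mb_degenerate(counts_sel, n_subsamples))
      stop("lambda path degenerate (all graphs empty or complete) even ",
           "after widening")
  }
  theta <- lapply(counts_sel, function(cm) cm / n_subsamples)
  D <- vapply(theta, function(th) {
    v <- th[lower.tri(th)]
    mean(2 * v * (1 - v))
  }, numeric(1))
  Dbar <- cummax(D) # path is sparse -> dense
  sel <- which(Dbar <= beta)
  k_star <- if (length(sel)) max(sel) else 1L
  score_matrix(theta[[k_star]], method = "spieceasi_mb",
               score_kind = "stability",
               params = list(lambda = path[k_star], lambda_path = path,
                             beta = beta, n_subsamples = n_subsamples,
                             subsample_fraction = subsample_fraction,
                             instability = D[k_star], widened = widened))
}

.mb_lambda_path <- function(Z, n_lambda, lambda_min_ratio,
                            lambda_max_factor = 1) {
  Cab <- abs(crossprod(Z) / nrow(Z))
  diag(Cab) <- 0
  lmax <- max(Cab) * lambda_max_factor
  if (lmax <= 0) stop("degenerate data: no variation")
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# per-lambda matrices counting in how many subsamples each edge was selected
.mb_stars_counts <- function(Z, sub_rows, path) {
  p <- ncol(Z)
  counts <- lapply(seq_along(path), function(k) matrix(0, p, p))
  for (rows in sub_rows) {
    Zs <- Z[rows, , drop = FALSE]
    sel <- .mb_fit_path(Zs, path)
    for (k in seq_along(path)) counts[[k]] <- counts[[k]] + sel[[k]]
  }
  counts
}

# neighborhood selection on one (sub)sample: list over lambda of 0/1
# adjacency matrices under the "or" symmetrization rule
.mb_fit_path <- function(Zs, path) {
  p <- ncol(Zs)
  nl <- length(path)
  sel <- lapply(seq_len(nl), function(k) matrix(0L, p, p))
  for (j in seq_len(p)) {
    y <- Zs[, j]
    if (sd(y) == 0) next
    fit <- glmnet::glmnet(Zs[, -j, drop = FALSE], y, family = "gaussian",
                          lambda = path, standardize = FALSE,
                          intercept = TRUE)
    B <- as.matrix(fit$beta) # (p-1) x n_fitted
    others <- seq_len(p)[-j]
    for (k in seq_len(min(nl, ncol(B)))) {
      nz <- others[B[, k] != 0]
      if (length(nz)) {
        sel[[k]][nz, j] <- 1L
        sel[[k]][j, nz] <- 1L
      }
    }
  }
  sel
}

.mb_degenerate <- function(counts_sel, n_subsamples) {
  p <- nrow(counts_sel[[1]])
  tot <- vapply(counts_sel, function(cm) sum(cm[lower.tri(cm)]), numeric(1))
  full <- n_subsamples * p * (p - 1) / 2
  all(tot == 0) || all(tot == full)
}
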