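#' SparCC confidence scores
#'
#' Estimates the correlations of the underlying absolute abundances from
#' compositional data under a sparsity assumption. For each Dirichlet-
#' resampled composition: (1) the log-ratio variance matrix
#' `t_ij = Var(log(x_i / x_j))` is computed over samples; (2) the basis
#' variances `w_i` are obtained from the linear system implied by the
#' approximation that most pairs are uncorrelated,
#' `sum_j t_ij = (n - 2) w_i + sum_j w_j`; (3) basis correlations
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))` are formed and clipped
#' to `[-1, 1]`; (4) the most strongly correlated pair above
#' `exclusion_threshold` is iteratively excluded from the system and the
#' basis re-estimated, up to `exclusion_rounds` times. Estimates are
#' averaged over `dirichlet_draws` resampled compositions and the absolute
#' value taken as the confidence score.
#'
#' Relative abundances are rescaled to pseudo-counts by the known total of
#' `100 * n` individuals before Dirichlet resampling, since the resampling
#' is defined on counts; `pseudocount` is added to every count.
#'
#' @param tab an `abundance_table`; relative abundances (absolute input is
#'   normalized internally).
#' @param dirichlet_draws number of Dirichlet resamples averaged (default 20).
#' @param exclusion_rounds maximum strongly-correlated pairs excluded
#'   (default 10).
#' @param exclusion_threshold correlation magnitude above which a pair may be
#'   excluded (default 0.1).
#' @param pseudocount added to the rescaled counts (default 1).
#' @param total_count scale used to convert relative abundances to counts;
#'   default `100 * n`.
#' @param seed optional integer seed for the resampling.
#' @return A `score_matrix` of kind `abs_correlation`.
#' @export
sparcc_scores <- function(tab, dirichlet_draws = 20, exclusion_rounds = 10,
                          exclusion_threshold = 0.1, pseudocount = 1,
                          total_count = NULL, seed = NULL) {
  stopifnot(inherits(tab, "abundance_table"), .is_count(dirichlet_draws),
            exclusion_rounds >= 0, exclusion_threshold > 0, pseudocount >= 0)
  vals <- tab$values
  n <- nrow(vals)
  if (n < 4) stop("SparCC needs at least 4 species (basis system is ",
                  "under-determined otherwise)")
  if (tab$mode == "absolute") vals <- sweep(vals, 2, colSums(vals), "/")
  if (is.null(total_count)) total_count <- 100 * n
  counts <- vals * total_count + pseudocount
  .maybe_seed(seed)
  acc <- matrix(0, n, n)
  for (d in seq_len(dirichlet_draws)) {
    # Dirichlet(counts) draw per sample via normalized gammas
    g <- matrix(rgamma(length(counts), shape = counts), n)
    g <- sweep(g, 2, colSums(g), "/")
    L <- log(g)
    C <- cov(t(L))
    dv <- diag(C)
    tmat <- outer(dv, dv, "+") - 2 * C
    diag(tmat) <- 0
    acc <- acc + .sparcc_basis_cor(tmat, exclusion_rounds,
                                   exclusion_threshold)
  }
  rho <- acc / dirichlet_draws
  S <- abs(rho)
  diag(S) <- 0
  score_matrix(pmin(S, 1), method = "sparcc", score_kind = "abs_correlation",
               params = list(dirichlet_draws = dirichlet_draws,
                             exclusion_rounds = exclusion_rounds,
                             exclusion_threshold = exclusion_threshold,
                             pseudocount = pseudocount))
}

# one basis-correlation estimate from a log-ratio variance matrix,
# with iterative exclusion of strongly correlated pairs
.sparcc_basis_cor <- function(tmat, exclusion_rounds, exclusion_threshold) {
  n <- nrow(tmat)
  Msys <- matrix(1, n, n) + diag(n - 2, n)
  twork <- tmat
  excluded <- matrix(FALSE, n, n)
  solve_basis <- function() {
    w <- solve(Msys, rowSums(twork))
    pmax(w, 1e-10)
  }
  w <- solve_basis()
  rho <- .basis_cor_from_var(w, tmat)
  for (it in seq_len(exclusion_rounds)) {
    cand <- abs(rho)
    cand[lower.tri(cand, diag = TRUE)] <- 0
    cand[excluded] <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    idx <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    # never let a component's effective equation count collapse
    if (Msys[i, i] <= 2 || Msys[j, j] <= 2) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    twork[i, j] <- twork[j, i] <- 0
    Msys[i, j] <- Msys[i, j] - 1
    Msys[j, i] <- Msys[j, i] - 1
    Msys[i, i] <- Msys[i, i] - 1
    Msys[j, j] <- Msys[j, j] - 1
    w <- solve_basis()
    rho <- .basis_cor_from_var(w, tmat)
  }
  rho
}

.basis_cor_from_var <- function(w, tmat) {
  rho <- (outer(w, w, "+") - tmat) / (2 * sqrt(outer(w, w)))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}
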