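#' Vectorize score and truth matrices over species pairs
#'
#' Extracts the strictly-lower-triangle entries of both matrices in the
#' canonical pair order (i < j, row-major: (1,2), (1,3), ..., (1,n), (2,3),
#' ...), excluding the diagonal. Because both matrices are symmetric this
#' loses no information.
#'
#' @param sm a `score_matrix` (or plain symmetric numeric matrix).
#' @param adj an `adjacency` (or plain symmetric 0/1 matrix) of matching
#'   dimension.
#' @return A list with `scores` and `labels`, both of length `n(n-1)/2`.
#' @export
vectorize_pairs <- function(sm, adj) {
  S <- if (inherits(sm, "score_matrix")) sm$S else sm
  A <- if (inherits(adj, "adjacency")) adj$A else adj
  stopifnot(is.matrix(S), is.matrix(A))
  if (!all(dim(S) == dim(A))) stop("dimension mismatch between scores and truth")
  # column-major lower triangle == row-major (i < j) pair order
  list(scores = S[lower.tri(S)], labels = as.integer(A[lower.tri(A)]))
}

#' Precision-recall curve
#'
#' Sweeps the binarization threshold over all distinct confidence scores
#' (descending) and records precision and recall at each. Tied scores enter
#' at a single threshold, so no within-tie ordering can leak the truth.
#'
#' @param scores numeric vector of confidence scores.
#' @param labels 0/1 vector of the same length; at least one positive and
#'   one negative are required.
#' @return An object of class `pr_curve` with `points` (data.frame of
#'   `threshold`, `recall`, `precision`), the cumulative confusion counts
#'   `tp`/`fp`, and `n_pos`, `n_neg`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  P <- sum(labels)
  Ng <- sum(1L - labels)
  if (P == 0L) stop("no positive labels: PR curve undefined")
  if (Ng == 0L) stop("no negative labels: PR curve undefined")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # group boundaries of tied scores
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(l)[last]
  fp <- cumsum(1L - l)[last]
  pts <- data.frame(threshold = s[last], recall = tp / P,
                    precision = tp / (tp + fp))
  structure(list(points = pts, tp = tp, fp = fp, n_pos = P, n_neg = Ng),
            class = "pr_curve")
}

#' Area under the precision-recall curve
#'
#' Integrates precision over recall using the continuous interpolation that
#' is exact in PR space: between adjacent operating points the confusion
#' counts are continued linearly in (TP, FP), giving precision
#' `t / (t + f1 + k (t - t1))` along the segment, whose integral has the
#' closed form used here. (Linear interpolation of precision itself would
#' systematically overestimate the area.) For a perfect ranking the area is
#' 1; for exchangeable random scores its expectation is the prevalence
#' `n_pos / (n_pos + n_neg)`.
#'
#' @param curve a [pr_curve()].
#' @return The area, a number in `[0, 1]`.
#' @export
aupr <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  .aupr_from_counts(curve$tp, curve$fp, curve$n_pos)
}

# closed-form Davis-Goadrich area from cumulative confusion counts,
# starting from the implicit (TP, FP) = (0, 0) operating point
.aupr_from_counts <- function(tp, fp, n_pos) {
  t1 <- c(0, tp[-length(tp)])
  f1 <- c(0, fp[-length(fp)])
  dt <- tp - t1
  df <- fp - f1
  area <- 0
  for (seg in which(dt > 0)) {
    k <- df[seg] / dt[seg]
    A <- 1 + k
    B <- f1[seg] - k * t1[seg]
    a <- t1[seg]; b <- tp[seg]
    # integral of t / (A t + B) dt over [a, b]
    piece <- if (abs(B) < 1e-300) {
      (b - a) / A
    } else {
      (b - a) / A - (B / A^2) * log((A * b + B) / (A * a + B))
    }
    area <- area + piece
  }
  area / n_pos
}

#' Baseline-corrected AUPR
#'
#' A random ranking attains AUPR equal to the edge prevalence
#' `AUPR_rand = 2m / (n (n - 1))` (equivalently `k_avg / (n - 1)`), so raw
#' AUPR values are not comparable across prevalences. The corrected value
#' `(AUPR_obs - AUPR_rand) / (1 - AUPR_rand)` is 0 for random performance
#' and 1 for perfect recovery; values below 0 (worse than random) are
#' preserved, not clipped.
#'
#' @param aupr_obs observed AUPR in `[0, 1]`.
#' @param n number of species.
#' @param m number of true edges, `0 < m < n(n-1)/2`.
#' @return A list with `aupr_obs`, `aupr_rand`, `aupr_bc`.
#' @export
#' @examples
#' baseline_corrected_aupr(0.5, n = 50, m = 50)$aupr_rand # 2/49
baseline_corrected_aupr <- function(aupr_obs, n, m) {
  stopifnot(is.numeric(aupr_obs), length(aupr_obs) == 1)
  if (aupr_obs < 0 || aupr_obs > 1) stop("aupr_obs must lie in [0, 1]")
  stopifnot(.is_count(n), n >= 3)
  if (m <= 0 || m >= n * (n - 1) / 2)
    stop("baseline undefined for m = 0 or a complete graph")
  aupr_rand <- 2 * m / (n * (n - 1))
  list(aupr_obs = aupr_obs, aupr_rand = aupr_rand,
       aupr_bc = (aupr_obs - aupr_rand) / (1 - aupr_rand))
}

#' Score a confidence matrix against the ground truth
#'
#' Convenience wrapper: vectorizes the pair scores, builds the PR curve, and
#' returns the observed, random-baseline and baseline-corrected AUPR.
#'
#' @param sm a `score_matrix`.
#' @param adj the ground-truth `adjacency`.
#' @return A list with `method`, `aupr_obs`, `aupr_rand`, `aupr_bc`, `n`, `m`.
#' @export
evaluate_scores <- function(sm, adj) {
  v <- vectorize_pairs(sm, adj)
  a <- aupr(pr_curve(v$scores, v$labels))
  n <- if (inherits(adj, "adjacency")) adj$n else nrow(adj)
  m <- sum(v$labels)
  bc <- baseline_corrected_aupr(a, n, m)
  c(list(method = if (inherits(sm, "score_matrix")) sm$method else NA_character_),
    bc, list(n = n, m = m))
}

#' Aggregate evaluation records across iterations
#'
#' Per-cell (method x condition) mean and standard deviation of the raw
#' AUPR values; the raw records should be kept for rank-correlation trend
#' tests, which use unaveraged values.
#'
#' @param records data.frame of evaluation records (one row per method x
#'   condition x iteration), as produced by [run_iteration()].
#' @param by character vector of grouping columns; defaults to `method` plus
#'   whichever condition columns are present.
#' @return data.frame with one row per cell: grouping columns,
#'   `mean_aupr_obs`, `sd_aupr_obs`, `mean_aupr_bc`, `sd_aupr_bc`,
#'   `n_iterations`.
#' @export
aggregate_iterations <- function(records, by = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (is.null(by)) {
    cond_cols <- c("method", "n", "k_avg", "topology", "itype", "p_C",
                   "n_samples", "s_max", "mode")
    by <- intersect(cond_cols, names(records))
  }
  if (!length(by)) stop("no grouping columns found")
  keydf <- lapply(records[by], function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ".na" # keep cells with unset condition fields (e.g. p_C)
    x
  })
  key <- interaction(keydf, drop = TRUE)
  cells <- split(records, key)
  out <- do.call(rbind, lapply(cells, function(cell) {
    row <- cell[1, by, drop = FALSE]
    row$mean_aupr_obs <- mean(cell$aupr_obs)
    row$sd_aupr_obs <- sd(cell$aupr_obs)
    row$mean_aupr_bc <- mean(cell$aupr_bc)
    row$sd_aupr_bc <- sd(cell$aupr_bc)
    row$n_iterations <- nrow(cell)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Compare two methods' AUPR distributions
#'
#' Two-sample Welch (unequal-variance) t-test on raw per-iteration AUPR
#' values.
#'
#' @param records_a,records_b numeric vectors of per-iteration AUPR values
#'   (length >= 2 each).
#' @return A list with `t` and `p_value`.
#' @export
compare_methods <- function(records_a, records_b) {
  stopifnot(is.numeric(records_a), is.numeric(records_b),
            length(records_a) >= 2, length(records_b) >= 2)
  if (sd(records_a) == 0 && sd(records_b) == 0)
    stop("degenerate (zero) variance in both groups")
  ht <- t.test(records_a, records_b, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value)
}

#' Rank-correlation trend between a condition and performance
#'
#' Spearman rank correlation between a swept condition value (e.g. average
#' degree, or the predator-prey fraction `1 - p_C`) and the raw
#' (unaveraged) per-iteration baseline-corrected AUPR values. Ties are
#' handled by midranks.
#'
#' @param x condition values (length >= 3, not constant).
#' @param y raw performance values, same length.
#' @return A list with `rho` and `p_value`.
#' @export
trend_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3)
  if (length(unique(x)) < 2) stop("condition values are constant")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Write an evaluation record as JSON
#'
#' @param record list as returned by [evaluate_scores()] (possibly with
#'   extra fields).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_record <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
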