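# Independent oracles used across test files.

# Confusion counts at every distinct threshold, by explicit enumeration
# (independent of pr_curve's cumulative-sum implementation).
pr_points_bruteforce <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(labels == 1 & scores >= t), numeric(1))
  fp <- vapply(th, function(t) sum(labels == 0 & scores >= t), numeric(1))
  data.frame(threshold = th, tp = tp, fp = fp)
}

# Area under the PR curve by adaptive quadrature of the interpolated
# precision along each TP segment (independent of the closed form).
aupr_quadrature <- function(tp, fp, n_pos) {
  t1v <- c(0, tp[-length(tp)])
  f1v <- c(0, fp[-length(fp)])
  area <- 0
  for (seg in seq_along(tp)) {
    dt <- tp[seg] - t1v[seg]
    if (dt <= 0) next
    k <- (fp[seg] - f1v[seg]) / dt
    t1 <- t1v[seg]; f1 <- f1v[seg]
    prec <- function(t) t / (t + f1 + k * (t - t1))
    area <- area + stats::integrate(prec, t1, tp[seg], rel.tol = 1e-12,
                                    abs.tol = 1e-14)$value
  }
  area / n_pos
}

aupr_oracle <- function(scores, labels) {
  pts <- pr_points_bruteforce(scores, labels)
  aupr_quadrature(pts$tp, pts$fp, sum(labels == 1))
}

# small random labelled instances, deliberately tie-heavy
random_pr_instance <- function(n_pairs, n_levels = 3) {
  repeat {
    labels <- rbinom(n_pairs, 1, 0.5)
    if (any(labels == 1) && any(labels == 0)) break
  }
  scores <- sample(seq_len(n_levels), n_pairs, replace = TRUE) / n_levels
  list(scores = scores, labels = labels)
}

# triangle ground truth used by several community tests
triangle_adjacency <- function() {
  generate_network(network_spec(3, 2, seed = 1))
}
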