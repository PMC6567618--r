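#' Draw species growth rates
#'
#' Growth rates `r_i` are i.i.d. Uniform(0, 1]: every species can grow in
#' isolation, and with self-regulation fixed at -1 the single-species
#' carrying capacity equals the growth rate.
#'
#' @param n number of species.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n`, all entries in (0, 1].
#' @export
draw_growth_rates <- function(n, seed = NULL) {
  stopifnot(.is_count(n))
  .maybe_seed(seed)
  r <- runif(n)
  while (any(bad <- r == 0)) r[bad] <- runif(sum(bad))
  r
}

#' Draw initial species abundances
#'
#' Initial abundances are i.i.d. Poisson with the given mean (default 100),
#' so a community of `n` species starts with about `100 * n` individuals.
#'
#' @param n number of species.
#' @param mean Poisson mean (> 0).
#' @param seed optional integer seed.
#' @return Integer vector of length `n`.
#' @export
draw_initial_abundances <- function(n, mean = 100, seed = NULL) {
  stopifnot(.is_count(n))
  if (!is.numeric(mean) || length(mean) != 1 || mean <= 0)
    stop("mean must be positive")
  .maybe_seed(seed)
  rpois(n, mean)
}

#' Bundle generalized Lotka-Volterra parameters
#'
#' @param M an `interaction_matrix` (or a plain numeric matrix).
#' @param r growth-rate vector, all entries > 0.
#' @param N0 initial-abundance vector, all entries >= 0.
#' @param t_end integration horizon in model time (default 1000).
#' @param extinction_eps abundance floor; species falling below it are
#'   clamped to exact 0 (default 1e-8).
#' @param divergence_cap abundance ceiling signalling blow-up (default 1e8).
#' @return An object of class `glv_params`.
#' @export
glv_params <- function(M, r, N0, t_end = 1000, extinction_eps = 1e-8,
                       divergence_cap = 1e8) {
  Mm <- if (inherits(M, "interaction_matrix")) M$M else M
  stopifnot(is.matrix(Mm), nrow(Mm) == ncol(Mm))
  n <- nrow(Mm)
  if (length(r) != n || length(N0) != n)
    stop("length(r) and length(N0) must equal nrow(M)")
  if (any(r <= 0)) stop("all growth rates must be positive")
  if (any(N0 < 0)) stop("initial abundances must be non-negative")
  stopifnot(t_end > 0, extinction_eps >= 0, divergence_cap > 0)
  structure(list(M = Mm, r = as.numeric(r), N0 = as.numeric(N0),
                 t_end = t_end, extinction_eps = extinction_eps,
                 divergence_cap = divergence_cap),
            class = "glv_params")
}

#' Integrate the generalized Lotka-Volterra equations
#'
#' Solves `dN_i/dt = N_i (r_i + sum_j M_ij N_j)` from `t = 0` to
#' `params$t_end` with an adaptive embedded Runge-Kutta 5(4) scheme
#' (relative tolerance 1e-8, absolute tolerance 1e-10 by default). Species
#' dropping below `extinction_eps` are set to exact 0 during integration.
#' If any abundance exceeds `divergence_cap` (or turns non-finite) the run
#' is flagged as divergent so the caller can resample.
#'
#' @param params a [glv_params()] object.
#' @param times optional non-decreasing vector of intermediate times at which
#'   to record the trajectory (the horizon `t_end` is appended if absent).
#' @param rtol,atol solver tolerances.
#' @return A list with `state` (abundances at `t_end`, all >= 0),
#'   `diverged` (logical), and, when `times` was supplied, `trajectory`
#'   (length(times) x n matrix) and `times`.
#' @export
#' @examples
#' p <- glv_params(matrix(-1, 1, 1), r = 0.7, N0 = 5)
#' integrate_glv(p)$state # logistic fixed point r/|M_11| = 0.7
integrate_glv <- function(params, times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "glv_params"))
  want_traj <- !is.null(times)
  tt <- if (want_traj) {
    if (any(diff(times) < 0)) stop("times must be non-decreasing")
    if (max(times) < params$t_end) c(times, params$t_end) else times
  } else params$t_end
  out <- .glv_integrate_cpp(params$N0, params$r, params$M, as.numeric(tt),
                            rtol, atol, params$extinction_eps,
                            params$divergence_cap)
  res <- list(state = out$state, diverged = out$diverged,
              nsteps = out$nsteps)
  if (want_traj) {
    res$trajectory <- out$trajectory[seq_along(times), , drop = FALSE]
    res$times <- times
  }
  res
}

#' Steady-state residuals of a GLV state
#'
#' Reports, per species, the absolute right-hand side `|N_i (r_i + (M N)_i)|`
#' (the literal rate of change `|dN_i/dt|`) and the per-capita rate
#' `|r_i + (M N)_i|`. At a converged interior steady state both vanish for
#' surviving species; a species still decaying toward extinction has a small
#' right-hand side but a per-capita rate bounded away from zero.
#'
#' @param M interaction matrix (or `interaction_matrix` object).
#' @param r growth-rate vector.
#' @param N abundance state.
#' @return A list with numeric vectors `rhs` and `per_capita`.
#' @export
glv_residual <- function(M, r, N) {
  Mm <- if (inherits(M, "interaction_matrix")) M$M else M
  pc <- abs(r + drop(Mm %*% pmax(N, 0)))
  list(rhs = pmax(N, 0) * pc, per_capita = pc)
}

#' Generate a steady-state abundance dataset
#'
#' Repeats the sampling process until `n_samples` non-divergent steady
#' states are collected: draw fresh growth rates and initial abundances,
#' integrate the GLV equations to `t_end`, and record the final state as one
#' sample (column). Divergent or fully extinct runs are resampled, up to a
#' budget of `10 * n_samples` attempts. Absolute abundances and their
#' per-sample relative (compositional) form are both returned.
#'
#' Growth rates are redrawn for every sample by default: with `M` and `r`
#' both fixed, a stable interior fixed point does not depend on the initial
#' abundances, so between-sample variation must come from the growth rates
#' (and from extinctions driven by initial conditions). Set
#' `redraw_growth = FALSE` to draw `r` once for the whole dataset.
#'
#' @param im an `interaction_matrix` (or numeric matrix).
#' @param n_samples number of samples (columns) to generate.
#' @param seed optional integer seed (bit-reproducible output).
#' @param redraw_growth redraw `r` for every sample (default `TRUE`).
#' @param mean_abundance Poisson mean of initial abundances.
#' @param t_end,extinction_eps,divergence_cap see [glv_params()].
#' @return A list with `absolute` and `relative` (both `abundance_table`
#'   objects) and `n_divergent`, the number of resampled runs.
#' @export
generate_dataset <- function(im, n_samples, seed = NULL,
                             redraw_growth = TRUE, mean_abundance = 100,
                             t_end = 1000, extinction_eps = 1e-8,
                             divergence_cap = 1e8) {
  Mm <- if (inherits(im, "interaction_matrix")) im$M else im
  stopifnot(is.matrix(Mm), nrow(Mm) == ncol(Mm), .is_count(n_samples))
  n <- nrow(Mm)
  .maybe_seed(seed)
  vals <- matrix(NA_real_, n, n_samples)
  n_div <- 0L
  budget <- 10L * n_samples
  r_fixed <- if (!redraw_growth) draw_growth_rates(n) else NULL
  got <- 0L
  while (got < n_samples) {
    if (budget <= 0L)
      stop("resample budget (10 * n_samples) exhausted; dynamics diverge ",
           "too often for these parameters")
    budget <- budget - 1L
    r <- if (redraw_growth) draw_growth_rates(n) else r_fixed
    N0 <- draw_initial_abundances(n, mean = mean_abundance)
    p <- glv_params(Mm, r, N0, t_end = t_end,
                    extinction_eps = extinction_eps,
                    divergence_cap = divergence_cap)
    out <- integrate_glv(p)
    if (out$diverged || sum(out$state) <= 0) {
      n_div <- n_div + 1L
      next
    }
    got <- got + 1L
    vals[, got] <- out$state
  }
  sp <- paste0("sp", seq_len(n))
  sa <- paste0("s", seq_len(n_samples))
  abs_tab <- abundance_table(vals, mode = "absolute", species_ids = sp,
                             sample_ids = sa)
  rel <- sweep(vals, 2, colSums(vals), "/")
  rel_tab <- abundance_table(rel, mode = "relative", species_ids = sp,
                             sample_ids = sa)
  list(absolute = abs_tab, relative = rel_tab, n_divergent = n_div)
}

#' Construct an abundance table
#'
#' Species x samples matrix of non-negative abundances, either `absolute` or
#' `relative` (each sample column summing to 1 within 1e-12).
#'
#' @param values numeric matrix, species as rows.
#' @param mode `"absolute"` or `"relative"`.
#' @param species_ids,sample_ids identifier vectors (defaults generated).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, mode = c("absolute", "relative"),
                            species_ids = NULL, sample_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0)) stop("abundances must be non-negative")
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  stopifnot(length(species_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  if (mode == "relative") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-12))
      stop("relative abundance columns must sum to 1 (within 1e-12)")
  }
  dimnames(values) <- NULL
  structure(list(values = values, mode = mode,
                 species_ids = as.character(species_ids),
                 sample_ids = as.character(sample_ids)),
            class = "abundance_table")
}

#' Write / read an abundance table
#'
#' OTU-table style TSV: species as rows (identifier in the first column),
#' samples as columns, with a `# mode=<mode>` comment line.
#'
#' @param tab an `abundance_table`.
#' @param path file path.
#' @param mode override the mode recorded in the file when reading.
#' @return `write_abundance` returns `path` invisibly; `read_abundance`
#'   returns an `abundance_table`.
#' @export
write_abundance <- function(tab, path) {
  stopifnot(inherits(tab, "abundance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s", tab$mode), con)
  df <- data.frame(species_id = tab$species_ids, tab$values,
                   check.names = FALSE)
  colnames(df) <- c("species_id", tab$sample_ids)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path, mode = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(mode)) {
    if (!grepl("^# mode=", first)) stop("missing '# mode=' header line")
    mode <- sub("^# mode=", "", first)
  }
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  abundance_table(vals, mode = mode, species_ids = tab[[1]],
                  sample_ids = colnames(tab)[-1])
}
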