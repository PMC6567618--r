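#' Default method settings
#'
#' Central registry of tunable settings for the inference methods, exposed
#' so a whole experiment can override them coherently.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of settings.
#' @export
method_config <- function(...) {
  cfg <- list(
    mic_alpha = 0.6, mic_c = 15,
    sparcc_dirichlet_draws = 20, sparcc_exclusion_rounds = 10,
    sparcc_exclusion_threshold = 0.1, sparcc_pseudocount = 1,
    stars_n_lambda = 20, stars_lambda_min_ratio = 0.01,
    stars_subsample_fraction = 0.8, stars_n_subsamples = 20,
    stars_beta = 0.05, stars_pseudocount = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown method_config fields: ", paste(unknown, collapse = ", "))
  modifyList(cfg, over)
}

#' Names of the implemented inference methods
#' @param include_mic include the MIC method (slow) in the default set.
#' @return Character vector of method identifiers.
#' @export
available_methods <- function(include_mic = FALSE) {
  m <- c("pearson", "spearman", "partial_pearson", "partial_spearman",
         "sparcc", "spieceasi_mb")
  if (include_mic) append(m, "mic", after = 2) else m
}

#' Run one inference method on an abundance table
#'
#' Dispatcher used by the benchmark runner and the command-line interface.
#'
#' @param tab an `abundance_table`.
#' @param method one of [available_methods()] plus `"mic"`.
#' @param seed optional seed for the stochastic methods (SparCC resampling,
#'   StARS subsampling).
#' @param config a [method_config()] list.
#' @return A `score_matrix`.
#' @export
infer_scores <- function(tab, method, seed = NULL, config = method_config()) {
  switch(method,
    pearson = correlation_scores(tab, "pearson"),
    spearman = correlation_scores(tab, "spearman"),
    partial_pearson = partial_correlation_scores(tab, "partial_pearson"),
    partial_spearman = partial_correlation_scores(tab, "partial_spearman"),
    mic = mic_scores(tab, alpha = config$mic_alpha, c = config$mic_c),
    sparcc = sparcc_scores(
      tab, dirichlet_draws = config$sparcc_dirichlet_draws,
      exclusion_rounds = config$sparcc_exclusion_rounds,
      exclusion_threshold = config$sparcc_exclusion_threshold,
      pseudocount = config$sparcc_pseudocount, seed = seed),
    spieceasi_mb = spieceasi_mb_scores(
      tab, n_lambda = config$stars_n_lambda,
      lambda_min_ratio = config$stars_lambda_min_ratio,
      subsample_fraction = config$stars_subsample_fraction,
      n_subsamples = config$stars_n_subsamples,
      beta = config$stars_beta, pseudocount = config$stars_pseudocount,
      seed = seed),
    stop("unknown method: ", method)
  )
}

#' Run one benchmark iteration
#'
#' One full pass of the pipeline for a single condition: generate a network,
#' build the signed interaction matrix, synthesize a steady-state abundance
#' dataset, run every requested inference method, and evaluate each against
#' the ground truth. The iteration's seed is derived deterministically from
#' the root seed, the condition and the iteration index, so any cell can be
#' reproduced in isolation and parallel execution order cannot change any
#' draw.
#'
#' @param condition named list with `n`, `k_avg`, `topology`, `itype`,
#'   `p_C` (may be `NA`), `n_samples`, `s_max`, and optionally `mode`
#'   (`"relative"`, the default, or `"absolute"`).
#' @param iteration iteration index (>= 1).
#' @param root_seed root integer seed.
#' @param methods character vector of method names.
#' @param config a [method_config()].
#' @return data.frame with one row per method: evaluation results plus the
#'   generating parameters, iteration index and derived seed.
#' @export
run_iteration <- function(condition, iteration, root_seed,
                          methods = available_methods(),
                          config = method_config()) {
  cond <- .normalize_condition(condition)
  seed <- child_seed(root_seed, cond$n, cond$k_avg, cond$topology,
                     cond$itype, cond$p_C, cond$n_samples, cond$s_max,
                     cond$mode, iteration)
  set.seed(seed)
  spec <- network_spec(cond$n, cond$k_avg, cond$topology)
  adj <- generate_network(spec)
  im <- build_interactions(adj, cond$itype, s_max = cond$s_max,
                           p_C = if (is.na(cond$p_C)) NULL else cond$p_C)
  ds <- generate_dataset(im, cond$n_samples)
  tab <- if (cond$mode == "absolute") ds$absolute else ds$relative
  rows <- lapply(methods, function(meth) {
    sm <- suppressWarnings(
      infer_scores(tab, meth, seed = child_seed(seed, meth), config = config))
    rec <- evaluate_scores(sm, adj)
    data.frame(method = meth, aupr_obs = rec$aupr_obs,
               aupr_rand = rec$aupr_rand, aupr_bc = rec$aupr_bc,
               n = cond$n, k_avg = cond$k_avg, topology = cond$topology,
               itype = cond$itype, p_C = cond$p_C,
               n_samples = cond$n_samples, s_max = cond$s_max,
               mode = cond$mode, iteration = iteration, seed = seed,
               n_divergent = ds$n_divergent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.normalize_condition <- function(condition) {
  defaults <- list(topology = "random", itype = "random", p_C = NA_real_,
                   n_samples = 300, s_max = 0.5, mode = "relative")
  cond <- modifyList(defaults, condition[!vapply(condition, is.null,
                                                 logical(1))])
  if (is.null(cond$n) || is.null(cond$k_avg))
    stop("condition must supply n and k_avg")
  if (is.null(cond$p_C)) cond$p_C <- NA_real_
  cond
}

#' Configure a benchmark experiment
#'
#' Any of the condition arguments may be vectors; the experiment grid is
#' their Cartesian product.
#'
#' @param n,k_avg,topology,itype,p_C,n_samples,s_max,mode condition grids.
#' @param iterations iterations per condition (default 50).
#' @param methods methods to run.
#' @param seed root seed.
#' @param output_dir optional directory for per-cell result caching
#'   (resumable runs).
#' @param config a [method_config()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n = 50, k_avg = 2, topology = "random",
                              itype = "random", p_C = NA_real_,
                              n_samples = 300, s_max = 0.5,
                              mode = "relative", iterations = 50,
                              methods = available_methods(), seed = 1,
                              output_dir = NULL,
                              config = method_config()) {
  stopifnot(.is_count(iterations), length(methods) >= 1)
  grid <- expand.grid(n = n, k_avg = k_avg, topology = topology,
                      itype = itype, p_C = p_C, n_samples = n_samples,
                      s_max = s_max, mode = mode,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  structure(list(grid = grid, iterations = iterations, methods = methods,
                 seed = seed, output_dir = output_dir, config = config),
            class = "experiment_config")
}

#' Run a benchmark experiment
#'
#' Loops over the condition grid and iterations, producing a tidy
#' long-format table (one row per method x condition x iteration). When the
#' config carries an `output_dir`, each (condition, iteration) cell is
#' written to its own CSV on completion and skipped on re-runs, so an
#' interrupted experiment resumes where it stopped. Failures in a cell are
#' recorded and the run continues; the failed cells are attached as the
#' `failures` attribute, and the aggregated summary (see
#' [aggregate_iterations()]) as the `summary` attribute.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-cell progress.
#' @return data.frame of raw records.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  use_cache <- !is.null(cfg$output_dir)
  if (use_cache && !dir.exists(cfg$output_dir))
    dir.create(cfg$output_dir, recursive = TRUE)
  rows <- list()
  failures <- list()
  for (g in seq_len(nrow(cfg$grid))) {
    cond <- as.list(cfg$grid[g, ])
    for (it in seq_len(cfg$iterations)) {
      cell_id <- sprintf(
        "cell_n%s_k%s_%s_%s_pC%s_S%s_smax%s_%s_it%03d",
        cond$n, cond$k_avg, cond$topology, cond$itype,
        ifelse(is.na(cond$p_C), "NA", cond$p_C), cond$n_samples,
        cond$s_max, cond$mode, it)
      cache <- if (use_cache) file.path(cfg$output_dir,
                                        paste0(cell_id, ".csv")) else NULL
      if (use_cache && file.exists(cache)) {
        cached <- read.csv(cache, stringsAsFactors = FALSE)
        cached$p_C <- as.numeric(cached$p_C) # all-NA column reads as logical
        rows[[cell_id]] <- cached
        next
      }
      rec <- tryCatch(
        run_iteration(cond, it, cfg$seed, methods = cfg$methods,
                      config = cfg$config),
        error = function(e) e)
      if (inherits(rec, "error")) {
        failures[[cell_id]] <- conditionMessage(rec)
        next
      }
      if (use_cache) write.csv(rec, cache, row.names = FALSE)
      rows[[cell_id]] <- rec
      if (verbose) message(cell_id, " done")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("every cell failed; first error: ",
         if (length(failures)) failures[[1]] else "none")
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  attr(out, "summary") <- aggregate_iterations(out)
  out
}

#' Experiment presets mirroring the benchmark figures
#'
#' Named experiment configurations for the main sweeps: method comparison at
#' sparse/dense degree (`fig1`), performance vs average degree (`fig2`),
#' performance vs network size and topology (`fig3`), community-type effect
#' (`fig4`), predator-prey fraction sweep (`fig5`), classical methods on
#' absolute abundances (`s3_absolute`), and sample-number sweep
#' (`s6_samplesize`). All use `s_max = 0.5`, 300 samples and 50 iterations
#' unless scaled.
#'
#' @param name preset name.
#' @param scale fraction applied to the iteration count (e.g. `scale = 0.2`
#'   gives 10 iterations) for desk-scale runs.
#' @param methods override the preset's method list.
#' @param seed root seed.
#' @param output_dir optional cache directory.
#' @return An [experiment_config()].
#' @export
preset <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig5",
                            "s3_absolute", "s6_samplesize"),
                   scale = 1, methods = NULL, seed = 1, output_dir = NULL) {
  name <- match.arg(name)
  iters <- max(2L, as.integer(round(50 * scale)))
  if (is.null(methods)) methods <- available_methods()
  base <- list(iterations = iters, methods = methods, seed = seed,
               output_dir = output_dir)
  args <- switch(name,
    fig1 = list(n = 50, k_avg = c(2, 8)),
    fig2 = list(n = c(50, 100), k_avg = c(2, 4, 6, 8, 10, 12, 14, 16)),
    fig3 = list(n = c(20, 50, 100),
                topology = c("random", "small_world", "scale_free"),
                k_avg = c(2, 8)),
    fig4 = list(n = 50, k_avg = 2,
                itype = c("random", "mutualistic", "mix_mut_comp",
                          "competitive", "predator_prey"),
                p_C = 0.5),
    fig5 = list(n = c(50, 100), k_avg = c(2, 8), itype = "mix_comp_pp",
                p_C = c(0, 0.25, 0.5, 0.75, 1)),
    s3_absolute = list(n = 50, k_avg = c(2, 8), mode = "absolute"),
    s6_samplesize = list(n = c(50, 100), k_avg = c(2, 8),
                         n_samples = c(30, 50, 100, 200, 300, 500)))
  cfg <- do.call(experiment_config, c(args, base))
  if (name == "fig4") {
    # p_C only applies to the mixture community; keep a single grid row per type
    cfg$grid$p_C[!cfg$grid$itype %in% c("mix_mut_comp", "mix_comp_pp")] <-
      NA_real_
    cfg$grid <- unique(cfg$grid)
  }
  cfg
}

#' Write / read an experiment configuration as YAML
#'
#' The YAML mirrors [experiment_config()] field-for-field (grids as lists).
#'
#' @param cfg an `experiment_config`.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  lst <- list(
    n = unique(cfg$grid$n), k_avg = unique(cfg$grid$k_avg),
    topology = unique(cfg$grid$topology), itype = unique(cfg$grid$itype),
    p_C = unique(cfg$grid$p_C), n_samples = unique(cfg$grid$n_samples),
    s_max = unique(cfg$grid$s_max), mode = unique(cfg$grid$mode),
    iterations = cfg$iterations, methods = cfg$methods, seed = cfg$seed,
    output_dir = cfg$output_dir, config = cfg$config)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  mc <- if (!is.null(lst$config)) do.call(method_config, lst$config) else
    method_config()
  experiment_config(
    n = unlist(lst$n), k_avg = unlist(lst$k_avg),
    topology = unlist(lst$topology), itype = unlist(lst$itype),
    p_C = if (is.null(lst$p_C)) NA_real_ else unlist(lst$p_C),
    n_samples = unlist(lst$n_samples), s_max = unlist(lst$s_max),
    mode = if (is.null(lst$mode)) "relative" else unlist(lst$mode),
    iterations = lst$iterations, methods = unlist(lst$methods),
    seed = lst$seed, output_dir = lst$output_dir, config = mc)
}
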