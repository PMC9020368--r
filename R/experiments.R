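#' Configure a figure-level experiment
#'
#' Bundles ensemble parameters, the hidden-size grid, training options and a
#' master seed into a validated config for [run_experiment()].  Every
#' per-run seed is derived deterministically from `seed`, so a config fully
#' determines the result bundle.
#'
#' @param experiment one of `"sparsity_sweep"`, `"modularity_sweep"`,
#'   `"size_scaling"`, `"robustness"`, `"deactivation"`,
#'   `"pair_activation"`, `"state_dependency"`.
#' @param N,M behaviors and motor units (equal in the study's settings).
#' @param k sparsity; a vector for `sparsity_sweep`/`robustness`.
#' @param m number of modules for modular ensembles.
#' @param sigma cross-module noise; a vector sweeps modularity levels.
#' @param sizes system sizes `N = M` for `size_scaling`.
#' @param R_grid hidden-layer sizes to evaluate.
#' @param replicates behavioral matrices per condition.
#' @param threshold fraction-learned criterion defining `R_c`.
#' @param epochs,learning_rate,momentum,batch_size,sigmoid_output training
#'   options, see [bottleneck_net()].
#' @param max_pairs pair subsampling for `pair_activation`.
#' @param seed master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment, N = 100, M = 100, k = 10,
                              m = 5, sigma = NULL, sizes = NULL,
                              R_grid, replicates = 10, threshold = 0.98,
                              epochs = 1e5, learning_rate = 1,
                              momentum = 0.9, batch_size = NULL,
                              sigmoid_output = TRUE, max_pairs = NULL,
                              seed = 1) {
  experiment <- match.arg(experiment,
                          c("sparsity_sweep", "modularity_sweep",
                            "size_scaling", "robustness", "deactivation",
                            "pair_activation", "state_dependency"))
  cfg <- list(experiment = experiment, N = N, M = M, k = k, m = m,
              sigma = sigma, sizes = sizes, R_grid = R_grid,
              replicates = replicates, threshold = threshold,
              epochs = epochs, learning_rate = learning_rate,
              momentum = momentum, batch_size = batch_size,
              sigmoid_output = sigmoid_output, max_pairs = max_pairs,
              seed = seed)
  class(cfg) <- "experiment_config"
  cfg
}

experiment_ensemble <- function(cfg, level_seed, N = cfg$N, M = cfg$M,
                                k = cfg$k[1], sigma = NULL) {
  lapply(seq_len(cfg$replicates), function(r) {
    s <- derive_seed(level_seed, 0L, r)
    if (is.null(sigma)) random_behaviors(N, M, k, seed = s)
    else modular_behaviors(N, M, k, cfg$m, sigma, seed = s)
  })
}

#' Run a figure-level experiment and persist its results
#'
#' Executes the protocol named by the config — capacity sweeps over sparsity
#' or modularity levels, size scaling, robustness/deactivation/pair curves,
#' or state-dependency MI curves — and writes a self-describing bundle to
#' `out_dir`: the generated behavioral matrices (delimited text + JSON
#' sidecars), a tidy `runs.csv` of every training cell, a `summary.json`
#' of the aggregated quantities, and a `manifest.json` holding the config
#' and master seed.  Re-running the same config reproduces the bundle
#' exactly.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-cell progress lines.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  train_args <- config[c("epochs", "learning_rate", "momentum",
                         "batch_size", "sigmoid_output")]
  say <- function(...) if (!quiet) message(sprintf(...))

  levels_df <- switch(config$experiment,
    sparsity_sweep = ,
    robustness = data.frame(level = config$k, what = "k"),
    modularity_sweep = ,
    deactivation = ,
    pair_activation = ,
    state_dependency = data.frame(level = config$sigma, what = "sigma"),
    size_scaling = data.frame(level = config$sizes, what = "size"))
  if (nrow(levels_df) == 0L) stop("no levels to sweep", call. = FALSE)

  all_runs <- list(); summary_rows <- list()
  for (li in seq_len(nrow(levels_df))) {
    lev <- levels_df$level[li]; what <- levels_df$what[li]
    lseed <- derive_seed(config$seed, 1000L + li)
    ens <- switch(what,
      k = experiment_ensemble(config, lseed, k = lev),
      sigma = experiment_ensemble(config, lseed, k = config$k[1], sigma = lev),
      size = experiment_ensemble(config, lseed, N = lev, M = lev,
                                 k = config$k[1],
                                 sigma = if (is.null(config$sigma)) NULL
                                         else config$sigma[1]))
    for (r in seq_along(ens))
      write_behaviors(ens[[r]],
                      file.path(out_dir, sprintf("matrix_%s%s_rep%d.csv",
                                                 what, lev, r)))
    mu <- vapply(ens, function(b) {
      if (is.na(attr(b, "n_modules"))) NA_real_ else newman_modularity(b)
    }, numeric(1))
    say("[%s] level %s = %s (%d matrices)", config$experiment, what, lev,
        length(ens))

    if (config$experiment %in% c("sparsity_sweep", "modularity_sweep",
                                 "size_scaling")) {
      sw <- do.call(capacity_sweep,
                    c(list(ensemble = ens, R_grid = config$R_grid,
                           threshold = config$threshold,
                           seed = derive_seed(lseed, 2L)), train_args))
      runs <- sw$runs; runs$level <- lev
      all_runs[[li]] <- runs
      summary_rows[[li]] <- list(
        level = lev, what = what, R_c = sw$R_c,
        R_c_per_matrix = sw$R_c_per_matrix,
        mean_modularity = if (all(is.na(mu))) NULL else mean(mu),
        entropy_bits = behavior_entropy(ens[[1]]))
    } else if (config$experiment %in% c("robustness", "deactivation",
                                        "pair_activation")) {
      mode <- switch(config$experiment, robustness = "activate",
                     deactivation = "deactivate",
                     pair_activation = "activate_pair")
      rc <- do.call(robustness_curve,
                    c(list(ensemble = ens, R_grid = config$R_grid,
                           mode = mode, seed = derive_seed(lseed, 2L),
                           max_pairs = config$max_pairs), train_args))
      runs <- rc$runs; runs$level <- lev
      all_runs[[li]] <- runs
      summary_rows[[li]] <- list(
        level = lev, what = what,
        mean_robustness_by_R = stats::setNames(
          rc$curve$mean_robustness, rc$curve$R),
        R_robust = estimate_R_robust(rc, config$threshold),
        mean_modularity = if (all(is.na(mu))) NULL else mean(mu))
    } else { # state_dependency
      sd_ <- do.call(state_dependency_curve,
                     c(list(ensemble = ens, R_grid = config$R_grid,
                            seed = derive_seed(lseed, 2L)), train_args))
      runs <- sd_$runs; runs$level <- lev
      all_runs[[li]] <- runs
      summary_rows[[li]] <- list(
        level = lev, what = what,
        mean_mi_by_R = stats::setNames(sd_$curve$mean_mi, sd_$curve$R),
        mean_modularity = if (all(is.na(mu))) NULL else mean(mu))
    }
  }

  runs <- do.call(rbind, all_runs)
  utils::write.table(runs, file.path(out_dir, "runs.csv"), sep = ",",
                     row.names = FALSE, qmethod = "double")
  summary <- list(experiment = config$experiment, levels = summary_rows)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package = "bottlenet",
                   version = as.character(utils::packageVersion("bottlenet")),
                   experiment = config$experiment,
                   config = unclass(config), master_seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

#' Summarize one or more experiment bundles
#'
#' Reads the manifest and summary of completed [run_experiment()] bundles
#' and returns one tidy row per swept level (with `R_c`, `R_robust` or the
#' per-`R` mean curves as applicable).  Directories from different
#' experiments cannot be mixed.
#'
#' @param dirs one or more bundle directories.
#' @return A data frame with one row per level per bundle.
#' @export
summarize_experiment <- function(dirs) {
  manifests <- lapply(dirs, function(d) {
    mf <- file.path(d, "manifest.json")
    if (!file.exists(mf))
      stop("missing manifest in ", d, call. = FALSE)
    jsonlite::read_json(mf)
  })
  exps <- vapply(manifests, `[[`, character(1), "experiment")
  if (length(unique(exps)) != 1L)
    stop("mixed bundles: manifests report different experiments (",
         paste(unique(exps), collapse = ", "), ")", call. = FALSE)
  rows <- lapply(seq_along(dirs), function(i) {
    s <- jsonlite::read_json(file.path(dirs[[i]], "summary.json"),
                             simplifyVector = TRUE)
    lv <- s$levels
    lv$dir <- as.character(dirs[[i]])
    lv$experiment <- s$experiment
    lv
  })
  do.call(rbind, lapply(rows, function(r)
    r[, intersect(names(r), Reduce(intersect, lapply(rows, names))),
      drop = FALSE]))
}
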