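#' Sweep the bottleneck size and estimate the critical size R_c
#'
#' For every hidden-layer size in `R_grid` and every behavioral matrix in
#' `ensemble`, trains a fresh network and records the fraction of behaviors
#' learned.  The critical bottleneck size `R_c` is the smallest grid value
#' whose mean fraction over the ensemble reaches `threshold` (98% by
#' convention).  The per-matrix crossing points are reported as well, since
#' "averaged across instantiations" admits either statistic; `R_c` from the
#' mean curve is the primary one.
#'
#' Per-run seeds are derived deterministically from `seed`, the grid
#' position, and the replicate index, so a sweep is exactly reproducible.
#' A run whose training diverges is recorded as `NA` and flagged rather than
#' aborting the sweep.
#'
#' @param ensemble a list of `behavior_matrix` objects (replicate
#'   instantiations from one generating distribution).
#' @param R_grid increasing vector of hidden-layer sizes.
#' @param threshold fraction of behaviors that must be reproduced.
#' @param seed master seed for the sweep.
#' @param ... training options passed on to [bottleneck_net()]
#'   (`epochs`, `learning_rate`, ...).
#' @return An object of class `capacity_sweep`:
#'   \describe{
#'     \item{runs}{data frame `(R, replicate, fraction_learned)`.}
#'     \item{curve}{data frame `(R, mean_fraction, sd_fraction, n)`.}
#'     \item{R_c}{smallest grid `R` with mean fraction >= threshold
#'       (`NA` when not reached).}
#'     \item{R_c_per_matrix}{per-replicate crossing points.}
#'   }
#' @examples
#' ens <- lapply(1:2, function(s) random_behaviors(12, 12, 3, seed = s))
#' sw <- capacity_sweep(ens, R_grid = c(4, 8, 12), epochs = 1500, seed = 1)
#' sw$R_c
#' @export
capacity_sweep <- function(ensemble, R_grid, threshold = 0.98, seed = 1,
                           ...) {
  if (length(ensemble) == 0L || length(R_grid) == 0L)
    stop("ensemble and R_grid must be non-empty", call. = FALSE)
  if (is.unsorted(R_grid, strictly = TRUE))
    stop("R_grid must be strictly increasing", call. = FALSE)
  runs <- expand.grid(replicate = seq_along(ensemble), R = R_grid)
  runs <- runs[, c("R", "replicate")]
  runs$fraction_learned <- NA_real_
  runs$failed <- FALSE
  for (row in seq_len(nrow(runs))) {
    R <- runs$R[row]; rep_i <- runs$replicate[row]
    fit <- tryCatch(
      bottleneck_net(ensemble[[rep_i]], R = R,
                     seed = derive_seed(seed, match(R, R_grid), rep_i), ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      runs$failed[row] <- TRUE
    } else {
      runs$fraction_learned[row] <- fit$fraction_learned
    }
  }
  curve <- aggregate_curve(runs, "fraction_learned")
  per_matrix <- vapply(seq_along(ensemble), function(rep_i) {
    sub <- runs[runs$replicate == rep_i, ]
    first_crossing(sub$R, sub$fraction_learned, threshold)
  }, numeric(1))
  structure(list(runs = runs, curve = curve,
                 threshold = threshold,
                 R_c = first_crossing(curve$R, curve$mean_fraction, threshold),
                 R_c_per_matrix = per_matrix,
                 seed = seed),
            class = "capacity_sweep")
}

aggregate_curve <- function(runs, col) {
  sp <- split(runs[[col]], runs$R)
  data.frame(R = as.numeric(names(sp)),
             mean_fraction = vapply(sp, mean, numeric(1), na.rm = TRUE),
             sd_fraction = vapply(sp, stats::sd, numeric(1), na.rm = TRUE),
             n = vapply(sp, function(x) sum(!is.na(x)), numeric(1)),
             row.names = NULL)
}

first_crossing <- function(R, value, threshold) {
  ok <- which(!is.na(value) & value >= threshold)
  if (length(ok) == 0L) NA_real_ else R[min(ok)]
}

#' Critical bottleneck size from a sweep
#'
#' Smallest hidden-layer size whose mean fraction of behaviors learned
#' reaches the threshold.  Returns `NA` (threshold "not reached") when no
#' grid value qualifies.
#'
#' @param sweep a `capacity_sweep`, or a data frame with columns `R` and
#'   `mean_fraction`.
#' @param threshold required mean fraction (defaults to the sweep's own).
#' @return The critical size, or `NA` if not reached on the grid.
#' @export
estimate_Rc <- function(sweep, threshold = NULL) {
  if (inherits(sweep, "capacity_sweep")) {
    curve <- sweep$curve
    if (is.null(threshold)) threshold <- sweep$threshold
  } else {
    curve <- sweep
    if (is.null(threshold)) threshold <- 0.98
  }
  if (is.null(curve$R) || is.null(curve$mean_fraction) || nrow(curve) == 0L)
    stop("sweep must provide R and mean_fraction", call. = FALSE)
  first_crossing(curve$R, curve$mean_fraction, threshold)
}

#' @export
print.capacity_sweep <- function(x, ...) {
  cat(sprintf("Capacity sweep: %d matrices x %d grid points\n",
              max(x$runs$replicate), nrow(x$curve)))
  print(x$curve, row.names = FALSE)
  if (is.na(x$R_c)) {
    cat(sprintf("R_c (threshold %.2f): not reached on the grid\n", x$threshold))
  } else {
    cat(sprintf("R_c (threshold %.2f): %g\n", x$threshold, x$R_c))
  }
  invisible(x)
}

#' @export
plot.capacity_sweep <- function(x, ...) {
  graphics::plot(x$curve$R, x$curve$mean_fraction, type = "b", ylim = c(0, 1),
                 xlab = "hidden layer size R", ylab = "fraction learned", ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (!is.na(x$R_c)) graphics::abline(v = x$R_c, lty = 3)
  invisible(x)
}

#' Robustness as a function of the bottleneck size
#'
#' For each grid size and matrix, trains a network and averages the
#' conserved-behavior fraction over all single-unit perturbations (or unit
#' pairs), giving the robustness curve from which `R_robust` — the smallest
#' hidden layer whose perturbations leave 98% of behaviors unaffected — is
#' read off with [estimate_R_robust()].
#'
#' @inheritParams capacity_sweep
#' @param mode perturbation mode, see [network_robustness()].
#' @param max_pairs passed to [network_robustness()] for pair activation.
#' @param ... training options passed on to [bottleneck_net()].
#' @return An object of class `robustness_curve` with `runs`
#'   (`R`, `replicate`, `robustness`, `fraction_learned`) and the aggregated
#'   `curve`.
#' @export
robustness_curve <- function(ensemble, R_grid, mode = "activate",
                             seed = 1, max_pairs = NULL, ...) {
  if (length(ensemble) == 0L || length(R_grid) == 0L)
    stop("ensemble and R_grid must be non-empty", call. = FALSE)
  runs <- expand.grid(replicate = seq_along(ensemble), R = R_grid)
  runs <- runs[, c("R", "replicate")]
  runs$robustness <- NA_real_
  runs$fraction_learned <- NA_real_
  runs$failed <- FALSE
  for (row in seq_len(nrow(runs))) {
    R <- runs$R[row]; rep_i <- runs$replicate[row]
    fit <- tryCatch(
      bottleneck_net(ensemble[[rep_i]], R = R,
                     seed = derive_seed(seed, match(R, R_grid), rep_i), ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      runs$failed[row] <- TRUE
      next
    }
    rb <- network_robustness(fit, mode = mode, max_pairs = max_pairs,
                             seed = derive_seed(seed, match(R, R_grid), rep_i))
    runs$robustness[row] <- rb$robustness
    runs$fraction_learned[row] <- fit$fraction_learned
  }
  sp <- split(runs$robustness, runs$R)
  curve <- data.frame(R = as.numeric(names(sp)),
                      mean_robustness = vapply(sp, mean, numeric(1), na.rm = TRUE),
                      sd_robustness = vapply(sp, stats::sd, numeric(1), na.rm = TRUE),
                      row.names = NULL)
  structure(list(runs = runs, curve = curve, mode = mode, seed = seed),
            class = "robustness_curve")
}

#' Smallest bottleneck size meeting a robustness threshold
#'
#' @param curve a `robustness_curve`, or a data frame with columns `R` and
#'   `mean_robustness`.
#' @param threshold required mean robustness (default 0.98).
#' @return Smallest `R` whose mean robustness reaches the threshold, `NA`
#'   when not reached.
#' @export
estimate_R_robust <- function(curve, threshold = 0.98) {
  if (inherits(curve, "robustness_curve")) curve <- curve$curve
  if (is.null(curve$R) || is.null(curve$mean_robustness) || nrow(curve) == 0L)
    stop("curve must provide R and mean_robustness", call. = FALSE)
  first_crossing(curve$R, curve$mean_robustness, threshold)
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("Robustness curve (%s): %d matrices x %d grid points\n",
              x$mode, max(x$runs$replicate), nrow(x$curve)))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

# deterministic per-run seed derived from a master seed and grid coordinates
derive_seed <- function(master, i, j = 0L) {
  as.integer((as.numeric(master) + 9973 * i + 131 * j) %% 2147483647)
}
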