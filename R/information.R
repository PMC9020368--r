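#' Census of the perturbed input-output mapping
#'
#' After a perturbation, each one-hot input maps to some binarized output
#' row.  Relative to the original (unperturbed) outputs, each input falls in
#' one of three cases: (i) its mapping is unaffected, (ii) it maps onto a
#' *different* member of the original output set (stereotypy), or (iii) it
#' maps to a novel row outside the original output set.  The census counts,
#' for every original output row `y_i`, the number of inputs `n_i` that land
#' on it, plus the number of inputs producing novel rows.
#'
#' @param original `N x M` binary matrix of unperturbed outputs; its rows
#'   must be distinct (the perfect-learning premise).
#' @param perturbed `N x M` binary matrix of outputs under perturbation.
#' @return An object of class `mapping_census` with fields `n_i`
#'   (length `N`), `novel_count`, `unaffected` (count of case-(i) inputs),
#'   `stereotypy_count` (case ii), `N_inputs` and `M_outputs`
#'   (`= N`, the number of original distinct outputs — not the number of
#'   motor units).
#' @examples
#' y <- random_behaviors(6, 8, k = 2, seed = 3)
#' census <- mapping_census(y, y)   # identity mapping
#' census$n_i
#' @export
mapping_census <- function(original, perturbed) {
  original <- unclass(original); perturbed <- unclass(perturbed)
  if (!all(dim(original) == dim(perturbed)))
    stop("original and perturbed outputs must have the same shape",
         call. = FALSE)
  okey <- apply(original, 1L, paste, collapse = "")
  if (anyDuplicated(okey))
    stop("original output rows must be distinct (perfect-learning premise)",
         call. = FALSE)
  pkey <- apply(perturbed, 1L, paste, collapse = "")
  hit <- match(pkey, okey)
  n_i <- tabulate(hit, nbins = nrow(original))
  structure(list(
    n_i = n_i,
    novel_count = sum(is.na(hit)),
    unaffected = sum(!is.na(hit) & hit == seq_along(hit)),
    stereotypy_count = sum(!is.na(hit) & hit != seq_along(hit)),
    N_inputs = nrow(original),
    M_outputs = nrow(original)),
    class = "mapping_census")
}

#' @export
print.mapping_census <- function(x, ...) {
  cat(sprintf("Mapping census over %d inputs:\n", x$N_inputs))
  cat(sprintf("  unaffected: %d, stereotyped: %d, novel: %d\n",
              x$unaffected, x$stereotypy_count, x$novel_count))
  invisible(x)
}

#' Mutual information between intended behavior and perturbed output
#'
#' With uniform priors `P(x) = 1/N` over intended behaviors and
#' `P(y) = 1/M` over original outputs, the mutual information between the
#' input distribution and the perturbed output distribution reduces to the
#' closed form
#' \deqn{I(X; Y) = \frac{1}{M} \sum_{y_i : n_i > 0} \log_2 \frac{N}{n_i},}
#' where `n_i` counts the inputs mapped onto original output `y_i`.  Novel
#' outputs (case iii of the census) carry no information about the input and
#' contribute nothing.  Without stereotypy (`n_i` in `{0, 1}`) this equals
#' `(m/M) log2 N` with `m` the number of conserved outputs, i.e. MI is then
#' proportional to the robustness; an unperturbed perfect mapping gives
#' `log2 N` exactly.
#'
#' @param census a [mapping_census()].
#' @return Mutual information in bits, in `[0, log2(N)]`.
#' @export
mutual_information <- function(census) {
  if (!inherits(census, "mapping_census"))
    stop("census must be a mapping_census", call. = FALSE)
  n_i <- census$n_i[census$n_i > 0]
  if (length(n_i) == 0L) return(0)
  sum(log2(census$N_inputs / n_i)) / census$M_outputs
}

#' State-dependency of perturbation effects across bottleneck sizes
#'
#' For each hidden-layer size and each behavioral matrix, trains a network,
#' forces each hidden unit on in turn, and computes the mutual information
#' between the intended-behavior distribution and the perturbed outputs
#' (relative to the network's own unperturbed outputs).  High MI means the
#' outcome of stimulating a descending unit is predictable from the intended
#' behavior — the perturbation effect is state-dependent rather than
#' stereotyped or chaotic.
#'
#' @inheritParams capacity_sweep
#' @param mode perturbation mode (single-unit `"activate"` or
#'   `"deactivate"`).
#' @param ... training options passed on to [bottleneck_net()].
#' @return An object of class `state_dependency` with `runs`
#'   (`R`, `replicate`, `mi_bits`, `robustness`, `stereotypy`) and an
#'   aggregated `curve` of mean MI per `R`.
#' @export
state_dependency_curve <- function(ensemble, R_grid, mode = "activate",
                                   seed = 1, ...) {
  if (length(ensemble) == 0L || length(R_grid) == 0L)
    stop("ensemble and R_grid must be non-empty", call. = FALSE)
  runs <- expand.grid(replicate = seq_along(ensemble), R = R_grid)
  runs <- runs[, c("R", "replicate")]
  runs$mi_bits <- NA_real_
  runs$robustness <- NA_real_
  runs$stereotypy <- NA_real_
  runs$failed <- FALSE
  for (row in seq_len(nrow(runs))) {
    R <- runs$R[row]; rep_i <- runs$replicate[row]
    fit <- tryCatch(
      bottleneck_net(ensemble[[rep_i]], R = R,
                     seed = derive_seed(seed, match(R, R_grid), rep_i), ...),
      error = function(e) e)
    if (inherits(fit, "error")) { runs$failed[row] <- TRUE; next }
    base <- binarize(net_forward(fit))
    # MI is defined against a distinct original output set; de-duplicate by
    # falling back to the target matrix when the net has not separated rows
    orig <- if (!anyDuplicated(apply(base, 1L, paste, collapse = "")))
      base else unclass(fit$target)
    if (anyDuplicated(apply(orig, 1L, paste, collapse = ""))) {
      runs$failed[row] <- TRUE; next
    }
    per_unit <- vapply(seq_len(fit$R), function(u) {
      pert <- binarize(perturbed_forward(fit, u,
                                         mode = if (mode == "deactivate")
                                           "deactivate" else "activate",
                                         mechanism = "clamp"))
      cen <- mapping_census(orig, pert)
      c(mi = mutual_information(cen),
        rob = cen$unaffected / cen$N_inputs,
        st = cen$stereotypy_count / cen$N_inputs)
    }, numeric(3))
    runs$mi_bits[row] <- mean(per_unit["mi", ])
    runs$robustness[row] <- mean(per_unit["rob", ])
    runs$stereotypy[row] <- mean(per_unit["st", ])
  }
  sp <- split(runs$mi_bits, runs$R)
  curve <- data.frame(R = as.numeric(names(sp)),
                      mean_mi = vapply(sp, mean, numeric(1), na.rm = TRUE),
                      sd_mi = vapply(sp, stats::sd, numeric(1), na.rm = TRUE),
                      row.names = NULL)
  structure(list(runs = runs, curve = curve, mode = mode, seed = seed),
            class = "state_dependency")
}

#' @export
print.state_dependency <- function(x, ...) {
  cat(sprintf("State-dependency curve (%s):\n", x$mode))
  print(x$curve, row.names = FALSE)
  invisible(x)
}
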