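#' Perturb a trained network by forcing hidden units on or off
#'
#' Emulates optogenetic activation/inhibition of descending neurons: the
#' listed hidden units are forced to activation 1 (`mode = "activate"`) or 0
#' (`mode = "deactivate"`) for every behavioral command while all trained
#' parameters stay untouched, and the perturbed binarized motor outputs are
#' compared row-wise with the unperturbed ones.
#'
#' Two forcing mechanisms are available.  `"clamp"` (default) overrides the
#' hidden activation exactly.  `"weight_injection"` instead sets the unit's
#' column of the first weight matrix to `injection_value` (negated for
#' deactivation), which saturates the sigmoid; it is the asymptotic version
#' of the clamp and must agree with it on binarized outputs.
#'
#' @param object a fitted [bottleneck_net()].
#' @param units one hidden-unit index, or two distinct indices to activate a
#'   pair at once.
#' @param mode `"activate"` or `"deactivate"`.
#' @param mechanism `"clamp"` or `"weight_injection"`.
#' @param injection_value magnitude used by the weight-injection mechanism.
#' @return An object of class `perturbation_outcome`:
#'   \describe{
#'     \item{flip_map}{`N x M` matrix over `{-1, 0, +1}`: `+1` where a motor
#'       unit turned on, `-1` where one turned off.}
#'     \item{conserved}{length-`N` logical, `TRUE` when a behavior's entire
#'       output row is unchanged.}
#'     \item{robustness}{`mean(conserved)`.}
#'     \item{affected_count}{`N - sum(conserved)`.}
#'     \item{robustness_active}{companion statistic under the narrower
#'       criterion that only the target-active motor units must be
#'       conserved (spurious activations ignored).}
#'   }
#' @examples
#' b <- random_behaviors(15, 15, k = 4, seed = 2)
#' fit <- bottleneck_net(b, R = 15, epochs = 2000, seed = 1)
#' p <- perturb(fit, units = 1)
#' p$robustness
#' @export
perturb <- function(object, units, mode = c("activate", "deactivate"),
                    mechanism = c("clamp", "weight_injection"),
                    injection_value = 1e3) {
  mode <- match.arg(mode)
  mechanism <- match.arg(mechanism)
  units <- as.integer(units)
  if (length(units) < 1L || length(units) > 2L || anyNA(units) ||
      any(units < 1L | units > object$R) || anyDuplicated(units))
    stop("units must be one or two distinct hidden-unit indices in [1, R]",
         call. = FALSE)
  base <- binarize(net_forward(object))
  pert <- binarize(perturbed_forward(object, units, mode, mechanism,
                                     injection_value))
  flip_map <- pert - base
  conserved <- rowSums(flip_map != 0L) == 0L
  tmat <- unclass(object$target)
  active_ok <- rowSums((tmat == 1L) & (pert != base)) == 0L
  structure(list(
    units = units, mode = mode, mechanism = mechanism,
    flip_map = flip_map,
    conserved = conserved,
    robustness = mean(conserved),
    affected_count = sum(!conserved),
    robustness_active = mean(active_ok),
    perturbed = pert, unperturbed = base),
    class = "perturbation_outcome")
}

perturbed_forward <- function(object, units, mode, mechanism,
                              injection_value = 1e3) {
  if (mechanism == "clamp") {
    net_forward(object, clamp_units = units,
                clamp_value = if (mode == "activate") 1 else 0)
  } else {
    params <- list(W1 = object$W1, B1 = object$B1,
                   W2 = object$W2, B2 = object$B2,
                   config = object$config)
    sign <- if (mode == "activate") 1 else -1
    params$W1[, units] <- sign * injection_value
    net_forward(params,
                sigmoid_output = isTRUE(object$config$sigmoid_output))
  }
}

#' @export
print.perturbation_outcome <- function(x, ...) {
  cat(sprintf("Perturbation: %s unit%s %s (%s)\n", x$mode,
              if (length(x$units) > 1) "s" else "",
              paste(x$units, collapse = ", "), x$mechanism))
  cat(sprintf("  robustness (strict rows conserved): %.3f\n", x$robustness))
  cat(sprintf("  behaviors affected: %d of %d\n", x$affected_count,
              length(x$conserved)))
  invisible(x)
}

#' Robustness of a network to single-unit (or pair) perturbations
#'
#' Applies [perturb()] to every hidden unit (or every unordered pair for
#' `mode = "activate_pair"`) and averages the conserved-behavior fraction.
#'
#' @inheritParams perturb
#' @param mode `"activate"`, `"deactivate"`, or `"activate_pair"`.
#' @param max_pairs for pair activation, subsample at most this many pairs
#'   (seeded); `NULL` enumerates all.
#' @param seed seed for pair subsampling.
#' @return List with `robustness` (mean over perturbations), `per_unit`
#'   (robustness per perturbation), and `outcomes` (the individual
#'   `perturbation_outcome` objects).
#' @export
network_robustness <- function(object, mode = c("activate", "deactivate",
                                                "activate_pair"),
                               mechanism = c("clamp", "weight_injection"),
                               max_pairs = NULL, seed = NULL) {
  mode <- match.arg(mode)
  mechanism <- match.arg(mechanism)
  if (mode == "activate_pair") {
    pairs <- utils::combn(object$R, 2, simplify = FALSE)
    if (!is.null(max_pairs) && length(pairs) > max_pairs) {
      if (!is.null(seed)) set.seed(seed)
      pairs <- pairs[sample.int(length(pairs), max_pairs)]
    }
    outcomes <- lapply(pairs, function(u)
      perturb(object, u, mode = "activate", mechanism = mechanism))
  } else {
    outcomes <- lapply(seq_len(object$R), function(u)
      perturb(object, u, mode = mode, mechanism = mechanism))
  }
  per_unit <- vapply(outcomes, `[[`, numeric(1), "robustness")
  list(robustness = mean(per_unit), per_unit = per_unit, outcomes = outcomes)
}

#' Distribution of the number of behaviors affected per perturbation
#'
#' @param outcomes a list of `perturbation_outcome` objects (e.g. from
#'   `network_robustness()$outcomes`).
#' @return A table of counts indexed by `affected_count`; its total equals
#'   the number of perturbations.
#' @export
affected_distribution <- function(outcomes) {
  if (length(outcomes) == 0L) stop("no outcomes supplied", call. = FALSE)
  counts <- vapply(outcomes, `[[`, numeric(1), "affected_count")
  table(factor(counts, levels = 0:max(counts)))
}
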