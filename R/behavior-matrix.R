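#' Behavioral matrices
#'
#' A behavioral matrix is an `N x M` binary matrix whose row `i` lists the
#' motor units that must be switched on to perform behavior `i`.  Every row
#' has exactly `k` active units ("sparsity").  Matrices are either fully
#' random, or modular: rows and motor units are partitioned into `m` equal
#' blocks and each behavior places `k - sigma` of its active units inside its
#' home block and `sigma` outside it ("cross-module noise").
#'
#' @name behavior_matrix
#' @keywords internal
NULL

new_behavior_matrix <- function(values, k, modules = NULL, sigma = NA_integer_,
                                seed = NA_integer_) {
  structure(values,
            k = as.integer(k),
            row_module = modules$rows,
            col_module = modules$cols,
            n_modules = if (is.null(modules)) NA_integer_ else modules$m,
            sigma = as.integer(sigma),
            seed = as.integer(seed),
            class = c("behavior_matrix", "matrix", "array"))
}

check_counts <- function(N, M, k) {
  if (length(N) != 1L || length(M) != 1L || length(k) != 1L ||
      N < 1 || M < 1 || N != round(N) || M != round(M) || k != round(k))
    stop("N and M must be positive integers and k a non-negative integer",
         call. = FALSE)
  if (k < 0 || k > M)
    stop("k must satisfy 0 <= k <= M", call. = FALSE)
  invisible(NULL)
}

#' Generate a random behavioral matrix
#'
#' Each of the `N` rows receives exactly `k` ones in columns drawn uniformly
#' at random without replacement from the `M` motor units.
#'
#' @param N number of behaviors (rows).
#' @param M number of motor units (columns).
#' @param k number of active motor units per behavior, `0 <= k <= M`.
#' @param seed optional integer seed; when given the draw is reproducible.
#' @return A `behavior_matrix`: an `N x M` 0/1 matrix with attributes
#'   recording `k` and the seed.
#' @examples
#' b <- random_behaviors(10, 20, k = 3, seed = 1)
#' rowSums(b)  # all equal 3
#' @export
random_behaviors <- function(N, M, k, seed = NULL) {
  check_counts(N, M, k)
  if (!is.null(seed)) set.seed(seed)
  vals <- matrix(0L, N, M)
  for (i in seq_len(N))
    vals[i, sample.int(M, k)] <- 1L
  new_behavior_matrix(vals, k, seed = if (is.null(seed)) NA else seed)
}

#' Generate a modular behavioral matrix
#'
#' Rows (behaviors) and columns (motor units) are split into `m` contiguous
#' blocks of equal size.  A behavior in block `b` activates `k - sigma`
#' units inside block `b`'s columns and `sigma` units outside, all positions
#' drawn uniformly without replacement.  `sigma = 0` gives perfect modularity;
#' increasing `sigma` interpolates toward a random matrix while preserving
#' the row sparsity `k`.
#'
#' @inheritParams random_behaviors
#' @param m number of modules; must divide both `N` and `M`.
#' @param sigma number of active units placed outside the home module,
#'   `0 <= sigma <= k`.
#' @return A `behavior_matrix` carrying the per-row/per-column module labels.
#' @examples
#' b <- modular_behaviors(20, 20, k = 4, m = 4, sigma = 0, seed = 1)
#' newman_modularity(b)  # (m - 1)/m = 0.75
#' @export
modular_behaviors <- function(N, M, k, m, sigma = 0, seed = NULL) {
  check_counts(N, M, k)
  if (m < 1 || N %% m != 0 || M %% m != 0)
    stop("m must divide both N and M", call. = FALSE)
  if (sigma < 0 || sigma > k)
    stop("sigma must satisfy 0 <= sigma <= k", call. = FALSE)
  m_size <- M %/% m
  if (k - sigma > m_size)
    stop("k - sigma exceeds the module width M/m", call. = FALSE)
  if (sigma > M - m_size)
    stop("sigma exceeds the number of columns outside a module", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  row_mod <- rep(seq_len(m), each = N %/% m)
  col_mod <- rep(seq_len(m), each = m_size)
  vals <- matrix(0L, N, M)
  for (i in seq_len(N)) {
    home <- which(col_mod == row_mod[i])
    away <- which(col_mod != row_mod[i])
    vals[i, home[sample.int(length(home), k - sigma)]] <- 1L
    if (sigma > 0)
      vals[i, away[sample.int(length(away), sigma)]] <- 1L
  }
  new_behavior_matrix(vals, k,
                      modules = list(rows = row_mod, cols = col_mod, m = as.integer(m)),
                      sigma = sigma, seed = if (is.null(seed)) NA else seed)
}

#' @export
print.behavior_matrix <- function(x, ...) {
  cat(sprintf("Behavioral matrix: %d behaviors x %d motor units, k = %d\n",
              nrow(x), ncol(x), attr(x, "k")))
  m <- attr(x, "n_modules")
  if (!is.na(m))
    cat(sprintf("  modular: %d blocks, sigma = %d\n", m, attr(x, "sigma")))
  invisible(x)
}

#' Write / read a behavioral matrix as delimited text
#'
#' The matrix itself is stored header-free, one behavior per line, 0/1
#' integers separated by commas.  A JSON sidecar (`<file>.json`) records the
#' generation parameters, realized modularity and entropy so a matrix on disk
#' is self-describing.
#'
#' @param x a `behavior_matrix`.
#' @param file path of the CSV file to create.
#' @return `write_behaviors` returns `file` invisibly; `read_behaviors`
#'   returns the reconstructed `behavior_matrix`.
#' @export
write_behaviors <- function(x, file) {
  utils::write.table(unclass(x), file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  m <- attr(x, "n_modules")
  meta <- list(N = nrow(x), M = ncol(x), k = attr(x, "k"),
               m = if (is.na(m)) NULL else m,
               sigma = if (is.na(attr(x, "sigma"))) NULL else attr(x, "sigma"),
               seed = if (is.na(attr(x, "seed"))) NULL else attr(x, "seed"),
               modularity = if (is.na(m)) NULL else newman_modularity(x),
               entropy_bits = behavior_entropy(x))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_behaviors
#' @export
read_behaviors <- function(file) {
  vals <- as.matrix(utils::read.table(file, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  storage.mode(vals) <- "integer"
  side <- paste0(file, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  k <- if (!is.null(meta$k)) meta$k else max(rowSums(vals))
  if (!is.null(meta$m)) {
    mods <- list(rows = rep(seq_len(meta$m), each = nrow(vals) %/% meta$m),
                 cols = rep(seq_len(meta$m), each = ncol(vals) %/% meta$m),
                 m = as.integer(meta$m))
    new_behavior_matrix(vals, k, modules = mods,
                        sigma = if (is.null(meta$sigma)) NA else meta$sigma,
                        seed = if (is.null(meta$seed)) NA else meta$seed)
  } else {
    new_behavior_matrix(vals, k, seed = if (is.null(meta$seed)) NA else meta$seed)
  }
}
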