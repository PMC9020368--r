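#' Entropy of behavioral-matrix ensembles
#'
#' The entropy (in bits) of the ensemble a behavioral matrix was drawn from,
#' i.e. the log2 count of equiprobable matrices with the same parameters.
#' For a random matrix with `k` of `M` units active per row,
#' \deqn{S = N \log_2 \binom{M}{k},}
#' and for a modular matrix with `m` equal modules of width
#' `m_size = M/m` and cross-module noise `sigma`,
#' \deqn{S = N \log_2\left[\binom{m_{size}}{k-\sigma}
#'   \binom{M - m_{size}}{\sigma}\right].}
#' Binomial coefficients enter through `lchoose()`, which evaluates the
#' log-coefficient exactly to double precision, so no overflow occurs even
#' at `choose(100, 50)`.
#'
#' `behavior_entropy()` dispatches on its input: given a `behavior_matrix` it
#' reads the stored parameters; given counts it evaluates the closed form
#' directly.
#'
#' @param x a `behavior_matrix`, or the number of behaviors `N`.
#' @param M,k motor-unit count and per-row sparsity (when `x` is a count).
#' @param m,sigma module count and cross-module noise; both `NULL` for the
#'   random ensemble.
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' behavior_entropy(100, M = 100, k = 10)          # 100 * log2(choose(100, 10))
#' behavior_entropy(100, M = 100, k = 10, m = 5, sigma = 0)
#' @export
behavior_entropy <- function(x, M = NULL, k = NULL, m = NULL, sigma = NULL) {
  if (inherits(x, "behavior_matrix")) {
    N <- nrow(x); M <- ncol(x); k <- attr(x, "k")
    m <- attr(x, "n_modules"); sigma <- attr(x, "sigma")
    if (is.na(m)) m <- NULL
  } else {
    N <- x
  }
  check_counts(N, M, k)
  if (is.null(m))
    return(N * lchoose(M, k) / log(2))
  m_size <- M %/% m
  if (M %% m != 0 || sigma < 0 || sigma > k || k - sigma > m_size ||
      sigma > M - m_size)
    stop("invalid modular parameters", call. = FALSE)
  N * (lchoose(m_size, k - sigma) + lchoose(M - m_size, sigma)) / log(2)
}
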