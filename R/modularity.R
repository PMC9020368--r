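#' Newman modularity of a behavioral matrix
#'
#' The `N x M` behavioral matrix is interpreted as the adjacency matrix of a
#' graph on `max(N, M)` nodes, where node `i` stands for both behavior `i`
#' (row) and motor unit `i` (column).  Modularity is Newman's score
#' \deqn{\mu = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{k_i k_j}{2m}\right)
#'   \delta(c_i, c_j)}
#' with `m` the number of edges, `k_i` the degree of node `i` and
#' `delta(c_i, c_j) = 1` when the nodes share a community.
#'
#' By default the asymmetric matrix is symmetrized as a weighted graph
#' (`w = A + t(A)`) and the weighted undirected form above is evaluated;
#' with `directed = TRUE` the directed variant
#' \eqn{\mu = (1/m)\sum_{ij}(A_{ij} - k^{out}_i k^{in}_j / m)\,\delta(c_i,c_j)}
#' is used instead.  For block-diagonal matrices with `m` equal modules both
#' conventions give exactly `(m - 1)/m`; for noisy matrices they can differ
#' slightly.
#'
#' @param x a `behavior_matrix`, or any square non-negative matrix to treat
#'   as a graph adjacency.
#' @param communities integer/factor vector of community labels, one per
#'   node.  Defaults to the block labels stored in a modular
#'   `behavior_matrix`; required otherwise.
#' @param directed use the directed-graph convention instead of weighted
#'   symmetrization.
#' @return Modularity score in `[-1, 1]`.  A single all-inclusive community
#'   scores exactly 0.
#' @examples
#' b <- modular_behaviors(20, 20, k = 4, m = 5, sigma = 0, seed = 1)
#' newman_modularity(b)        # exactly (5 - 1)/5 = 0.8
#' newman_modularity(b, communities = rep(1, 20))  # 0
#' @export
newman_modularity <- function(x, communities = NULL, directed = FALSE) {
  A <- unclass(x)
  if (!is.matrix(A) || any(A < 0))
    stop("x must be a non-negative matrix", call. = FALSE)
  n <- max(nrow(A), ncol(A))
  if (nrow(A) != ncol(A)) {
    # embed a rectangular behavior matrix in a square adjacency, node i being
    # row i and column i at once
    sq <- matrix(0, n, n)
    sq[seq_len(nrow(A)), seq_len(ncol(A))] <- A
    A <- sq
  }
  if (is.null(communities)) {
    rm_ <- attr(x, "row_module")
    cm_ <- attr(x, "col_module")
    if (is.null(rm_) || is.null(cm_))
      stop("communities must be supplied for a non-modular matrix",
           call. = FALSE)
    communities <- integer(n)
    communities[seq_along(rm_)] <- rm_
    # column j and row j are the same node; labels must agree where both exist
    if (length(cm_) == n && any(communities[seq_along(cm_)] != cm_))
      communities[seq_along(cm_)] <- cm_
  }
  if (length(communities) != n)
    stop(sprintf("communities must label all %d nodes", n), call. = FALSE)
  if (anyNA(communities))
    stop("communities must not contain missing labels", call. = FALSE)
  # grouped per-community form of the Newman sum: exact cancellation (a
  # single all-inclusive community scores 0 with no round-off)
  groups <- split(seq_len(n), communities)
  if (directed) {
    m <- sum(A)
    if (m == 0) return(0)
    kout <- rowSums(A)
    kin <- colSums(A)
    sum(vapply(groups, function(idx)
      sum(A[idx, idx]) / m - (sum(kout[idx]) / m) * (sum(kin[idx]) / m),
      numeric(1)))
  } else {
    W <- A + t(A)
    two_m <- sum(W)
    if (two_m == 0) return(0)
    s <- rowSums(W)
    sum(vapply(groups, function(idx)
      sum(W[idx, idx]) / two_m - (sum(s[idx]) / two_m)^2, numeric(1)))
  }
}
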