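# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force so they never share code with the implementation.

# Newman modularity by literal term-by-term evaluation of the double sum
# mu = 1/(2m) sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j), on a symmetric
# weighted adjacency.
brute_force_modularity <- function(W, communities) {
  two_m <- sum(W)
  s <- rowSums(W)
  total <- 0
  for (i in seq_len(nrow(W)))
    for (j in seq_len(ncol(W)))
      if (communities[i] == communities[j])
        total <- total + (W[i, j] - s[i] * s[j] / two_m)
  total / two_m
}

# directed variant: mu = 1/m sum_ij (A_ij - kout_i kin_j / m) delta
brute_force_modularity_directed <- function(A, communities) {
  m <- sum(A)
  kout <- rowSums(A); kin <- colSums(A)
  total <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (communities[i] == communities[j])
        total <- total + (A[i, j] - kout[i] * kin[j] / m)
  total / m
}

# log2 of a binomial coefficient by explicit product of ratios
log2_choose <- function(n, k) {
  if (k < 0 || k > n) return(-Inf)
  k <- min(k, n - k)
  if (k == 0) return(0)
  sum(log2((n - k + 1):n)) - sum(log2(1:k))
}

# hand-rolled forward pass used as oracle for small networks
oracle_forward <- function(W1, B1, W2, B2, x, sigmoid_output = TRUE) {
  a1 <- as.numeric(x %*% W1) - B1
  h <- 1 / (1 + exp(-a1))
  a2 <- as.numeric(h %*% W2) - B2
  if (sigmoid_output) 1 / (1 + exp(-a2)) else a2
}

# generic discrete mutual information (the textbook double sum) evaluated on
# the joint distribution implied by a census without novel outputs:
# P(y_i) = 1/M for each original output, P(x | y_i) uniform over the n_i
# inputs mapped to y_i.
oracle_generic_mi <- function(n_i, N, M) {
  total <- 0
  for (i in seq_along(n_i)) {
    if (n_i[i] == 0) next
    p_y <- 1 / M
    for (x in seq_len(n_i[i])) {
      p_xy <- p_y * (1 / n_i[i])
      total <- total + p_xy * log2(p_xy / ((1 / N) * p_y))
    }
  }
  total
}

# row-by-row comparison oracle for fraction_learned
oracle_fraction <- function(binary, target) {
  hits <- 0
  for (i in seq_len(nrow(target)))
    if (all(binary[i, ] == target[i, ])) hits <- hits + 1
  hits / nrow(target)
}

# small trained network shared by perturbation/information tests
trained_fixture <- function(N = 15, M = 15, k = 4, R = N, seed = 7,
                            epochs = 2500, ...) {
  b <- random_behaviors(N, M, k, seed = seed)
  bottleneck_net(b, R = R, epochs = epochs, seed = seed, ...)
}

# census builder given an explicit mapping: map[i] = index of the original
# output row input i lands on, NA for a novel row
census_from_mapping <- function(original, map) {
  perturbed <- original
  for (i in seq_along(map)) {
    if (is.na(map[i])) {
      # novel row: all ones with a single zero -- cannot equal an original
      # row as long as originals have row sum < M - 1
      row <- rep(1L, ncol(original))
      row[(i %% ncol(original)) + 1L] <- 0L
      perturbed[i, ] <- row
    } else {
      perturbed[i, ] <- original[map[i], ]
    }
  }
  mapping_census(original, perturbed)
}
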