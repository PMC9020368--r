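orig6 <- unclass(random_behaviors(6, 10, k = 3, seed = 12))

test_that("census classifies unaffected, stereotyped and novel mappings", {
  # identity mapping
  cen <- mapping_census(orig6, orig6)
  expect_equal(cen$n_i, rep(1L, 6))
  expect_equal(cen$novel_count, 0L)
  expect_equal(cen$unaffected, 6L)
  # everything novel
  allnov <- census_from_mapping(orig6, rep(NA, 6))
  expect_equal(allnov$n_i, rep(0L, 6))
  expect_equal(allnov$novel_count, 6L)
  # hand-built collision: inputs 1 and 2 -> output 1, 3 -> novel, 4..6 kept
  cen2 <- census_from_mapping(orig6, c(1, 1, NA, 4, 5, 6))
  expect_equal(cen2$n_i, c(2L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(cen2$novel_count, 1L)
  expect_equal(cen2$stereotypy_count, 1L)
  expect_equal(cen2$unaffected, 4L)
  # identities: sum(n_i) + novel = N
  for (cen_ in list(cen, allnov, cen2))
    expect_equal(sum(cen_$n_i) + cen_$novel_count, cen_$N_inputs)
})

test_that("census enforces the perfect-learning premise", {
  dup <- orig6; dup[2, ] <- dup[1, ]
  expect_error(mapping_census(dup, dup), "distinct")
  expect_error(mapping_census(orig6, orig6[, 1:5]), "same shape")
})

test_that("closed-form MI equals the generic double-sum on every census", {
  maps <- list(1:6,                       # identity
               c(1, 1, 2, 4, 5, 6),      # one collision
               c(2, 1, 3, 4, 5, 6),      # pure stereotypy swap
               c(1, 1, 1, 4, 4, 6))      # heavier collisions
  for (map in maps) {
    cen <- census_from_mapping(orig6, map)
    expect_equal(mutual_information(cen),
                 oracle_generic_mi(cen$n_i, cen$N_inputs, cen$M_outputs),
                 tolerance = 1e-12)
  }
})

test_that("MI identities: perfect mapping, null census, and the robustness form", {
  # unperturbed perfect mapping carries log2(N) bits
  expect_equal(mutual_information(mapping_census(orig6, orig6)), log2(6),
               tolerance = 1e-12)
  # no information at all
  expect_equal(mutual_information(census_from_mapping(orig6, rep(NA, 6))), 0)
  # without stereotypy, MI = (conserved / M) * log2 N exactly
  for (conserved in c(1, 3, 5)) {
    map <- rep(NA, 6); map[seq_len(conserved)] <- seq_len(conserved)
    cen <- census_from_mapping(orig6, map)
    expect_equal(mutual_information(cen), (conserved / 6) * log2(6),
                 tolerance = 1e-12)
  }
})

test_that("MI is bounded by [0, log2 N] over random censuses", {
  set.seed(99)
  for (i in 1:20) {
    map <- sample(c(NA, 1:6), 6, replace = TRUE)
    cen <- census_from_mapping(orig6, map)
    mi <- mutual_information(cen)
    expect_gte(mi, 0)
    expect_lte(mi, log2(6) + 1e-12)
  }
})

test_that("perturbed networks without stereotypy obey MI = robustness * log2(N)", {
  f <- trained_fixture(N = 15, M = 15, k = 4, R = 15, seed = 31, epochs = 3000)
  base <- binarize(net_forward(f))
  for (u in 1:5) {
    p <- perturb(f, u)
    cen <- mapping_census(base, p$perturbed)
    if (cen$stereotypy_count == 0)
      expect_equal(mutual_information(cen),
                   (cen$unaffected / cen$M_outputs) * log2(cen$N_inputs),
                   tolerance = 1e-12)
  }
})

test_that("state-dependency MI falls as the bottleneck tightens", {
  ens <- lapply(1:3, function(s) random_behaviors(20, 20, 4, seed = s + 3))
  sdc <- state_dependency_curve(ens, R_grid = c(5, 20), epochs = 3000,
                                seed = 2)
  expect_true(all(is.finite(sdc$curve$mean_mi)))
  expect_true(all(diff(sdc$curve$mean_mi) > 0))
  # over-provisioned, effect-free perturbation recovers log2 N per unit:
  # clamp a disconnected unit on a hand-built network
  f <- trained_fixture(N = 12, M = 12, k = 3, R = 12, seed = 8, epochs = 2500)
  f$W2[4, ] <- 0
  base <- binarize(net_forward(f))
  cen <- mapping_census(base, perturb(f, 4)$perturbed)
  expect_equal(mutual_information(cen), log2(12), tolerance = 1e-12)
})
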