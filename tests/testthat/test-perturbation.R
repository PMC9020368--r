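fit20 <- trained_fixture(N = 20, M = 20, k = 5, R = 20, seed = 17,
                         epochs = 3000)

test_that("perturbation outcomes satisfy their accounting identities", {
  p <- perturb(fit20, units = 3)
  expect_true(all(p$flip_map %in% c(-1L, 0L, 1L)))
  expect_equal(p$robustness, mean(p$conserved))
  expect_equal(p$affected_count, nrow(p$flip_map) - sum(p$conserved))
  expect_equal(p$conserved, rowSums(p$flip_map != 0) == 0)
  # flip_map entries recomputed element-wise from the two output matrices
  expect_true(all((p$flip_map == 1L) == (p$perturbed == 1L & p$unperturbed == 0L)))
  expect_true(all((p$flip_map == -1L) == (p$perturbed == 0L & p$unperturbed == 1L)))
  expect_error(perturb(fit20, units = 0), "hidden-unit")
  expect_error(perturb(fit20, units = c(1, 1)), "distinct")
})

test_that("clamp and weight-injection agree on all binarized outputs", {
  for (mode in c("activate", "deactivate")) {
    for (u in seq_len(fit20$R)) {
      pc <- perturb(fit20, u, mode = mode, mechanism = "clamp")
      pw <- perturb(fit20, u, mode = mode, mechanism = "weight_injection")
      expect_identical(pc$perturbed, pw$perturbed)
    }
  }
})

test_that("a perturbation with no effect leaves every behavior conserved", {
  # hidden unit with all-zero outgoing weights: clamping it changes nothing
  f <- fit20
  f$W2[5, ] <- 0
  f$fitted <- net_forward(f)
  p_off <- perturb(f, 5, mode = "deactivate")
  p_on <- perturb(f, 5, mode = "activate")
  for (p in list(p_off, p_on)) {
    expect_equal(p$robustness, 1.0)
    expect_true(all(p$flip_map == 0L))
    expect_equal(p$affected_count, 0L)
  }
  # clamping a unit to the value it already saturates at is idempotent
  g <- fit20
  g$B1[2] <- -1e4             # unit 2 saturates on for every input
  expect_equal(perturb(g, 2, mode = "activate")$robustness, 1.0)
})

test_that("network_robustness averages over units and enumerates pairs", {
  rb <- network_robustness(fit20)
  expect_length(rb$per_unit, fit20$R)
  expect_equal(rb$robustness, mean(rb$per_unit))
  rp <- network_robustness(fit20, mode = "activate_pair", max_pairs = 10,
                           seed = 1)
  expect_length(rp$per_unit, 10)
  expect_true(all(vapply(rp$outcomes, function(o) length(o$units), 0L) == 2L))
})

test_that("affected_distribution conserves the number of perturbations", {
  rb <- network_robustness(fit20)
  h <- affected_distribution(rb$outcomes)
  expect_equal(sum(h), length(rb$outcomes))
  # all-null perturbations give a point mass at zero
  f <- fit20; f$W2[] <- 0; f$B2[] <- 10
  null_out <- lapply(1:4, function(u) perturb(f, u))
  h0 <- affected_distribution(null_out)
  expect_equal(as.integer(h0["0"]), 4L)
  expect_equal(sum(h0), 4)
  expect_error(affected_distribution(list()), "no outcomes")
})

test_that("robustness grows with the hidden layer and deactivation mirrors activation", {
  ens <- lapply(1:3, function(s) random_behaviors(24, 24, 4, seed = s + 7))
  act <- robustness_curve(ens, R_grid = c(6, 12, 24), epochs = 2500, seed = 3)
  expect_true(all(diff(act$curve$mean_robustness) > 0))
  deact <- robustness_curve(ens, R_grid = c(6, 12, 24), mode = "deactivate",
                            epochs = 2500, seed = 3)
  expect_true(all(diff(deact$curve$mean_robustness) > 0))
  # over-provisioned networks are nearly immune to single-unit perturbation
  expect_gt(act$curve$mean_robustness[act$curve$R == 24], 0.9)
})

test_that("modular perturbation effects concentrate within one module", {
  # at the critical region of a perfectly modular instance, the behaviors a
  # single activation affects come predominantly from one block
  b <- modular_behaviors(30, 30, k = 6, m = 5, sigma = 0, seed = 23)
  f <- bottleneck_net(b, R = 10, epochs = 8000, seed = 4)
  rb <- network_robustness(f)
  rm_ <- attr(b, "row_module")
  modal_frac <- vapply(rb$outcomes, function(o) {
    hit <- rm_[!o$conserved]
    if (length(hit) == 0) NA_real_ else max(table(hit)) / length(hit)
  }, numeric(1))
  # chance level is 1/5 of affected rows per module
  expect_gt(mean(modal_frac, na.rm = TRUE), 0.4)
})
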