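test_that("the pathwise fitness difference obeys the detailed relation", {
  m <- fixture_model()
  y <- c(1, 2, 1, 3)
  z <- c(2, 1, 1, 2)
  g <- fitness_difference_g(m, y, z)
  # both sides computed through independent enumeration
  pbi <- oracle_pbi(m, y)
  ps <- exp(sensing_logprob(m, z, y))
  iz <- which(apply(all_idx(2, 3), 1, function(v) all(v == z)))
  expect_equal(exp(-g), pbi[iz] / ps, tolerance = 1e-10)
  # degenerate cases
  ds <- deterministic_sensing_model()
  expect_equal(fitness_difference_g(ds, c(1, 2, 2), c(1, 2, 2)), 0,
               tolerance = 1e-12)
  ck <- constant_k_model(0.7)
  expect_equal(fitness_difference_g(ck, c(1, 2, 1), c(2, 2, 1)), 0,
               tolerance = 1e-12)
})

test_that("the detailed relation holds pathwise across whole models", {
  expect_lt(check_detailed_fr_g(fixture_model(), 3), 1e-10)
  expect_lt(check_detailed_fr_g(random_model(c(2, 3, 2), seed = 11), 3), 1e-10)
  expect_equal(check_detailed_fr_g(random_model(c(2, 2, 1), seed = 2), 3), 0)
})

test_that("exact integral fluctuation relations integrate to one", {
  m <- fixture_model()
  expect_equal(ifr_exact(m, "g", 4), 1, tolerance = 1e-10)
  expect_equal(ifr_exact(m, "gamma_sigma", 4), 1, tolerance = 1e-10)
  # any valid model, including random ones with memoryful kernels
  r <- random_model(c(2, 2, 3), seed = 19, memoryless = FALSE)
  expect_equal(ifr_exact(r, "g", 3), 1, tolerance = 1e-10)
  rd <- random_model(c(3, 2, 2), seed = 23, with_decomposition = TRUE)
  expect_equal(ifr_exact(rd, "g", 3), 1, tolerance = 1e-10)
  expect_equal(ifr_exact(rd, "gamma_sigma", 3), 1, tolerance = 1e-10)
  # degenerate one-state model: the integrand is identically 1
  expect_equal(ifr_exact(one_state_model(), "g", 3), 1, tolerance = 1e-12)
  expect_equal(ifr_exact(one_state_model(), "psi0_i_g", 3), 1,
               tolerance = 1e-12)
})

test_that("the posterior-path relation integrates to one from a known start", {
  # the reference measure of this relation carries no distribution over the
  # initial environment state: from a deterministic start the expectation is
  # exactly 1, from a stochastic start it equals the size of the support
  m <- fixture_model()
  expect_equal(ifr_exact(point_start(m), "psi0_i_g", 3), 1, tolerance = 1e-10)
  expect_equal(ifr_exact(point_start(m, 3), "psi0_i_g", 3), 1,
               tolerance = 1e-10)
  expect_equal(ifr_exact(m, "psi0_i_g", 3), 3, tolerance = 1e-10)
  rd <- point_start(random_model(c(2, 2, 2), seed = 31,
                                 with_decomposition = TRUE))
  expect_equal(ifr_exact(rd, "psi0_i_g", 3), 1, tolerance = 1e-10)
})

test_that("Monte Carlo runs are reproducible and consistent with Jensen", {
  m <- fixture_model()
  a <- ifr_monte_carlo(m, "g", t = 6, n = 400, seed = 5)
  b <- ifr_monte_carlo(m, "g", t = 6, n = 400, seed = 5)
  expect_identical(a, b)
  expect_length(a$running_average, 400)
  # constant k: every integrand equals 1 exactly
  ck <- ifr_monte_carlo(constant_k_model(0.3), "g", t = 8, n = 50, seed = 1)
  expect_equal(ck$integrand_samples, rep(1, 50), tolerance = 1e-12)
  # e^{-g} averages to 1 while <g> = G > 0: positive and negative g coexist
  mc <- ifr_monte_carlo(m, "g", t = 10, n = 20000, seed = 7)
  gvals <- -log(mc$integrand_samples)
  expect_gt(mean(gvals), 0)
  se <- stats::sd(mc$integrand_samples) / sqrt(mc$n_samples)
  expect_lt(abs(mc$running_average[mc$n_samples] - 1), 3 * se)
  # running averages tighten with n (1/sqrt(n) envelope, coarse check)
  dev_early <- abs(mean(mc$integrand_samples[1:500]) - 1)
  dev_late <- abs(mc$running_average[mc$n_samples] - 1)
  expect_lt(dev_late, dev_early + 3 * se)
  ex <- ifr_monte_carlo(m, "gamma_sigma", t = 4, n = 100, seed = 2,
                        exact = TRUE)
  expect_equal(ex$exact_value, 1, tolerance = 1e-10)
})

test_that("average fluctuation-relation residuals vanish", {
  m <- fixture_model()
  rp <- average_fr_report(m, 4)
  expect_setequal(rp$relation,
                  c("gain", "fitness_decomposition", "fidelity",
                    "individual_balance", "common_balance"))
  expect_lt(max(abs(rp$residual)), 1e-9)
  # constant k: no gain, and the information terms cancel
  ckm <- constant_k_model(0.3)
  ckd <- decompose_replication(ckm, pin = c(y1 = 2 * exp(0.3)))
  rp2 <- average_fr_report(ckd, 3)
  expect_lt(max(abs(rp2$residual)), 1e-9)
  expect_equal(rp2$lhs[rp2$relation == "gain"] -
                 rp2$rhs[rp2$relation == "gain"], 0, tolerance = 1e-12)
  # random-model sweep
  for (seed in 1:10) {
    r <- random_model(c(2, 2, 2), seed, with_decomposition = TRUE)
    expect_lt(max(abs(average_fr_report(r, 3)$residual)), 1e-9)
  }
})
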