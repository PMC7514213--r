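test_that("the fitness gain G vanishes without selection bias and matches the average FR", {
  expect_equal(fitness_gain_G(constant_k_model(0.3), 3), 0, tolerance = 1e-12)
  expect_equal(fitness_gain_G(deterministic_sensing_model(), 3), 0,
               tolerance = 1e-12)
  m <- fixture_model()
  G <- fitness_gain_G(m, 2)
  # independent route: exhaustive oracle averaging of Psi_i and Psi_c
  av <- oracle_averages(m, 2)
  expect_equal(G, av$psi_i - av$psi_c, tolerance = 1e-10)
  expect_gte(G, 0)
  # and the packaged exact averages agree with the oracle
  pav <- psi_averages(m, 2)
  expect_equal(pav$psi_i, av$psi_i, tolerance = 1e-10)
  expect_equal(pav$psi_c, av$psi_c, tolerance = 1e-10)
})

test_that("allocation-history probabilities normalize and match triple enumeration", {
  m <- fixture_model()
  y <- c(1, 1, 1, 1)
  expect_equal(pkfs(m, y, y), oracle_pkfs(m, y, y), tolerance = 1e-10)
  ya <- c(1, 3, 2, 1)
  expect_equal(pkfs(m, ya, y), oracle_pkfs(m, ya, y), tolerance = 1e-10)
  # normalization over all allocation histories for a fixed realization
  Yg <- all_idx(3, 2)
  y2 <- c(2, 1, 3)
  tot <- sum(apply(Yg, 1, function(a) pkfs(m, a, y2)))
  expect_equal(tot, 1, tolerance = 1e-9)
  # one-state environment: allocation is always correct
  expect_equal(pkfs(one_state_model(), c(1, 1, 1), c(1, 1, 1)), 1)
  expect_error(pkfs(random_model(c(2, 2, 2), 1), c(1, 2), c(1, 2)),
               "decomposition")
})

test_that("sigma satisfies the pathwise fitness decomposition", {
  m <- fixture_model()
  for (y in list(c(1, 1, 1, 1), c(1, 2, 3, 1), c(3, 3, 2, 1))) {
    lhs <- sigma_of_history(m, y)
    # independent chain: sigma = Psi_i - Psi_0 with each term computed on its own
    psi0 <- kmax_fitness(m, y) + env_logprob(m, y)
    expect_equal(lhs, fitness_individual(m, y) - psi0, tolerance = 1e-10)
    # and via the enumeration oracle for PKFS
    expect_equal(lhs, log(oracle_pkfs(m, y, y)) - env_logprob(m, y),
                 tolerance = 1e-10)
  }
  expect_equal(sigma_of_history(one_state_model(), c(1, 1, 1)), 0)
})

test_that("fidelity report: gamma, P_gamma and the average sigma identity", {
  m <- fixture_model()
  fid <- gamma_and_pgamma(m, 4)
  expect_equal(sum(fid$p_gamma), 1, tolerance = 1e-12)
  expect_equal(fid$gamma_total, gamma_total(m, 4), tolerance = 1e-12)
  # <sigma>_Q + D[Q || P_gamma] = gamma_t
  Yg <- all_idx(3, 4)
  q <- apply(Yg, 1, function(y) exp(env_logprob(m, y)))
  sig_avg <- sum(q * fid$sigma_by_history)
  expect_equal(sig_avg + fid$kl_env_pgamma, fid$gamma_total,
               tolerance = 1e-10)
  expect_gte(fid$kl_env_pgamma, 0)
  # perfect machinery: every history decoded correctly
  pm <- perfect_machinery_model()
  fp <- gamma_and_pgamma(pm, 3)
  expect_equal(fp$gamma_total, log(2^4), tolerance = 1e-12)
  expect_equal(unname(fp$p_gamma), rep(1 / 16, 16), tolerance = 1e-12)
  # one-state environment: no fidelity to gain
  f1 <- gamma_and_pgamma(one_state_model(), 3)
  expect_equal(f1$gamma_total, 0, tolerance = 1e-12)
  expect_equal(f1$kl_env_pgamma, 0, tolerance = 1e-12)
})

test_that("Bayesian kernels invert the sensing chain and rebuild the joint law", {
  m <- fixture_model()
  bk <- bayes_kernels(m)
  expect_equal(bk$signal_predictive["s1y", "s1z"],
               0.8 * 0.7 + 0.2 * 0.25 + 0.5 * 0.05)
  expect_equal(bk$env_posterior["s1y", "s1z", "s1y"], 0.8 * 0.7 / 0.635,
               tolerance = 1e-12)
  expect_lt(max(abs(rowSums(bk$signal_predictive) - 1)), 1e-9)
  expect_lt(max(abs(apply(bk$env_posterior, c(1, 2), sum) - 1)), 1e-9)
  # reconstruction: TSB(z'|y) TSB(y'|z',y) = TS(z'|y') TEF(y'|y) for all triples
  for (y in 1:3) for (zp in 1:2) for (yp in 1:3)
    expect_equal(bk$signal_predictive[y, zp] * bk$env_posterior[y, zp, yp],
                 m$sensing$kernel[1, yp, zp] * m$env$transition[y, yp],
                 tolerance = 1e-12)
  # uninformative sensing: the posterior falls back to the prior
  u <- random_model(c(2, 3, 2), seed = 2)
  u$sensing$kernel[] <- 0.5
  u$sensing$initial[] <- 0.5
  bu <- bayes_kernels(u)
  for (zp in 1:2)
    expect_equal(matrix(bu$env_posterior[, zp, ], 3, 3), unname(u$env$transition),
                 tolerance = 1e-12)
  expect_error(bayes_kernels(random_model(c(2, 2, 2), 3, memoryless = FALSE)),
               "memoryless")
})

test_that("the joint forward law factorizes through the Bayesian kernels", {
  m <- fixture_model()
  t <- 3
  Yg <- all_idx(3, t)
  Zg <- all_idx(2, t)
  bk <- bayes_kernels(m)
  for (i in seq(1, nrow(Yg), by = 7)) {
    y <- Yg[i, ]
    for (j in seq_len(nrow(Zg))) {
      z <- Zg[j, ]
      fwd <- exp(env_logprob(m, y) + sensing_logprob(m, z, y))
      psb_env <- bk$initial_posterior[z[1], y[1]]
      psb_sig <- bk$initial_signal[z[1]]
      for (tau in seq_len(t)) {
        psb_env <- psb_env * bk$env_posterior[y[tau], z[tau + 1], y[tau + 1]]
        psb_sig <- psb_sig * bk$signal_predictive[y[tau], z[tau + 1]]
      }
      expect_equal(unname(psb_env * psb_sig), fwd, tolerance = 1e-12)
    }
  }
})

test_that("directed information is non-negative and matches closed forms", {
  # uninformative sensing carries no directed information
  u <- random_model(c(2, 2, 2), seed = 6)
  u$sensing$kernel[] <- 0.5
  u$sensing$initial[] <- 0.5
  expect_equal(directed_information(u, 3), 0, tolerance = 1e-12)
  expect_equal(pointwise_directed_info(u, c(1, 2, 1), c(2, 1, 1)), 0,
               tolerance = 1e-12)
  # deterministic sensing of a uniform i.i.d. 2-state environment:
  # each of the t+1 perfectly revealed symbols is worth ln 2
  d <- deterministic_sensing_model()
  d$env$transition[] <- 0.5
  d$env$initial[] <- 0.5
  expect_equal(directed_information(d, 1), 2 * log(2), tolerance = 1e-12)
  expect_equal(directed_information(d, 3), 4 * log(2), tolerance = 1e-12)
  # one signal state can never inform
  s1 <- random_model(c(2, 2, 1), seed = 9)
  expect_equal(directed_information(s1, 2), 0, tolerance = 1e-12)
  expect_gte(directed_information(fixture_model(), 3), 0)
})

test_that("the inference loss closes the directed-information balances", {
  # identities <Psi_i> = <Psi_0> + I + G - Dloss and
  # <Psi_c> = <Psi_0> + I - Dloss hold for any initial distribution
  for (seed in c(3, 11)) {
    r <- random_model(c(2, 2, 2), seed, with_decomposition = TRUE)
    av <- psi_averages(r, 3)
    I <- directed_information(r, 3)
    dl <- dloss(r, 3)
    G <- fitness_gain_G(r, 3)
    expect_equal(av$psi_i, av$psi0 + I + G - dl, tolerance = 1e-10)
    expect_equal(av$psi_c, av$psi0 + I - dl, tolerance = 1e-10)
  }
  # with a known initial environment state the loss is a true divergence
  m <- point_start(fixture_model())
  expect_gte(dloss(m, 3), 0)
  expect_error(dloss(random_model(c(2, 2, 2), 1), 3), "decomposition")
})

test_that("the measures report collects consistent columns per horizon", {
  m <- fixture_model()
  rp <- measures_report(m, 1:2)
  expect_equal(rp$t, 1:2)
  expect_equal(rp$G, rp$psi_i_avg - rp$psi_c_avg, tolerance = 1e-10)
  expect_equal(rp$psi_i_avg, rp$psi0_avg + rp$gamma - rp$kl_q_pgamma,
               tolerance = 1e-10)
  expect_equal(rp$psi_c_avg, rp$psi0_avg + rp$I_directed - rp$Dloss,
               tolerance = 1e-10)
})
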