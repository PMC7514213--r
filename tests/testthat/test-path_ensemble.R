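test_that("path log-probabilities match the kernel products and normalize", {
  m <- fixture_model()
  mp <- point_start(m)
  expect_equal(env_logprob(mp, c("s1y", "s1y")), log(0.70))
  expect_equal(sensing_logprob(m, c("s1z", "s1z"), c("s1y", "s1y")),
               log(0.8) + log(0.8))
  expect_equal(switching_logprob(m, c("s1x", "s1x"), c("s1z", "s1z")),
               log(0.95) + log(0.95))
  expect_equal(env_logprob(one_state_model(), rep(1, 6)), 0)
  expect_equal(sensing_logprob(one_state_model(), rep(1, 4), rep(1, 4)), 0)

  # exhaustive normalization of each path measure at t = 4
  t <- 4
  Yg <- all_idx(3, t)
  expect_equal(sum(exp(apply(Yg, 1, function(y) env_logprob(m, y)))), 1)
  y <- c(1, 2, 3, 1, 2)
  Zg <- all_idx(2, t)
  expect_equal(sum(exp(apply(Zg, 1, function(z) sensing_logprob(m, z, y)))), 1)
  z <- c(2, 1, 1, 2, 1)
  Xg <- all_idx(2, t)
  expect_equal(sum(exp(apply(Xg, 1, function(x) switching_logprob(m, x, z)))), 1)
  expect_error(sensing_logprob(m, c(1, 1), c(1, 2, 1)), "horizons differ")
  expect_error(env_logprob(m, c("bogus", "s1y")), "alphabet")
})

test_that("historical fitness sums the realized log rates", {
  m <- fixture_model()
  expect_equal(historical_fitness(m, "s1x", "s2y"), 0)       # t = 0
  expect_equal(historical_fitness(m, c("s1x", "s1x"), c("s1y", "s1y")),
               log(2.24))
  ck <- constant_k_model(0.25)
  expect_equal(historical_fitness(ck, c(1, 2, 1, 2), c(2, 1, 1, 2)), 3 * 0.25)
  expect_equal(kmax_fitness(m, "s1y"), 0)
  expect_equal(kmax_fitness(m, c("s3y", "s1y")), log(5.12))
  expect_error(kmax_fitness(random_model(c(2, 2, 2), 1), c(1, 2)),
               "decomposition")
})

test_that("fitness recursions agree with exhaustive path sums", {
  m <- fixture_model()
  y <- c(1, 1, 1, 2)
  expect_equal(fitness_individual(m, y), oracle_psi_i(m, y), tolerance = 1e-10)
  z <- c(1, 2, 2, 1)
  expect_equal(fitness_common(m, y, z), oracle_psi_c(m, y, z),
               tolerance = 1e-10)
  # random-model sweep (the DP-oracle equivalence property)
  for (seed in 1:6) {
    r <- random_model(c(3, 2, 3), seed, rate_scale = 1.5,
                      memoryless = seed %% 2 == 0)
    yr <- all_idx(2, 3)[seed + 3, ]
    zr <- all_idx(3, 3)[2 * seed, ]
    expect_equal(fitness_individual(r, yr), oracle_psi_i(r, yr),
                 tolerance = 1e-10)
    expect_equal(fitness_common(r, yr, zr), oracle_psi_c(r, yr, zr),
                 tolerance = 1e-10)
  }
})

test_that("fitness degenerates correctly at horizon 0 and constant rates", {
  m <- fixture_model()
  expect_equal(fitness_individual(m, "s2y"), 0)
  expect_equal(fitness_common(m, "s2y", "s1z"), 0)
  ck <- constant_k_model(0.4)
  y <- c(1, 2, 2, 1, 2)
  expect_equal(fitness_individual(ck, y), 4 * 0.4)
  expect_equal(fitness_common(ck, y, c(2, 1, 1, 2, 2)), 4 * 0.4)
  # deterministic sensing: the two recursions coincide on the forced signal
  ds <- deterministic_sensing_model()
  y2 <- c(1, 2, 1, 1)
  expect_equal(fitness_common(ds, y2, y2), fitness_individual(ds, y2),
               tolerance = 1e-12)
})

test_that("retrospective distributions are normalized and selection-biased", {
  m <- fixture_model()
  y <- c(1, 1, 1, 1)
  pb <- retrospective_sensing_dist(m, y)
  expect_length(pb, 2^4)
  expect_equal(sum(pb), 1, tolerance = 1e-9)
  expect_equal(unname(pb), oracle_pbi(m, y), tolerance = 1e-10)
  # no selection (constant k): retrospective equals forward
  ck <- constant_k_model(0.2)
  y2 <- c(1, 2, 2)
  pb2 <- retrospective_sensing_dist(ck, y2)
  fwd <- apply(all_idx(2, 2), 1, function(z) exp(sensing_logprob(ck, z, y2)))
  expect_equal(unname(pb2), fwd, tolerance = 1e-12)
  # absolute continuity: zero forward probability implies zero retrospective
  zs <- deterministic_sensing_model()
  pbz <- retrospective_sensing_dist(zs, c(1, 2, 1))
  fwdz <- apply(all_idx(2, 2), 1, function(z) exp(sensing_logprob(zs, z, c(1, 2, 1))))
  expect_true(all(pbz[fwdz == 0] == 0))

  pbc <- retrospective_phenotype_dist(m, c(1, 2, 1), c(1, 2, 2))
  expect_equal(sum(pbc), 1, tolerance = 1e-9)
  # constant k: retrospective phenotype law equals the forward switching law
  pbc2 <- retrospective_phenotype_dist(ck, y2, c(2, 1, 1))
  fwdx <- apply(all_idx(2, 2), 1,
                function(x) exp(switching_logprob(ck, x, c(2, 1, 1))))
  expect_equal(unname(pbc2), fwdx, tolerance = 1e-12)
})

test_that("history enumeration is lexicographic and guarded", {
  e <- enumerate_histories(c("a", "b"), 2)
  expect_equal(nrow(e), 8)
  expect_equal(e[1, ], c("a", "a", "a"))
  expect_equal(e[2, ], c("a", "a", "b"))
  expect_equal(e[8, ], c("b", "b", "b"))
  expect_equal(nrow(enumerate_histories(c("a", "b", "c"), 5)), 729)
  expect_equal(nrow(enumerate_histories("only", 5)), 1)
  expect_error(enumerate_histories(c("a", "b"), 40), "guard")
})

test_that("the exhaustive environment ensemble log-sum-exps to zero", {
  m <- fixture_model()
  pe <- env_path_ensemble(m, 3)
  expect_s3_class(pe, "path_ensemble")
  mx <- max(pe$log_weight)
  expect_equal(mx + log(sum(exp(pe$log_weight - mx))), 0, tolerance = 1e-9)
  expect_equal(attr(pe, "kind"), "exhaustive")
})
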