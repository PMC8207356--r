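test_that("depletion integrator: closed-form limits and domain checks", {
  expect_equal(integrate_depletion(1.5, 0, 2, 16, 0.75),
               16 * exp(-1.5 * 2 * 0.75), tolerance = 1e-7)
  expect_equal(integrate_depletion(1.5, 0.25, 0, 16, 0.75), 16)
  expect_equal(integrate_depletion(0, 0.25, 2, 16, 0.75), 16)
  expect_error(integrate_depletion(-1, 0.25, 1, 16, 0.75), "domain")
  n_end <- integrate_depletion(1.5, 0.25, 4, 64, 18)
  expect_true(n_end >= 0 && n_end <= 64)
})

test_that("the ODE integral coincides with the Rogers closed form under the
          predator-time substitution", {
  set.seed(7)
  for (i in 1:25) {
    N0 <- sample(2:64, 1); a <- runif(1, 0.01, 5); h <- runif(1, 0, 1)
    P <- sample(1:4, 1); T <- sample(c(0.5, 0.75, 1), 1)
    eaten_ode <- N0 - integrate_depletion(a, h, P, N0, T)
    eaten_cf <- rogers_expected_eaten(N0, a, h, T, P = P)
    expect_lt(abs(eaten_ode - eaten_cf), 1e-6 * N0)
  }
})

test_that("interaction strength is the proportion killed", {
  expect_equal(interaction_strength(16, 16), 0)
  expect_equal(interaction_strength(16, 0), 1)
  expect_equal(interaction_strength(8, 6), 0.25)
  expect_equal(interaction_strength(c(16, 8), c(0, 6)), c(1, 0.25))
  expect_error(interaction_strength(0, 0), "domain")
  expect_error(interaction_strength(8, 9), "domain")
})

test_that("trophic prediction is a proportion, increasing in predator
          density, and consistent with the closed form at P = 1", {
  f <- fake_fr_fit(1.52, 0.25)
  is_t <- vapply(1:4, function(P) predict_trophic_IS(f, 8, P), numeric(1))
  expect_true(all(is_t >= 0 & is_t <= 1))
  expect_true(all(diff(is_t) > 0))
  expect_equal(is_t,
               vapply(1:4, function(P)
                 rogers_expected_eaten(8, 1.52, 0.25, 0.75, P = P) / 8,
                 numeric(1)),
               tolerance = 1e-6)
  expect_equal(predict_trophic_IS(fake_fr_fit(0 + 1e-300, 0.25), 8, 2), 0,
               tolerance = 1e-10)
  bad <- fake_fr_fit(1, 0.2); bad$converged <- FALSE
  expect_error(predict_trophic_IS(bad, 8, 2), "converge")
})

test_that("IS decomposition: identity, volume routing, and error on a
          missing fit", {
  tr <- simulate_experiment(experiment_design(), default_generator_params(),
                            seed = 17)
  fits <- list(`40` = fake_fr_fit(1.5, 0.25), `80` = fake_fr_fit(0.8, 0.28))
  rec <- nontrophic_IS(tr, fits)
  expect_identical(nrow(rec), 240L)           # controls excluded
  expect_true(all(rec$predator_count >= 1))
  expect_equal(rec$is_nontrophic, rec$is_observed - rec$is_trophic)
  expect_true(all(rec$is_observed >= 0 & rec$is_observed <= 1))
  expect_true(all(rec$is_trophic >= 0 & rec$is_trophic <= 1))
  expect_true(all(abs(rec$is_nontrophic) <= 1))
  # same cell, same volume -> same trophic prediction
  cell <- rec[rec$volume_ml == 40 & rec$prey_density_initial == 8 &
                rec$predator_count == 2, ]
  expect_equal(length(unique(cell$is_trophic)), 1L)
  # predictions must come from the trial's own volume's fit
  one_vol <- list(`40` = fake_fr_fit(1.5, 0.25))
  expect_error(nontrophic_IS(tr, one_vol), "80")
})

test_that("strong interference yields negative mean IS_NT at high predator
          density; the additive case does not", {
  des <- experiment_design(volume_levels_ml = 80)
  anta <- simulate_experiment(des, generator_params(interference = 2),
                              seed = 23)
  fit <- fit_rogers(anta[anta$predator_count == 1, ], T = 0.75)
  rec <- nontrophic_IS(anta, fit)
  expect_lt(mean(rec$is_nontrophic[rec$predator_count == 4]), -0.05)

  addi <- simulate_experiment(des, generator_params(interference = 0),
                              seed = 24)
  fit0 <- fit_rogers(addi[addi$predator_count == 1, ], T = 0.75)
  rec0 <- nontrophic_IS(addi, fit0)
  m <- mean(rec0$is_nontrophic)
  mc_se <- stats::sd(rec0$is_nontrophic) / sqrt(nrow(rec0))
  expect_lt(abs(m), 6 * mc_se)  # loose single-experiment check
})

test_that("Latin hypercube band: stratification, determinism, degeneracy
          and containment", {
  f <- fake_fr_fit(1.52, 0.25, se_a = 0.93, se_h = 0.05)
  b1 <- lhs_sensitivity(f, 16, 2, n_draws = 100, seed = 5)
  b2 <- lhs_sensitivity(f, 16, 2, n_draws = 100, seed = 5)
  expect_identical(b1$draws, b2$draws)
  expect_identical(nrow(b1$draws), 100L)
  # one draw per equal-probability stratum per marginal
  for (p in c("a", "h")) {
    rng <- b1$ranges[p, ]
    stratum <- floor(100 * (b1$draws[[p]] - rng[1]) / (rng[2] - rng[1]))
    expect_setequal(pmin(stratum, 99), 0:99)
  }
  # negative lower CI bound for a is truncated at a positive floor
  expect_gte(min(b1$draws$a), 1e-12)
  # band contains the point prediction
  expect_true(b1$quantiles[1] <= b1$point && b1$point <= b1$quantiles[3])

  expect_warning(b0 <- lhs_sensitivity(fake_fr_fit(1.5, 0.25), 16, 2,
                                       n_draws = 10, seed = 1),
                 "point estimate")
  expect_equal(max(abs(b0$draws$prop_killed - b0$point)), 0, tolerance = 1e-9)

  # widening the SEs never narrows the band
  wide <- lhs_sensitivity(fake_fr_fit(1.52, 0.25, se_a = 1.5, se_h = 0.1),
                          16, 2, n_draws = 100, seed = 5)
  expect_gte(diff(range(wide$draws$prop_killed)) + 1e-12,
             diff(range(b1$draws$prop_killed)))
})
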