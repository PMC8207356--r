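test_that("random predator closed form: limits, bounds and monotonicity", {
  expect_equal(rogers_expected_eaten(16, 0, 0.25, 0.75), 0)
  expect_equal(rogers_expected_eaten(0, 1.5, 0.25, 0.75), 0)
  expect_equal(rogers_expected_eaten(16, 1.5, 0.25, 0.75, P = 0), 0)
  # h = 0 reduces to simple exponential depletion
  expect_equal(rogers_expected_eaten(16, 1.5, 0, 0.75),
               16 * (1 - exp(-1.5 * 0.75)), tolerance = 1e-12)
  expect_error(rogers_expected_eaten(16, -1, 0.25, 0.75), "domain")
  expect_error(rogers_expected_eaten(16, 1, 0.25, 0), "domain")

  # nondecreasing in a, T, P, N0; nonincreasing in h; bounded by N0
  a_seq <- seq(0.01, 5, length.out = 25)
  ne_a <- vapply(a_seq, function(a)
    rogers_expected_eaten(16, a, 0.25, 0.75), numeric(1))
  expect_true(all(diff(ne_a) >= -1e-12))
  h_seq <- seq(0, 1, length.out = 25)
  ne_h <- vapply(h_seq, function(h)
    rogers_expected_eaten(16, 1.5, h, 0.75), numeric(1))
  expect_true(all(diff(ne_h) <= 1e-12))
  ne_P <- vapply(1:4, function(P)
    rogers_expected_eaten(16, 1.5, 0.25, 0.75, P = P), numeric(1))
  expect_true(all(diff(ne_P) >= 0))
  ne_N <- vapply(c(2, 4, 8, 16, 32, 64), function(n)
    rogers_expected_eaten(n, 1.5, 0.25, 0.75), numeric(1))
  expect_true(all(diff(ne_N) >= 0))
  expect_true(all(ne_N <= c(2, 4, 8, 16, 32, 64)))
})

test_that("Lambert W evaluation matches the bisection root of the implicit
          equation", {
  grid <- expand.grid(N0 = c(2, 8, 64), a = c(0.01, 1.52, 5),
                      h = c(0, 0.25, 1), T = c(0.75, 18))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_lt(abs(rogers_expected_eaten(g$N0, g$a, g$h, g$T) -
                    bisection_rogers(g$N0, g$a, g$h, g$T)), 1e-8)
  }
  # overflow-scale Lambert argument still finite and bounded
  big <- rogers_expected_eaten(64, 5, 1, 18)
  expect_true(is.finite(big) && big <= 64 && big >= 0)
})

test_that("type classification detects declining, flat and rising
          proportions", {
  des <- sp_design(replicates = 5)
  tr <- simulate_experiment(des, generator_params(), seed = 21)
  cl <- classify_fr_type(tr)
  expect_identical(cl$classification, "type II")
  expect_lt(cl$linear_coefficient, 0)
  expect_lt(cl$p_value, 0.05)

  # proportions identical at all densities: no density dependence
  flat <- data.frame(trial_id = as.character(1:12),
                     prey_density_initial = rep(c(4L, 8L, 16L, 32L), 3),
                     volume_ml = 80, predator_count = 1L,
                     prey_eaten = rep(c(2L, 4L, 8L, 16L), 3),
                     replicate = rep(1:3, each = 4))
  clf <- classify_fr_type(flat)
  expect_identical(clf$classification, "not type II (flat)")
  expect_lt(abs(clf$linear_coefficient), 1e-6)

  one_density <- flat[flat$prey_density_initial == 8, ]
  expect_error(classify_fr_type(one_density), "distinct prey densities")
  multi <- flat; multi$predator_count <- 2L
  expect_error(classify_fr_type(multi), "predator_count = 1")
})

test_that("fitting noiseless data on the curve recovers the parameters", {
  a_true <- 1.5; h_true <- 0.25; T <- 0.75
  N0 <- rep(c(2, 4, 8, 16, 32, 64), each = 30)
  ne <- rogers_expected_eaten(unique(N0), a_true, h_true, T)
  # integer data bracketing the expected value at each density
  Ne <- unlist(lapply(seq_along(unique(N0)), function(i) {
    lo <- floor(ne[i]); frac <- ne[i] - lo
    c(rep(lo + 1L, round(30 * frac)), rep(lo, 30 - round(30 * frac)))
  }))
  tr <- data.frame(trial_id = as.character(seq_along(N0)),
                   prey_density_initial = N0, volume_ml = 80,
                   predator_count = 1L, prey_eaten = Ne,
                   replicate = rep(1:30, times = 6))
  f <- fit_rogers(tr, T = T)
  expect_true(f$converged)
  expect_lt(abs(coef(f)["a"] / a_true - 1), 0.05)
  expect_lt(abs(coef(f)["h"] / h_true - 1), 0.05)
  # fitted likelihood at the optimum is at least that at the truth
  expect_gte(f$loglik,
             -mpefr:::.rogers_nll_log(log(c(a_true, h_true)),
                                      tr$prey_density_initial,
                                      tr$prey_eaten, T))
  # vcov well formed
  expect_true(isSymmetric(f$vcov))
  expect_true(all(diag(f$vcov) >= 0))
  expect_equal(unname(f$se), unname(sqrt(diag(f$vcov))), tolerance = 1e-12)
  ci <- confint(f)
  expect_true(all(ci[, "lower"] > 0))
  expect_true(all(ci[, "lower"] < coef(f) & coef(f) < ci[, "upper"]))
})

test_that("optimum log-likelihood dominates the generator truth across
          stochastic data sets", {
  des <- sp_design(replicates = 5)
  for (s in c(101, 202, 303)) {
    tr <- simulate_experiment(des, generator_params(), seed = s)
    f <- fit_rogers(tr, T = 0.75)
    ll_truth <- -mpefr:::.rogers_nll_log(log(c(1.5, 0.25)),
                                         tr$prey_density_initial,
                                         tr$prey_eaten, 0.75)
    expect_gte(f$loglik, ll_truth - 1e-8)
  }
})

test_that("degenerate data are flagged rather than crashing", {
  zero <- data.frame(trial_id = as.character(1:12),
                     prey_density_initial = rep(c(2L, 8L, 32L, 64L), 3),
                     volume_ml = 80, predator_count = 1L, prey_eaten = 0L,
                     replicate = rep(1:3, each = 4))
  expect_warning(f <- fit_rogers(zero, T = 0.75), "lower bound")
  expect_false(f$converged)
  expect_lt(coef(f)["a"], 1e-6)
})

test_that("delta-method comparison: zero difference on identical data,
          power on a real difference", {
  des <- sp_design(replicates = 5)
  tr <- simulate_experiment(des, generator_params(), seed = 31)
  same <- compare_params_delta(tr, tr, T = 0.75)
  expect_lt(max(abs(same$table$estimate)), 1e-6)
  expect_lt(max(abs(same$table$z), na.rm = TRUE), 1e-4)

  big <- sp_design(replicates = 30)
  trA <- simulate_experiment(big, generator_params(attack_rate = 0.8),
                             seed = 32)
  trB <- simulate_experiment(big, generator_params(attack_rate = 1.6),
                             seed = 33)
  cmp <- compare_params_delta(trA, trB, T = 0.75)
  d_a <- cmp$table[cmp$table$parameter == "D_a", ]
  expect_gt(d_a$estimate, 0)
  expect_lt(d_a$p, 0.05)
})
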