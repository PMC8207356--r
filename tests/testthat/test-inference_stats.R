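# random factorial proportion data on the standard design frame
random_fixture <- function(seed, effect = 0) {
  set.seed(seed)
  des <- expand.grid(prey = c(2, 4, 8, 16, 32, 64), vol = c(40, 80),
                     pred = 1:4, rep = 1:2)
  eta <- -0.5 + effect * (scale(log(des$prey)) + (des$pred == 4))
  p <- stats::plogis(eta + stats::rnorm(nrow(des), 0, 0.3 * (effect > 0)))
  data.frame(trial_id = as.character(seq_len(nrow(des))),
             prey_density_initial = des$prey, volume_ml = des$vol,
             predator_count = des$pred,
             prey_eaten = stats::rbinom(nrow(des), des$prey, p),
             replicate = des$rep, stringsAsFactors = FALSE)
}

test_that("sequential F statistics agree with the standard analysis of
          deviance to numerical precision", {
  for (s in 1:10) {
    tr <- random_fixture(s, effect = if (s %% 2) 0 else 0.5)
    an <- glm_quasibinomial_anodev(tr, eliminate = FALSE)
    ref <- suppressWarnings(stats::anova(an$model_full, test = "F"))
    expect_equal(an$table$F, ref$F[-1], tolerance = 1e-6)
    expect_equal(an$table$df1, ref$Df[-1])
    expect_equal(an$table$df2, ref$`Resid. Df`[-1])
    expect_gt(an$dispersion, 0)
  }
})

test_that("backward elimination keeps a strong prey-density effect and
          discards null terms", {
  tr <- random_fixture(41, effect = 1.2)
  an <- glm_quasibinomial_anodev(tr)
  tab <- an$table
  expect_true(tab$retained[tab$term == "prey_density"])
  expect_true(tab$retained[tab$term == "predator_density"])
  kept <- attr(stats::terms(an$model_final), "term.labels")
  expect_false("pred_f:vol_f:prey" %in% kept)

  null_tr <- random_fixture(42, effect = 0)
  an0 <- glm_quasibinomial_anodev(null_tr)
  expect_lt(sum(an0$table$retained), 3)
})

test_that("deviance never increases as terms are added", {
  tr <- random_fixture(7, effect = 0.5)
  an <- glm_quasibinomial_anodev(tr, eliminate = FALSE)
  # sequential deviance drops are the scaled F numerators: all nonnegative
  expect_true(all(an$table$F > -1e-10, na.rm = TRUE))
})

test_that("Tukey post hoc: adjusted p is never below unadjusted, two-level
          factors coincide", {
  tr <- random_fixture(11, effect = 0.8)
  an <- glm_quasibinomial_anodev(tr, eliminate = FALSE)
  tk <- suppressWarnings(tukey_posthoc(an$model_full, "pred_f"))
  expect_identical(nrow(tk), 6L)  # 4 levels -> 6 pairs
  expect_true(all(tk$p_adjusted >= tk$p_unadjusted - 1e-10))
  expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))

  d <- data.frame(y = rnorm(40), g = factor(rep(c("lo", "hi"), 20)))
  fit2 <- stats::lm(y ~ g, data = d)
  tk2 <- tukey_posthoc(fit2, "g")
  expect_equal(tk2$p_adjusted, tk2$p_unadjusted, tolerance = 1e-8)
  expect_error(tukey_posthoc(fit2, "absent"), "not a term")
})

test_that("AICc: direct arithmetic, asymptotic identity with AIC, and an
          independent likelihood oracle", {
  expect_equal(aicc(0, k = 1, n = 3), 6)
  expect_error(aicc(0, k = 2, n = 3), "domain")
  expect_lt(abs(aicc(-10, k = 3, n = 1e8) - (2 * 10 + 2 * 3)), 1e-6)

  set.seed(3)
  d <- data.frame(x = runif(25), z = runif(25))
  d$y <- 1 + 2 * d$x + rnorm(25)
  fit <- stats::lm(y ~ x + z, data = d)
  # independent log-likelihood: gaussian density at the MLE variance
  res <- stats::residuals(fit)
  sig2 <- mean(res^2)
  ll_oracle <- sum(stats::dnorm(res, 0, sqrt(sig2), log = TRUE))
  k <- length(stats::coef(fit)) + 1
  expect_equal(aicc(as.numeric(stats::logLik(fit)), k, 25),
               -2 * ll_oracle + 2 * k + 2 * k * (k + 1) / (25 - k - 1),
               tolerance = 1e-8)
  # AICc always exceeds AIC at finite n
  expect_gt(aicc(as.numeric(stats::logLik(fit)), k, 25), stats::AIC(fit))
})

test_that("IS_NT model selection recovers a quadratic prey-density bowl and
          stays quiet on noise", {
  des <- expand.grid(prey = c(2, 4, 8, 16, 32, 64), vol = c(40, 80),
                     pred = 1:4, rep = 1:5)
  make_rec <- function(y) data.frame(
    trial_id = as.character(seq_len(nrow(des))),
    prey_density_initial = des$prey, volume_ml = des$vol,
    predator_count = des$pred, replicate = des$rep,
    is_observed = NA_real_, is_trophic = NA_real_, is_nontrophic = y)

  set.seed(8)
  bowl <- -0.25 + 0.002 * (des$prey - 20)^2 / 20 + rnorm(nrow(des), 0, 0.05)
  sel <- fit_isnt_models(make_rec(bowl))
  expect_identical(sel$chosen, "quadratic")
  expect_gt(sel$delta_aicc, 0)
  expect_true("prey_density^2" %in% sel$coefficients$term)

  set.seed(9)
  quiet_hits <- sum(vapply(1:10, function(i) {
    sel0 <- fit_isnt_models(make_rec(rnorm(nrow(des), 0, 0.1)))
    q <- sel0$coefficients[sel0$coefficients$term == "prey_density^2", ]
    sel0$chosen == "quadratic" && nrow(q) == 1 && q$p < 0.05
  }, logical(1)))
  expect_lte(quiet_hits, 3)
})

test_that("IS_NT model selection validates its inputs", {
  rec <- data.frame(prey_density_initial = c(2, 4), volume_ml = 80,
                    predator_count = c(1, 2), is_nontrophic = c(0, 0))
  expect_error(fit_isnt_models(rec), ">= 3 prey densities")
})
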