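# shared fixtures: everything is generated in code at test time

# independent root of the implicit random predator equation
# Ne = N0 (1 - exp(a (Ne h - P T))), by plain bisection on [0, N0]
bisection_rogers <- function(N0, a, h, T, P = 1) {
  if (N0 == 0 || a == 0 || P == 0) return(0)
  g <- function(Ne) Ne - N0 * (1 - exp(a * (Ne * h - P * T)))
  lo <- 0; hi <- N0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# single-predator, single-volume design at the standard six prey densities
sp_design <- function(replicates = 5, volume = 80) {
  experiment_design(prey_density_levels = c(2, 4, 8, 16, 32, 64),
                    volume_levels_ml = volume,
                    predator_density_levels = 1,
                    replicates_per_cell = replicates,
                    duration_T = 0.75,
                    control_replicates_per_cell = 0)
}

# minimal valid hand-built trial table
toy_trials <- function() {
  data.frame(trial_id = c("t1", "t2", "t3", "c1"),
             prey_density_initial = c(8L, 16L, 16L, 10L),
             volume_ml = c(40, 40, 80, 80),
             predator_count = c(1L, 2L, 1L, 0L),
             prey_eaten = c(4L, 10L, 3L, 1L),
             replicate = c(1L, 1L, 1L, 1L),
             stringsAsFactors = FALSE)
}

# fr_fit object with prescribed coefficients/SEs, for prediction-layer tests
fake_fr_fit <- function(a, h, se_a = 0, se_h = 0, T = 0.75) {
  vc <- diag(c(se_a^2, se_h^2))
  dimnames(vc) <- list(c("a", "h"), c("a", "h"))
  structure(list(coefficients = c(a = a, h = h), se = c(a = se_a, h = se_h),
                 vcov = vc, loglik = NA_real_, T = T, n_trials = 0L,
                 converged = TRUE),
            class = "fr_fit")
}
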