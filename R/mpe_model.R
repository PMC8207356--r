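#' Integrate the predator-independent prey depletion model
#'
#' Numerically integrates the population-dynamic model
#' \deqn{dN/dt = - a N P / (1 + a h N)}
#' from \code{N(0) = N0} to time \code{T} (adaptive lsoda, relative
#' tolerance \code{rtol}). The model assumes no emergent multiple predator
#' effects: predators contribute independently, so the closed-form Rogers
#' solution with total predator-time \code{P T} is its exact integral (used
#' as a cross-check in the test suite, never as a silent substitute here).
#'
#' @param a attack rate (>= 0).
#' @param h handling time (>= 0).
#' @param P predator density, constant over the run (>= 0).
#' @param N0 initial prey density (>= 0).
#' @param T integration horizon (> 0).
#' @param rtol relative tolerance (default 1e-8).
#' @return Survivors N(T), clamped to [0, N0].
#' @export
integrate_depletion <- function(a, h, P, N0, T, rtol = 1e-8) {
  if (a < 0 || h < 0 || P < 0 || N0 < 0 || T <= 0)
    stop("domain error: need a, h, P, N0 >= 0 and T > 0", call. = FALSE)
  if (N0 == 0 || a == 0 || P == 0) return(N0)
  deriv <- function(t, y, parms) {
    N <- max(y[1], 0)
    list(-parms$a * N * parms$P / (1 + parms$a * parms$h * N))
  }
  out <- deSolve::ode(y = c(N = N0), times = c(0, T), func = deriv,
                      parms = list(a = a, h = h, P = P),
                      method = "lsoda", rtol = rtol, atol = 1e-10 * max(N0, 1))
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0 || nrow(out) < 2 ||
      abs(out[nrow(out), "time"] - T) > 1e-8 * T)
    stop("integrate_depletion: integration failed to reach T within tolerance",
         call. = FALSE)
  min(max(out[nrow(out), "N"], 0), N0)
}

#' Observed interaction strength: proportion of prey killed
#'
#' \eqn{IS = (N_{start} - N_{end}) / N_{start}}, the proportion of prey
#' killed over a trial, which conflates trophic consumption with any
#' nontrophic (emergent) effects among predators.
#'
#' @param n_start live prey at the start (> 0); vectorized.
#' @param n_end live prey at the end (0 <= n_end <= n_start).
#' @return Proportion killed, in [0, 1].
#' @export
interaction_strength <- function(n_start, n_end) {
  if (any(n_start <= 0))
    stop("domain error: n_start must be > 0", call. = FALSE)
  if (any(n_end < 0) || any(n_end > n_start))
    stop("domain error: need 0 <= n_end <= n_start", call. = FALSE)
  (n_start - n_end) / n_start
}

#' Predict the trophic interaction strength from a single-predator fit
#'
#' Integrates the depletion model under the fitted single-predator attack
#' rate and handling time at predator density \code{P}, and returns the
#' predicted proportion of prey killed \eqn{IS_T = (N_0 - N(T)) / N_0} on a
#' continuous scale (no rounding to integer prey). This is the feeding
#' expected if predators act independently; deviations of observed IS from
#' it measure emergent multiple predator effects.
#'
#' @param fit a converged \code{\link{fit_rogers}} result.
#' @param N0 initial prey density (>= 1).
#' @param P predator density (>= 1).
#' @param T horizon; defaults to the duration used in the fit.
#' @return Predicted trophic proportion killed, in [0, 1].
#' @export
predict_trophic_IS <- function(fit, N0, P, T = fit$T) {
  stopifnot(inherits(fit, "fr_fit"))
  if (!isTRUE(fit$converged))
    stop("predict_trophic_IS: functional response fit did not converge",
         call. = FALSE)
  if (N0 < 1 || P < 1) stop("domain error: need N0 >= 1, P >= 1",
                            call. = FALSE)
  a <- fit$coefficients[["a"]]; h <- fit$coefficients[["h"]]
  (N0 - integrate_depletion(a, h, P, N0, T)) / N0
}

#' Decompose interaction strength into trophic and nontrophic components
#'
#' For every experimental trial (controls excluded), computes the observed
#' interaction strength \eqn{IS}, the trophic prediction \eqn{IS_T} from the
#' trial's own volume's single-predator fit, and the nontrophic component
#' \eqn{IS_{NT} = IS - IS_T}. Negative \eqn{IS_{NT}} is prey risk reduction
#' (antagonism, e.g. predator interference); positive is risk enhancement.
#' By default the subtraction uses the point-estimate prediction; with
#' \code{ensemble_draws > 0} the mean prediction over a Latin hypercube
#' ensemble (see \code{\link{lhs_sensitivity}}) is reported alongside, the
#' two coinciding when the sensitivity band is symmetric.
#'
#' @param trials feeding-trial table (experimental + optional control rows).
#' @param fits a single \code{fr_fit} (applied to all volumes) or a named
#'   list keyed by volume level, e.g. \code{list("40" = ..., "80" = ...)}.
#' @param T horizon; defaults to the duration of the first fit.
#' @param ensemble_draws Latin hypercube draws for the ensemble-mean
#'   prediction (0 = point estimate only).
#' @param seed seed for the ensemble draws.
#' @return Data frame of class \code{isnt_records}: one row per experimental
#'   trial with cell labels, \code{is_observed}, \code{is_trophic},
#'   \code{is_nontrophic}, and (if requested) \code{is_trophic_mean},
#'   \code{is_nontrophic_mean}.
#' @export
nontrophic_IS <- function(trials, fits, T = NULL, ensemble_draws = 0,
                          seed = NULL) {
  validate_trials(trials)
  exp_rows <- trials[trials$predator_count >= 1, , drop = FALSE]
  if (nrow(exp_rows) == 0)
    stop("no experimental (predator_count >= 1) trials", call. = FALSE)
  vols <- sort(unique(exp_rows$volume_ml))
  if (inherits(fits, "fr_fit"))
    fits <- stats::setNames(rep(list(fits), length(vols)),
                            as.character(vols))
  missing_v <- setdiff(as.character(vols), names(fits))
  if (length(missing_v) > 0)
    stop("configuration error: no functional response fit for volume(s) ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  if (is.null(T)) T <- fits[[1]]$T

  cells <- unique(exp_rows[, c("volume_ml", "prey_density_initial",
                               "predator_count")])
  cells$is_trophic <- NA_real_
  if (ensemble_draws > 0) cells$is_trophic_mean <- NA_real_
  for (i in seq_len(nrow(cells))) {
    f <- fits[[as.character(cells$volume_ml[i])]]
    n0 <- cells$prey_density_initial[i]; p <- cells$predator_count[i]
    cells$is_trophic[i] <- predict_trophic_IS(f, n0, p, T)
    if (ensemble_draws > 0) {
      band <- lhs_sensitivity(f, n0, p, T, n_draws = ensemble_draws,
                              seed = if (is.null(seed)) NULL
                              else .substream_seed(seed, i))
      cells$is_trophic_mean[i] <- mean(band$draws$prop_killed)
    }
  }
  out <- merge(exp_rows, cells,
               by = c("volume_ml", "prey_density_initial", "predator_count"),
               sort = FALSE)
  out <- out[order(match(out$trial_id, exp_rows$trial_id)), , drop = FALSE]
  out$is_observed <- interaction_strength(
    out$prey_density_initial, out$prey_density_initial - out$prey_eaten)
  out$is_nontrophic <- out$is_observed - out$is_trophic
  if (ensemble_draws > 0)
    out$is_nontrophic_mean <- out$is_observed - out$is_trophic_mean
  keep <- c("trial_id", "prey_density_initial", "volume_ml", "predator_count",
            "replicate", "is_observed", "is_trophic", "is_nontrophic",
            if (ensemble_draws > 0) c("is_trophic_mean", "is_nontrophic_mean"))
  out <- out[, keep]
  rownames(out) <- NULL
  class(out) <- c("isnt_records", "data.frame")
  out
}

#' Latin hypercube sensitivity band for a depletion prediction
#'
#' Propagates functional-response parameter uncertainty through the
#' depletion model. Each of \code{n_draws} parameter sets places exactly one
#' draw in each equal-probability stratum of each parameter's marginal
#' (Latin hypercube), uniform over the 95\% Wald interval
#' [estimate - 1.96 SE, estimate + 1.96 SE] truncated below at 1e-12
#' (attack rates whose lower CI bound crosses zero are common at small n).
#' Marginals are paired by random permutation, i.e. zero correlation, unless
#' a variance-covariance matrix with non-zero off-diagonal is supplied, in
#' which case the uniform strata are Gaussian-copula-coupled with the
#' implied correlation. The depletion model is integrated per draw.
#'
#' @param fit a \code{\link{fit_rogers}} result with finite SEs.
#' @param N0 initial prey density.
#' @param P predator density.
#' @param T horizon; defaults to the fit's duration.
#' @param n_draws number of parameter sets (default 100, >= 2).
#' @param seed optional integer seed.
#' @param use_vcov honour the off-diagonal of \code{fit$vcov} (default FALSE:
#'   covariance assumed zero).
#' @return Object of class \code{sensitivity_band}: \code{draws} (a, h,
#'   survivors, prop_killed per draw), \code{quantiles} (2.5/50/97.5\% of
#'   proportion killed), \code{point} (point-estimate prediction),
#'   \code{ranges}, \code{n_draws}.
#' @export
lhs_sensitivity <- function(fit, N0, P, T = fit$T, n_draws = 100, seed = NULL,
                            use_vcov = FALSE) {
  stopifnot(inherits(fit, "fr_fit"), n_draws >= 2, N0 >= 1, P >= 1)
  est <- fit$coefficients; se <- fit$se
  if (any(!is.finite(se))) stop("lhs_sensitivity: fit has no finite SEs",
                                call. = FALSE)
  degenerate <- all(se <= 0)
  if (degenerate)
    warning("lhs_sensitivity: zero SEs; band degenerates to the point estimate")
  lo <- pmax(est - 1.96 * se, 1e-12)
  hi <- pmax(est + 1.96 * se, 1e-12)
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n_draws, 2)
  if (use_vcov && all(is.finite(fit$vcov)) && se[1] > 0 && se[2] > 0) {
    rho <- fit$vcov[1, 2] / (se[1] * se[2])
    rho <- min(max(rho, -0.999), 0.999)
    z <- stats::qnorm(u)
    z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    u <- stats::pnorm(z)
  }
  a_draw <- lo[1] + u[, 1] * (hi[1] - lo[1])
  h_draw <- lo[2] + u[, 2] * (hi[2] - lo[2])
  surv <- vapply(seq_len(n_draws), function(i)
    integrate_depletion(a_draw[i], h_draw[i], P, N0, T), numeric(1))
  prop <- (N0 - surv) / N0
  point <- predict_trophic_IS(fit, N0, P, T)
  out <- list(draws = data.frame(a = a_draw, h = h_draw, survivors = surv,
                                 prop_killed = prop),
              quantiles = stats::quantile(prop, c(0.025, 0.5, 0.975),
                                          names = TRUE),
              point = point,
              ranges = rbind(a = c(lo[1], hi[1]), h = c(lo[2], hi[2])),
              n_draws = n_draws, N0 = N0, P = P, T = T)
  class(out) <- "sensitivity_band"
  out
}

#' @export
print.sensitivity_band <- function(x, ...) {
  cat(sprintf(
    "LHS sensitivity band (n = %d draws; N0 = %g, P = %g, T = %g):\n",
    x$n_draws, x$N0, x$P, x$T))
  cat(sprintf("  proportion killed: point %.4f; 2.5%% %.4f, 50%% %.4f, 97.5%% %.4f\n",
              x$point, x$quantiles[1], x$quantiles[2], x$quantiles[3]))
  invisible(x)
}
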