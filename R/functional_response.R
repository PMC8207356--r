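# Principal-branch Lambert W for x >= 0: Halley iteration with a relative
# stopping rule and a hard iteration cap (an absolute 1e-15 rule is below
# the floating-point spacing of w once w is large, and then never triggers).
.lambertW0 <- function(x) {
  if (x == 0) return(0)
  w <- if (x < exp(1)) x / (1 + x) else { lx <- log(x); lx - log(lx) }
  for (i in 1:80) {
    ew <- exp(w)
    f <- w * ew - x
    step <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    w <- w - step
    if (abs(step) <= 1e-13 * (1 + abs(w))) break
  }
  w
}

# Lambert W of exp(logx): above the overflow scale, solves w + log(w) = logx
# by Newton from the asymptotic w ~ logx - log(logx).
.lambertW_exp <- function(logx) {
  if (!is.finite(logx)) {
    if (logx == -Inf) return(0)
    stop("Lambert W: non-finite log-argument", call. = FALSE)
  }
  if (logx < 700) return(.lambertW0(exp(logx)))
  w <- logx - log(logx)
  for (i in 1:100) {
    step <- (w + log(w) - logx) * w / (w + 1)
    w <- w - step
    if (abs(step) <= 1e-13 * w) break
  }
  w
}

#' Expected prey eaten under Rogers' random predator equation
#'
#' Closed-form solution of the implicit random predator equation
#' \deqn{N_e = N_0 (1 - \exp(a (N_e h - P T)))}
#' for a type II response without prey replacement, evaluated via the
#' principal branch of the Lambert W function:
#' \deqn{N_e = N_0 - W(a h N_0 e^{-a (P T - h N_0)}) / (a h).}
#' With \code{h = 0} this reduces to \eqn{N_0 (1 - e^{-a P T})}. The
#' multi-predator form substitutes total predator-time \code{P * T} for
#' \code{T}, consistent with integrating the predator-independent depletion
#' dynamic \code{dN/dt = -a N P / (1 + a h N)} (see
#' \code{\link{integrate_depletion}}). The Lambert W argument is assembled on
#' the log scale, so large \code{a h N_0} never overflows.
#'
#' @param N0 initial prey density (>= 0); vectorized.
#' @param a attack rate (>= 0), per unit time.
#' @param h handling time (>= 0), time per prey.
#' @param T trial duration (> 0).
#' @param P predator count (default 1).
#' @return Expected number eaten, continuous, in [0, N0]; same length as N0.
#' @examples
#' rogers_expected_eaten(16, a = 1.52, h = 0.25, T = 0.75)
#' @export
rogers_expected_eaten <- function(N0, a, h, T, P = 1) {
  if (any(N0 < 0) || a < 0 || h < 0 || T <= 0 || P < 0)
    stop("domain error: need N0 >= 0, a >= 0, h >= 0, T > 0, P >= 0",
         call. = FALSE)
  if (a == 0 || P == 0) return(rep(0, length(N0)))
  Te <- P * T  # total predator-time
  out <- numeric(length(N0))
  for (i in seq_along(N0)) {
    n0 <- N0[i]
    if (n0 == 0) { out[i] <- 0; next }
    if (h == 0) { out[i] <- n0 * (1 - exp(-a * Te)); next }
    logx <- log(a) + log(h) + log(n0) + a * (h * n0 - Te)
    out[i] <- n0 - .lambertW_exp(logx) / (a * h)
  }
  pmin(pmax(out, 0), N0)
}

# extract and check single-predator trials; returns data.frame(N0, Ne)
.single_predator_data <- function(trials, min_densities = 2, min_trials = 1) {
  validate_trials(trials)
  if (!all(trials$predator_count == 1))
    stop("all trials must have predator_count = 1; subset first",
         call. = FALSE)
  if (length(unique(trials$prey_density_initial)) < min_densities)
    stop("need >= ", min_densities, " distinct prey densities", call. = FALSE)
  if (nrow(trials) < min_trials)
    stop("need >= ", min_trials, " trials", call. = FALSE)
  data.frame(N0 = trials$prey_density_initial, Ne = trials$prey_eaten)
}

#' Classify the functional response type from single-predator trials
#'
#' Fits a binomial logistic regression of the proportion eaten on initial
#' prey density (linear term). A significantly negative slope indicates a
#' type II response (proportion consumed declining with density); a
#' significantly positive slope flags a candidate type I/III (a density
#' range where the proportion rises); otherwise the response is flat at the
#' chosen level. Optionally a quadratic term screens for type III
#' (off by default).
#'
#' @param trials single-predator feeding trials (predator_count = 1).
#' @param alpha significance level for the slope test (default 0.05).
#' @param quadratic_screen also fit a quadratic density term and report its
#'   coefficient (default FALSE).
#' @return Object of class \code{fr_type}: list with
#'   \code{linear_coefficient}, \code{se}, \code{p_value},
#'   \code{classification}, and optionally \code{quadratic}.
#' @export
classify_fr_type <- function(trials, alpha = 0.05, quadratic_screen = FALSE) {
  d <- .single_predator_data(trials, min_densities = 2)
  d$surv <- d$N0 - d$Ne
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(Ne, surv) ~ N0, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  slope <- cf["N0", "Estimate"]; se <- cf["N0", "Std. Error"]
  p <- cf["N0", "Pr(>|z|)"]
  classification <- if (separation) "indeterminate"
  else if (p < alpha && slope < 0) "type II"
  else if (p < alpha && slope > 0) "candidate type I/III"
  else "not type II (flat)"
  out <- list(linear_coefficient = slope, se = se, p_value = p,
              alpha = alpha, classification = classification,
              separation = separation)
  if (quadratic_screen) {
    fit2 <- suppressWarnings(
      stats::glm(cbind(Ne, surv) ~ N0 + I(N0^2), family = stats::binomial(),
                 data = d))
    cf2 <- summary(fit2)$coefficients
    out$quadratic <- c(estimate = unname(cf2["I(N0^2)", "Estimate"]),
                       p_value = unname(cf2["I(N0^2)", "Pr(>|z|)"]))
  }
  class(out) <- "fr_type"
  out
}

#' @export
print.fr_type <- function(x, ...) {
  cat(sprintf(
    "FR type: %s (linear coefficient %.4g, SE %.3g, p = %.3g, alpha = %g)\n",
    x$classification, x$linear_coefficient, x$se, x$p_value, x$alpha))
  invisible(x)
}

# negative binomial log-likelihood of (log a, log h) for Rogers' equation
.rogers_nll_log <- function(par, N0, Ne, T, eps = 1e-9) {
  a <- exp(par[1]); h <- exp(par[2])
  if (!is.finite(a) || !is.finite(h)) return(1e10)
  pe <- rogers_expected_eaten(N0, a, h, T) / N0
  pe <- pmin(pmax(pe, eps), 1 - eps)
  -sum(stats::dbinom(Ne, N0, pe, log = TRUE))
}

#' Fit Rogers' random predator equation by maximum likelihood
#'
#' Maximizes the trial-level binomial log-likelihood of the eaten counts,
#' with success probability given by the Lambert W closed form of
#' Rogers' equation divided by N0 (clamped to (1e-9, 1 - 1e-9) so that
#' total-depletion trials are retained, not dropped). Optimization is
#' quasi-Newton on (log a, log h) from a coarse grid of starting values
#' (functional-response likelihoods are often multi-modal at small n);
#' ties are broken by highest log-likelihood then lowest attack rate.
#' Standard errors come from the inverse observed information
#' (finite-difference Hessian on the log scale) back-transformed to the
#' natural scale by the delta method.
#'
#' @param trials single-predator trials (predator_count = 1, >= 2 distinct
#'   prey densities, >= 3 trials).
#' @param T trial duration, in the time unit that defines a and h
#'   (default 0.75, i.e. 18 hours in days).
#' @param starts optional matrix of (log a, log h) starting values; default
#'   a 3 x 3 coarse grid around data-driven scales.
#' @return Object of class \code{fr_fit}: coefficients (a, h), se, vcov
#'   (natural scale), loglik, T, n_trials, converged.
#' @export
fit_rogers <- function(trials, T = 0.75, starts = NULL) {
  d <- .single_predator_data(trials, min_densities = 2, min_trials = 3)
  N0 <- d$N0; Ne <- d$Ne
  if (all(Ne == 0)) {
    warning("all prey_eaten are zero; attack rate at lower bound")
    a0 <- 1e-8
    ll <- -.rogers_nll_log(c(log(a0), log(0.1)), N0, Ne, T)
    out <- list(coefficients = c(a = a0, h = 0.1),
                se = c(a = NA_real_, h = NA_real_),
                vcov = matrix(NA_real_, 2, 2,
                              dimnames = list(c("a", "h"), c("a", "h"))),
                loglik = ll, T = T, n_trials = nrow(d), converged = FALSE)
    class(out) <- "fr_fit"
    return(out)
  }
  if (is.null(starts)) {
    # scale heuristics: a from initial depletion, h from the max feeding rate
    h_top <- T / max(max(Ne), 1)
    starts <- as.matrix(expand.grid(
      log_a = log(c(0.05, 0.5, 5) / T),
      log_h = log(c(0.05, 0.5, 2) * h_top)))
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::nlminb(as.numeric(starts[s, ]), .rogers_nll_log, N0 = N0,
                    Ne = Ne, T = T,
                    control = list(iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    opt$value <- opt$objective
    if (is.null(best) || opt$value < best$value - 1e-9 ||
        (abs(opt$value - best$value) <= 1e-9 && opt$par[1] < best$par[1]))
      best <- opt
  }
  if (is.null(best)) stop("fit_rogers: all optimizer starts failed",
                          call. = FALSE)
  a <- exp(best$par[1]); h <- exp(best$par[2])
  converged <- best$convergence == 0
  H <- tryCatch(stats::optimHess(best$par, .rogers_nll_log, N0 = N0, Ne = Ne,
                                 T = T),
                error = function(e) NULL)
  vcov_nat <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "h"), c("a", "h")))
  if (!is.null(H)) {
    Vlog <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vlog) && all(is.finite(Vlog))) {
      J <- diag(c(a, h))  # d(natural)/d(log)
      V <- J %*% Vlog %*% J
      if (all(diag(V) >= 0)) {
        vcov_nat <- (V + t(V)) / 2
        dimnames(vcov_nat) <- list(c("a", "h"), c("a", "h"))
      } else converged <- FALSE
    } else converged <- FALSE
  } else converged <- FALSE
  out <- list(coefficients = c(a = a, h = h),
              se = c(a = sqrt(vcov_nat[1, 1]), h = sqrt(vcov_nat[2, 2])),
              vcov = vcov_nat,
              loglik = -best$value, T = T, n_trials = nrow(d),
              converged = converged)
  class(out) <- "fr_fit"
  out
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf(
    "Rogers random predator fit (n = %d trials, T = %g):\n", x$n_trials, x$T))
  cat(sprintf("  attack rate a  = %.4g (SE %.3g)\n",
              x$coefficients["a"], x$se["a"]))
  cat(sprintf("  handling time h = %.4g (SE %.3g)\n",
              x$coefficients["h"], x$se["h"]))
  cat(sprintf("  logLik = %.4f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, ...) object$coefficients

#' @export
vcov.fr_fit <- function(object, ...) object$vcov

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' Wald confidence intervals for functional response parameters
#'
#' Intervals are computed on the log-parameter scale (the optimization
#' scale, where the sampling distribution is closer to normal for these
#' positivity-constrained parameters) and back-transformed, so bounds are
#' always positive.
#'
#' @param object a \code{\link{fit_rogers}} result.
#' @param parm parameters to include ("a", "h").
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return Matrix with columns \code{lower}, \code{upper}.
#' @export
confint.fr_fit <- function(object, parm = c("a", "h"), level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  se_log <- object$se[parm] / est  # delta method back to the log scale
  out <- cbind(lower = est * exp(-z * se_log), upper = est * exp(z * se_log))
  rownames(out) <- parm
  out
}

# joint negative log-likelihood for the delta parameterization
# theta = (aA, hA, Da, Dh) on the natural scale; soft barrier keeps the
# group-B parameters positive without breaking quasi-Newton steps
.delta_nll <- function(theta, NA0, NeA, NB0, NeB, T) {
  aA <- theta[1]; hA <- theta[2]
  aB <- aA + theta[3]; hB <- hA + theta[4]
  pen <- 0
  if (aA <= 0) { pen <- pen + 1e6 * (1 - aA); aA <- 1e-10 }
  if (hA < 0)  { pen <- pen + 1e6 * (1 - hA); hA <- 0 }
  if (aB <= 0) { pen <- pen + 1e6 * (1 - aB); aB <- 1e-10 }
  if (hB < 0)  { pen <- pen + 1e6 * (1 - hB); hB <- 0 }
  .rogers_nll_log(log(c(aA, max(hA, 1e-12))), NA0, NeA, T) +
    .rogers_nll_log(log(c(aB, max(hB, 1e-12))), NB0, NeB, T) + pen
}

#' Compare functional response parameters between two treatments
#'
#' Juliano's differences (delta) method: the two single-predator data sets
#' are fitted jointly with \code{a = a_A + D_a j} and \code{h = h_A + D_h j}
#' (indicator j = 1 for the second set) on the natural scale, so the
#' difference terms may be negative. Wald z statistics and two-sided normal
#' p-values test \code{D_a = 0} and \code{D_h = 0}.
#'
#' @param trials_a,trials_b single-predator trial sets (each satisfying the
#'   \code{\link{fit_rogers}} preconditions).
#' @param T trial duration (shared).
#' @return Object of class \code{delta_comparison}: data frame of the two
#'   difference terms with estimate, se, z, p, plus the underlying fits.
#' @export
compare_params_delta <- function(trials_a, trials_b, T = 0.75) {
  da <- .single_predator_data(trials_a, min_densities = 2, min_trials = 3)
  db <- .single_predator_data(trials_b, min_densities = 2, min_trials = 3)
  fa <- fit_rogers(trials_a, T = T)
  fb <- fit_rogers(trials_b, T = T)
  pooled <- fit_rogers(rbind(trials_a, trials_b), T = T)
  starts <- rbind(
    c(coef(pooled)["a"], coef(pooled)["h"], 0, 0),
    c(coef(fa)["a"], coef(fa)["h"],
      coef(fb)["a"] - coef(fa)["a"], coef(fb)["h"] - coef(fa)["h"]))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::nlminb(as.numeric(starts[s, ]), .delta_nll,
                    NA0 = da$N0, NeA = da$Ne, NB0 = db$N0, NeB = db$Ne, T = T,
                    control = list(iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    opt$value <- opt$objective
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("compare_params_delta: optimization failed",
                          call. = FALSE)
  H <- stats::optimHess(best$par, .delta_nll, NA0 = da$N0, NeA = da$Ne,
                        NB0 = db$N0, NeB = db$Ne, T = T)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 4, 4))
  est <- best$par[3:4]
  se <- sqrt(pmax(diag(V)[3:4], 0))
  z <- ifelse(se > 0, est / se, ifelse(est == 0, 0, NA_real_))
  p <- 2 * stats::pnorm(-abs(z))
  out <- list(table = data.frame(
    parameter = c("D_a", "D_h"), estimate = est, se = se, z = z, p = p,
    stringsAsFactors = FALSE),
    fit_a = fa, fit_b = fb, loglik = -best$value, T = T)
  class(out) <- "delta_comparison"
  out
}

#' @export
print.delta_comparison <- function(x, ...) {
  cat("Delta-method comparison of functional response parameters:\n")
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %s = %.4g (SE %.3g), z = %.3g, p = %.3g\n",
                tb$parameter[i], tb$estimate[i], tb$se[i], tb$z[i], tb$p[i]))
  invisible(x)
}
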