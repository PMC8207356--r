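# Assemble the modelling frame used by the statistical layer: predator
# density and volume as factors, prey density as a continuous covariate.
.anodev_frame <- function(trials) {
  validate_trials(trials)
  d <- trials[trials$predator_count >= 1, , drop = FALSE]
  if (nrow(d) == 0) stop("no experimental trials", call. = FALSE)
  data.frame(eaten = d$prey_eaten,
             survived = d$prey_density_initial - d$prey_eaten,
             pred_f = factor(d$predator_count),
             vol_f = factor(d$volume_ml),
             prey = as.numeric(d$prey_density_initial))
}

.pretty_term <- function(x) {
  x <- gsub("pred_f", "predator_density", x, fixed = TRUE)
  x <- gsub("vol_f", "volume", x, fixed = TRUE)
  x <- gsub("I(prey^2)", "@Q2@", x, fixed = TRUE)
  x <- gsub("prey", "prey_density", x, fixed = TRUE)
  gsub("@Q2@", "prey_density^2", x, fixed = TRUE)
}

#' Quasi-binomial analysis of deviance with backward elimination
#'
#' Fits a binomial-logit GLM of (eaten, survived) with a free dispersion
#' parameter estimated as Pearson chi-squared over residual degrees of
#' freedom (quasi-binomial: proportion-eaten data from feeding trials are
#' typically overdispersed). Terms enter sequentially -- main effects in the
#' order predator density, volume, prey density (continuous), then two-way
#' and three-way interactions -- and each term's F statistic is the scaled
#' deviance drop between the nested fits, with the dispersion taken from
#' the full model. The reported denominator df is the residual df of the
#' row's cumulative model. Backward elimination then repeatedly removes the
#' least significant eligible term (respecting marginality, partial F test)
#' until every retained term has p < alpha.
#'
#' @param trials feeding-trial table (control rows are dropped).
#' @param alpha retention threshold for backward elimination (default 0.05).
#' @param term_order order of the three main effects; interactions follow
#'   in the corresponding order.
#' @param eliminate run backward elimination (default TRUE); if FALSE only
#'   the sequential table is computed and all terms are marked retained.
#' @return Object of class \code{anodev}: \code{table} (term, F, df1, df2,
#'   p, retained), \code{dispersion}, \code{model_full}, \code{model_final},
#'   \code{alpha}.
#' @export
glm_quasibinomial_anodev <- function(trials, alpha = 0.05,
                                     term_order = c("predator_density",
                                                    "volume", "prey_density"),
                                     eliminate = TRUE) {
  d <- .anodev_frame(trials)
  var_of <- c(predator_density = "pred_f", volume = "vol_f",
              prey_density = "prey")
  stopifnot(setequal(term_order, names(var_of)))
  mains <- unname(var_of[term_order])
  for (v in c("pred_f", "vol_f"))
    if (v %in% mains && nlevels(d[[v]]) < 2)
      stop("factor '", .pretty_term(v), "' has fewer than 2 levels",
           call. = FALSE)
  if (length(unique(d$prey)) < 2)
    stop("prey density has fewer than 2 distinct values", call. = FALSE)
  twoway <- c(paste(mains[1], mains[2], sep = ":"),
              paste(mains[1], mains[3], sep = ":"),
              paste(mains[2], mains[3], sep = ":"))
  threeway <- paste(mains, collapse = ":")
  terms_seq <- c(mains, twoway, threeway)

  fml_full <- stats::as.formula(paste("cbind(eaten, survived) ~",
                                      paste(terms_seq, collapse = " + ")))
  fit_full <- suppressWarnings(
    stats::glm(fml_full, family = stats::quasibinomial(), data = d))
  # Pearson chi-squared / residual df, from the working residuals exactly as
  # standard GLM summaries compute it
  phi <- sum((fit_full$weights * fit_full$residuals^2)[fit_full$weights > 0]) /
    stats::df.residual(fit_full)
  if (!is.finite(phi) || phi <= 0)
    stop("dispersion estimate is not positive", call. = FALSE)

  # sequential (type I) deviance decomposition via cumulative nested fits
  dev_prev <- NULL; df_prev <- NULL
  tab <- data.frame(term = .pretty_term(terms_seq), F = NA_real_,
                    df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
                    retained = TRUE, stringsAsFactors = FALSE)
  null_fit <- suppressWarnings(
    stats::glm(cbind(eaten, survived) ~ 1, family = stats::quasibinomial(),
               data = d))
  dev_prev <- stats::deviance(null_fit); df_prev <- stats::df.residual(null_fit)
  for (k in seq_along(terms_seq)) {
    fml_k <- stats::as.formula(paste("cbind(eaten, survived) ~",
                                     paste(terms_seq[seq_len(k)],
                                           collapse = " + ")))
    fit_k <- suppressWarnings(
      stats::glm(fml_k, family = stats::quasibinomial(), data = d))
    dev_k <- stats::deviance(fit_k); df_k <- stats::df.residual(fit_k)
    ddf <- df_prev - df_k
    tab$df1[k] <- ddf
    tab$df2[k] <- df_k
    if (ddf > 0) {
      tab$F[k] <- ((dev_prev - dev_k) / ddf) / phi
      tab$p[k] <- stats::pf(tab$F[k], ddf, df_k, lower.tail = FALSE)
    }
    dev_prev <- dev_k; df_prev <- df_k
  }

  fit_final <- fit_full
  if (eliminate) {
    repeat {
      dr <- suppressWarnings(stats::drop1(fit_final, test = "F"))
      cand <- rownames(dr)[-1]
      if (length(cand) == 0) break
      pvals <- dr[["Pr(>F)"]][-1]
      worst <- which.max(pvals)
      if (is.na(pvals[worst]) || pvals[worst] < alpha) break
      fit_final <- suppressWarnings(stats::update(
        fit_final, stats::as.formula(paste(". ~ . -", cand[worst]))))
    }
    kept <- attr(stats::terms(fit_final), "term.labels")
    tab$retained <- .pretty_term(terms_seq) %in% .pretty_term(kept)
  }
  out <- list(table = tab, dispersion = phi, model_full = fit_full,
              model_final = fit_final, alpha = alpha)
  class(out) <- "anodev"
  out
}

#' @export
print.anodev <- function(x, ...) {
  cat(sprintf(
    "Quasi-binomial analysis of deviance (dispersion = %.3f):\n",
    x$dispersion))
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-45s F(%d, %d) = %.2f, p = %.3g%s\n", tb$term[i],
                tb$df1[i], tb$df2[i], tb$F[i], tb$p[i],
                if (tb$retained[i]) "  [retained]" else ""))
  invisible(x)
}

#' Tukey post hoc pairwise comparisons for a model factor
#'
#' All pairwise level contrasts of \code{factor} on the link scale, with
#' standard errors from the coefficient covariance and family-wise adjusted
#' p-values by the single-step multivariate-normal (studentized-range-type)
#' method of \pkg{multcomp}. Unadjusted p-values are reported alongside;
#' with a two-level factor the two coincide.
#'
#' @param model a fitted \code{glm} or \code{lm} containing \code{factor}.
#' @param factor name of a factor retained in the model (>= 2 levels).
#' @return Data frame: contrast, estimate, se, statistic, p_unadjusted,
#'   p_adjusted.
#' @export
tukey_posthoc <- function(model, factor) {
  tl <- attr(stats::terms(model), "term.labels")
  if (!factor %in% tl)
    stop("factor '", factor, "' is not a term of the model", call. = FALSE)
  lf <- do.call(multcomp::mcp, stats::setNames(list("Tukey"), factor))
  gh <- multcomp::glht(model, linfct = lf)
  s_adj <- summary(gh)  # single-step
  s_raw <- summary(gh, test = multcomp::adjusted("none"))
  data.frame(contrast = names(s_adj$test$coefficients),
             estimate = as.numeric(s_adj$test$coefficients),
             se = as.numeric(s_adj$test$sigma),
             statistic = as.numeric(s_adj$test$tstat),
             p_unadjusted = as.numeric(s_raw$test$pvalues),
             p_adjusted = as.numeric(s_adj$test$pvalues),
             stringsAsFactors = FALSE)
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n - k - 1)}, where k counts all
#' estimated parameters including any variance parameter. Converges to AIC
#' as n grows.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (including variance).
#' @param n sample size; must exceed k + 1.
#' @return The AICc value.
#' @examples
#' aicc(0, k = 1, n = 3)  # 6
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(length(loglik) == 1, length(k) == 1, length(n) == 1)
  if (n <= k + 1)
    stop("domain error: AICc undefined for n <= k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# backward-eliminate nonsignificant interaction terms of an lm by partial F
# (explicit nested refits), keeping all main-effect and polynomial terms
.eliminate_interactions <- function(fit, d, alpha) {
  repeat {
    tl <- attr(stats::terms(fit), "term.labels")
    inter <- tl[grepl(":", tl, fixed = TRUE)]
    if (length(inter) == 0) break
    pvals <- vapply(inter, function(tm) {
      small <- stats::lm(stats::reformulate(setdiff(tl, tm), response = "y"),
                         data = d)
      stats::anova(small, fit)[2, "Pr(>F)"]
    }, numeric(1))
    worst <- which.max(pvals)
    if (is.na(pvals[worst]) || pvals[worst] < alpha) break
    fit <- stats::lm(stats::reformulate(setdiff(tl, inter[worst]),
                                        response = "y"), data = d)
  }
  fit
}

#' Model the nontrophic interaction strength
#'
#' Ordinary least squares on \eqn{IS_{NT}} with predator density and volume
#' as factors and prey density as a continuous covariate, entered either
#' linearly or as linear + quadratic (raw polynomial, both terms retained
#' together). For each coding, nonsignificant interactions are removed
#' backwards by partial F tests (main effects are the quantities of
#' interest and stay); the two final models are then compared by AICc. A
#' unimodal (bowl- or dome-shaped) dependence of the emergent effect on
#' prey density favours the quadratic coding.
#'
#' @param records an \code{isnt_records} table from
#'   \code{\link{nontrophic_IS}} (needs >= 2 predator levels and >= 3 prey
#'   densities).
#' @param alpha significance level for interaction elimination.
#' @param response which IS_NT column to model (default
#'   \code{"is_nontrophic"}, the point-estimate decomposition).
#' @return Object of class \code{isnt_selection}: \code{aicc} (named,
#'   linear/quadratic), \code{delta_aicc} (>= 0), \code{chosen},
#'   \code{model} (the chosen lm), \code{models}, \code{coefficients}
#'   (t and p for the chosen model), \code{anova_table} (type II F tests,
#'   denominator df = residual df).
#' @export
fit_isnt_models <- function(records, alpha = 0.05,
                            response = "is_nontrophic") {
  stopifnot(is.data.frame(records), response %in% names(records))
  d <- data.frame(y = records[[response]],
                  pred_f = factor(records$predator_count),
                  vol_f = factor(records$volume_ml),
                  prey = as.numeric(records$prey_density_initial))
  if (nlevels(d$pred_f) < 2)
    stop("need >= 2 predator-density levels", call. = FALSE)
  if (length(unique(d$prey)) < 3)
    stop("need >= 3 prey densities", call. = FALSE)
  has_vol <- nlevels(d$vol_f) >= 2
  base_terms <- c("pred_f", if (has_vol) "vol_f", "prey")
  inter_terms <- c(if (has_vol) "pred_f:vol_f", "pred_f:prey",
                   if (has_vol) "vol_f:prey")
  fml <- function(extra) stats::as.formula(
    paste("y ~", paste(c(base_terms, extra, inter_terms), collapse = " + ")))
  fit_lin <- .eliminate_interactions(stats::lm(fml(NULL), data = d), d, alpha)
  fit_quad <- .eliminate_interactions(stats::lm(fml("I(prey^2)"), data = d),
                                      d, alpha)
  n <- nrow(d)
  aicc_of <- function(fit) {
    ll <- stats::logLik(fit)
    aicc(as.numeric(ll), attr(ll, "df"), n)
  }
  aiccs <- c(linear = aicc_of(fit_lin), quadratic = aicc_of(fit_quad))
  chosen <- names(aiccs)[which.min(aiccs)]
  fit <- if (chosen == "quadratic") fit_quad else fit_lin
  a2 <- car::Anova(fit, type = 2)
  rows <- rownames(a2)[rownames(a2) != "Residuals"]
  atab <- data.frame(term = .pretty_term(rows),
                     F = a2[rows, "F value"],
                     df1 = a2[rows, "Df"],
                     df2 = stats::df.residual(fit),
                     p = a2[rows, "Pr(>F)"],
                     stringsAsFactors = FALSE)
  cf <- summary(fit)$coefficients
  out <- list(aicc = aiccs, delta_aicc = abs(diff(aiccs))[[1]],
              chosen = chosen, model = fit,
              models = list(linear = fit_lin, quadratic = fit_quad),
              coefficients = data.frame(
                term = .pretty_term(rownames(cf)),
                estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
                t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                row.names = NULL, stringsAsFactors = FALSE),
              anova_table = atab, alpha = alpha, n = n)
  class(out) <- "isnt_selection"
  out
}

#' @export
print.isnt_selection <- function(x, ...) {
  cat(sprintf(
    "IS_NT model selection: %s prey-density coding chosen (delta AICc = %.2f)\n",
    x$chosen, x$delta_aicc))
  cat(sprintf("  AICc: linear %.2f, quadratic %.2f (n = %d)\n",
              x$aicc["linear"], x$aicc["quadratic"], x$n))
  tb <- x$anova_table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-30s F(%d, %d) = %.2f, p = %.3g\n", tb$term[i],
                tb$df1[i], tb$df2[i], tb$F[i], tb$p[i]))
  invisible(x)
}
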