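#' Fixed effects of the logistic survival model
#'
#' Population-level coefficients (logit scale) of the repeated-measures
#' logistic survival model: an intercept, additive treatment contrasts
#' relative to the reference arm \code{"Cocoon"}, and a linear age slope
#' (per year). Defaults are the published estimates for the Galapagos
#' restoration cohort.
#'
#' @param intercept Intercept (logit units).
#' @param contrasts Named numeric vector of treatment contrasts relative to
#'   the reference level; the reference itself carries contrast 0 and is
#'   added automatically if missing.
#' @param age_slope Age coefficient (logit per year).
#' @param reference Reference treatment level.
#' @return A list of class \code{"survival_fixed_effects"}.
#' @export
survival_fixed_effects <- function(intercept = 3.932,
                                   contrasts = c(
                                     "Cocoon+Hydrogel" = 1.973,
                                     "Control" = -0.223,
                                     "Hydrogel" = -0.333,
                                     "Waterboxx" = 0.264,
                                     "Waterboxx+Hydrogel" = 0.711),
                                   age_slope = -0.234,
                                   reference = "Cocoon") {
  if (!all(is.finite(c(intercept, contrasts, age_slope))))
    stop("survival fixed effects must be finite", call. = FALSE)
  if (!reference %in% names(contrasts)) {
    contrasts <- c(stats::setNames(0, reference), contrasts)
  } else if (contrasts[[reference]] != 0) {
    stop("the reference level must carry contrast 0", call. = FALSE)
  }
  structure(list(intercept = intercept, contrasts = contrasts,
                 age_slope = age_slope, reference = reference),
            class = "survival_fixed_effects")
}

#' Random-effect variances of the survival model
#'
#' Variances (logit^2) of the plant-level and site-level Gaussian random
#' intercepts. Defaults are the published estimates.
#'
#' @param var_plant Plant-level intercept variance.
#' @param var_site Site-level intercept variance.
#' @return A list of class \code{"survival_random_effects"}.
#' @export
survival_random_effects <- function(var_plant = 0.812, var_site = 0.994) {
  if (var_plant < 0 || var_site < 0)
    stop("random-effect variances must be >= 0", call. = FALSE)
  structure(list(var_plant = var_plant, var_site = var_site),
            class = "survival_random_effects")
}

#' Fit the repeated-measures logistic survival model
#'
#' Fits \code{alive ~ treatment + age + (1 | plant_id) + (1 | site_id)} by
#' maximum marginal likelihood with the random intercepts integrated out by
#' the Laplace approximation (\code{lme4::glmer}). Each monitoring record is
#' one Bernoulli trial; the plant random intercept absorbs the repeated
#' measurements, the site intercept the farm dependence. Treatment enters
#' with \code{"Cocoon"} as reference level.
#'
#' @param records Monitoring data.frame with columns \code{alive},
#'   \code{treatment}, \code{age}, \code{plant_id}, \code{site_id}.
#' @param reference Reference treatment level.
#' @return An object of class \code{"survival_fit"}: list with elements
#'   \code{fixed} (a \code{\link{survival_fixed_effects}}), \code{random}
#'   (a \code{\link{survival_random_effects}}), \code{vcov} (fixed-effects
#'   covariance, rows/columns named like the coefficient vector),
#'   \code{coef} (named coefficient vector in model order), \code{loglik},
#'   \code{n_obs}, \code{n_plants}, \code{n_sites}, \code{converged}, and
#'   \code{model} (the underlying \code{merMod}).
#' @export
fit_survival_glmm <- function(records, reference = "Cocoon") {
  need <- c("alive", "treatment", "age", "plant_id", "site_id")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(is.na(records$age)) || any(is.na(records$alive)))
    stop("every record needs an age and an alive status", call. = FALSE)
  lv <- unique(as.character(records$treatment))
  if (length(lv) < 2)
    stop("degenerate design: 'treatment' has a single level", call. = FALSE)
  if (length(unique(records$site_id)) < 2)
    stop("degenerate design: need records from at least 2 sites", call. = FALSE)
  if (all(records$alive) || !any(records$alive))
    stop("separation: the alive flag is constant (all ",
         if (all(records$alive)) "alive" else "dead",
         "); the logistic model is not identifiable", call. = FALSE)

  d <- records
  d$treatment <- stats::relevel(factor(d$treatment), ref = reference)
  d$alive <- as.numeric(d$alive)
  fit <- withCallingHandlers(
    lme4::glmer(alive ~ treatment + age + (1 | plant_id) + (1 | site_id),
                data = d, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             optimizer = "bobyqa")),
    warning = function(w) invokeRestart("muffleWarning"))
  conv <- is.null(fit@optinfo$conv$lme4$code) && fit@optinfo$conv$opt == 0

  beta <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  contr_names <- grep("^treatment", names(beta), value = TRUE)
  contrasts <- stats::setNames(beta[contr_names],
                               sub("^treatment", "", contr_names))
  fixed <- survival_fixed_effects(
    intercept = beta[["(Intercept)"]], contrasts = contrasts,
    age_slope = beta[["age"]], reference = reference)
  random <- survival_random_effects(
    var_plant = max(as.numeric(vc$plant_id), 0),
    var_site = max(as.numeric(vc$site_id), 0))
  structure(list(
    fixed = fixed, random = random,
    coef = beta, vcov = as.matrix(stats::vcov(fit)),
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(d), n_plants = length(unique(d$plant_id)),
    n_sites = length(unique(d$site_id)), converged = conv,
    model = fit), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Logistic mixed survival model (Laplace)\n")
  cat(sprintf("  %d records, %d plants, %d sites; logLik %.2f; converged: %s\n",
              x$n_obs, x$n_plants, x$n_sites, x$loglik, x$converged))
  cat(sprintf("  random effects: var(plant) = %.3f, var(site) = %.3f\n",
              x$random$var_plant, x$random$var_site))
  cat("  fixed effects:\n")
  est <- x$coef
  se <- sqrt(diag(x$vcov))
  for (i in seq_along(est))
    cat(sprintf("    %-28s %8.3f  (SE %.3f)\n", names(est)[i], est[i], se[i]))
  invisible(x)
}

#' Wald chi-square test of a model term
#'
#' Tests the joint nullity of a term's coefficient block using the
#' estimated fixed-effects covariance: \eqn{\chi^2 = c^T V^{-1} c} on
#' \code{df = length(c)} degrees of freedom (5 for Treatment, 1 for Age or
#' the Intercept), with the p-value from the chi-square distribution.
#'
#' @param fit A \code{\link{fit_survival_glmm}} result.
#' @param term One of \code{"Treatment"}, \code{"Age"}, \code{"Intercept"}.
#' @return A list of class \code{"wald_result"} with \code{term},
#'   \code{chisq}, \code{df}, \code{p}.
#' @export
wald_test <- function(fit, term = c("Treatment", "Age", "Intercept")) {
  term <- match.arg(term)
  if (!isTRUE(fit$converged))
    warning("Wald test on a fit flagged as not converged")
  idx <- switch(term,
    Treatment = grep("^treatment", names(fit$coef)),
    Age = which(names(fit$coef) == "age"),
    Intercept = which(names(fit$coef) == "(Intercept)"))
  cb <- fit$coef[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance block for term '", term, "'", call. = FALSE))
  chisq <- as.numeric(t(cb) %*% Vi %*% cb)
  df <- length(idx)
  structure(list(term = term, chisq = chisq, df = df,
                 p = stats::pchisq(chisq, df, lower.tail = FALSE)),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald chi-square test: %s  Chisq = %.3f, df = %d, p = %.4g\n",
              x$term, x$chisq, x$df, x$p))
  invisible(x)
}

#' Population-level survival probability
#'
#' Inverse-logit of \code{intercept + contrast(treatment) + age_slope * age}
#' with the random effects at zero.
#'
#' @param fixed A \code{\link{survival_fixed_effects}} set.
#' @param treatment A treatment level known to \code{fixed}, or
#'   \code{"all-data"} for the arm-size-weighted average contrast (see
#'   \code{\link{all_data_contrast}}).
#' @param age Age in years (vectorised, >= 0).
#' @param arm_weights Optional named arm weights, used for
#'   \code{"all-data"}.
#' @return Survival probabilities.
#' @export
predict_survival <- function(fixed, treatment, age, arm_weights = NULL) {
  stopifnot(all(age >= 0))
  cc <- if (identical(treatment, "all-data")) {
    all_data_contrast(fixed, arm_weights)
  } else {
    if (!treatment %in% names(fixed$contrasts))
      stop("unknown treatment level '", treatment, "'; valid levels: ",
           paste(names(fixed$contrasts), collapse = ", "), call. = FALSE)
    fixed$contrasts[[treatment]]
  }
  stats::plogis(fixed$intercept + cc + fixed$age_slope * age)
}

#' Arm-weighted average treatment contrast
#'
#' The "all-data" survival scenario uses a single curve whose contrast is
#' the average of the treatment contrasts weighted by arm sizes (by default
#' the generator's allocation).
#'
#' @param fixed A \code{\link{survival_fixed_effects}} set.
#' @param arm_weights Named weights over treatment levels; defaults to the
#'   default cohort allocation.
#' @return A single averaged contrast (logit units).
#' @export
all_data_contrast <- function(fixed, arm_weights = NULL) {
  if (is.null(arm_weights))
    arm_weights <- cohort_config()$treatment_allocation
  lv <- names(arm_weights)
  if (!all(lv %in% names(fixed$contrasts)))
    stop("arm weights name unknown treatment level(s)", call. = FALSE)
  sum(arm_weights * fixed$contrasts[lv]) / sum(arm_weights)
}

#' Survival curve over age
#'
#' Dense evaluation of \code{\link{predict_survival}} on a regular age
#' grid, with the 1-year and 4-year cut-off probabilities (the adaptation
#' and maturation benchmarks used in the field trials) attached as
#' attributes.
#'
#' @param fixed A \code{\link{survival_fixed_effects}} set.
#' @param treatment Treatment level or \code{"all-data"}.
#' @param horizon Curve end (years, > 0).
#' @param step Grid step (years, > 0); a step larger than the horizon
#'   yields just the two endpoints.
#' @param arm_weights Passed to \code{\link{predict_survival}}.
#' @return data.frame with columns \code{age} and \code{survival}, and
#'   attributes \code{cutoff_1y} / \code{cutoff_4y} (when within horizon).
#' @export
survival_curve <- function(fixed, treatment, horizon = 10, step = 0.25,
                           arm_weights = NULL) {
  stopifnot(horizon > 0, step > 0)
  age <- if (step > horizon) c(0, horizon) else seq(0, horizon, by = step)
  if (age[length(age)] < horizon) age <- c(age, horizon)
  out <- data.frame(age = age,
                    survival = predict_survival(fixed, treatment, age,
                                                arm_weights))
  if (horizon >= 1)
    attr(out, "cutoff_1y") <- predict_survival(fixed, treatment, 1, arm_weights)
  if (horizon >= 4)
    attr(out, "cutoff_4y") <- predict_survival(fixed, treatment, 4, arm_weights)
  out
}
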