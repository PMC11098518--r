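test_that("population-level survival predictions match the model algebra", {
  fx <- survival_fixed_effects()
  expect_equal(predict_survival(fx, "Control", 4), 0.9412, tolerance = 1e-4)
  expect_equal(predict_survival(fx, "Cocoon", 0), 0.9807, tolerance = 1e-4)
  expect_equal(predict_survival(fx, "Waterboxx", 2),
               plogis(3.932 + 0.264 - 0.234 * 2))
  # strictly decreasing in age, and vanishing at extreme ages
  ages <- seq(0, 60, by = 0.5)
  p <- predict_survival(fx, "Hydrogel", ages)
  expect_true(all(diff(p) < 0))
  expect_lt(predict_survival(fx, "Hydrogel", 500), 1e-10)
  expect_error(predict_survival(fx, "Drone", 1), "valid levels")
})

test_that("predictions are invariant to shifting intercept against contrasts", {
  fx <- survival_fixed_effects()
  shift <- 0.7
  fx2 <- structure(list(intercept = fx$intercept - shift,
                        contrasts = fx$contrasts + shift,
                        age_slope = fx$age_slope, reference = fx$reference),
                   class = "survival_fixed_effects")
  for (tr in names(fx$contrasts))
    expect_equal(predict_survival(fx2, tr, c(0, 3, 7)),
                 predict_survival(fx, tr, c(0, 3, 7)))
})

test_that("survival curves have the documented grid and ordering", {
  fx <- survival_fixed_effects()
  cv <- survival_curve(fx, "Cocoon", horizon = 10, step = 0.25)
  expect_equal(nrow(cv), 41)
  expect_equal(attr(cv, "cutoff_1y"), predict_survival(fx, "Cocoon", 1))
  expect_equal(attr(cv, "cutoff_4y"), predict_survival(fx, "Cocoon", 4))
  # step larger than horizon: endpoints only
  expect_equal(nrow(survival_curve(fx, "Cocoon", horizon = 2, step = 5)), 2)
  # uniformly ordered curves under an additive model
  ch <- survival_curve(fx, "Cocoon+Hydrogel", 10, 0.25)$survival
  ct <- survival_curve(fx, "Control", 10, 0.25)$survival
  expect_true(all(ch >= ct))
})

test_that("the GLMM fit returns a complete, sane structure", {
  rec <- generate_cohort(small_config(n_plants = 60), seed = 7)
  fit <- fit_survival_glmm(rec)
  expect_s3_class(fit, "survival_fit")
  expect_equal(fit$n_plants, 60)
  expect_equal(fit$n_sites, 3)
  expect_equal(fit$n_obs, nrow(rec))
  expect_true(fit$random$var_plant >= 0 && fit$random$var_site >= 0)
  expect_equal(sort(names(fit$fixed$contrasts)), sort(treatment_levels()))
  expect_equal(fit$fixed$contrasts[["Cocoon"]], 0)
  expect_equal(dim(fit$vcov), c(7, 7))
  # covariance positive semi-definite
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("degenerate designs raise the documented errors", {
  rec <- generate_cohort(small_config(), seed = 7)
  one_arm <- rec
  one_arm$treatment <- "Control"
  expect_error(fit_survival_glmm(one_arm), "single level")
  one_site <- rec
  one_site$site_id <- "S01"
  expect_error(fit_survival_glmm(one_site), "2 sites")
  all_alive <- rec
  all_alive$alive <- TRUE
  expect_error(fit_survival_glmm(all_alive), "separation")
})

test_that("with zero generating variances the fit matches a plain logistic fit", {
  cfg <- cohort_config(n_plants = 150, n_sites = 4)
  rec <- generate_cohort(cfg, random = survival_random_effects(0, 0), seed = 3)
  fit <- fit_survival_glmm(rec)
  oracle <- glm(alive ~ relevel(factor(treatment), "Cocoon") + age,
                family = binomial(), data = rec)
  expect_lt(max(abs(fit$coef - coef(oracle))), 1e-4)
})

test_that("the Laplace log-likelihood agrees with the quadrature oracle", {
  rec <- generate_cohort(small_config(n_plants = 40), seed = 7)
  fit <- fit_survival_glmm(rec)
  ll_gh <- survival_loglik_gh(rec, fit$fixed, fit$random, nodes = 15)
  expect_lt(abs(fit$loglik - ll_gh), 0.5)
})

test_that("Wald tests follow the quadratic-form definition", {
  rec <- generate_cohort(small_config(n_plants = 60), seed = 9)
  fit <- fit_survival_glmm(rec)
  wt <- wald_test(fit, "Treatment")
  expect_equal(wt$df, 5)
  expect_gte(wt$chisq, 0)
  expect_true(wt$p >= 0 && wt$p <= 1)
  # 1-df term equals the squared z statistic
  wa <- wald_test(fit, "Age")
  z <- fit$coef[["age"]] / sqrt(fit$vcov["age", "age"])
  expect_equal(wa$chisq, z^2)
  expect_equal(wa$df, 1)
  # agreement with the car implementation of the same test
  skip_if_not_installed("car")
  ca <- car::Anova(fit$model, type = "III")
  expect_equal(wt$chisq, ca["treatment", "Chisq"], tolerance = 1e-8)
  expect_equal(wa$chisq, ca["age", "Chisq"], tolerance = 1e-8)
})

test_that("Wald algebra on hand-built fits", {
  cf <- c("(Intercept)" = 1, treatmentA = 0, treatmentB = 0, age = -0.2)
  wt <- wald_test(fake_fit(cf, diag(4)), "Treatment")
  expect_equal(wt$chisq, 0)
  expect_equal(wt$p, 1)
  expect_equal(wt$df, 2)
  V <- diag(4)
  V[2, 2] <- 0  # singular block
  expect_error(wald_test(fake_fit(cf, V), "Treatment"), "singular")
})
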