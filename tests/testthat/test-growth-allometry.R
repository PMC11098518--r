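test_that("multi-stem aggregation follows the summed-basal-area rule", {
  expect_equal(aggregate_multistem(c(3, 4)), 10)
  expect_equal(aggregate_multistem(7), 14)
  expect_equal(aggregate_multistem(c(1, 1, 1, 1)), 4)
  # permutation invariance and two-step consistency
  r <- c(2.3, 1.1, 4.7)
  expect_equal(aggregate_multistem(r), aggregate_multistem(rev(r)))
  two_step <- aggregate_multistem(c(aggregate_multistem(r[1:2]) / 2, r[3]))
  expect_equal(two_step, aggregate_multistem(r))
  expect_error(aggregate_multistem(numeric(0)), "invalid measurement")
  expect_error(aggregate_multistem(c(3, 0)), "invalid measurement")
})

test_that("OLS recovers an exact linear DBH law and passes through the means", {
  d <- exact_dbh_data()
  fit <- fit_dbh_model(d)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_equal(fit$age_coef, 0.8, tolerance = 1e-8)
  expect_equal(fit$height_coef, 0.01, tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-8)
  # prediction at the predictor means equals the mean response
  expect_equal(estimate_dbh(fit, mean(d$age), mean(d$height)), mean(d$dbh),
               tolerance = 1e-10)
  # positive coefficients: taller at equal age, and older at equal height,
  # both mean larger estimated DBH
  expect_gt(estimate_dbh(fit, 5, 600), estimate_dbh(fit, 5, 400))
  expect_gt(estimate_dbh(fit, 8, 400), estimate_dbh(fit, 5, 400))
})

test_that("degenerate DBH designs are rejected", {
  d <- exact_dbh_data(n = 30)
  expect_error(fit_dbh_model(d[1:2, ]), "3 observations")
  d$height <- 2 * d$age  # collinear
  expect_error(fit_dbh_model(d), "collinear")
  expect_error(fit_dbh_model(data.frame(dbh = 1:5, age = 1:5, height = 7)),
               "collinear|constant")
})

test_that("negative linear predictions are floored at zero", {
  fit <- fit_dbh_model(exact_dbh_data())
  fit$intercept <- -50
  expect_equal(estimate_dbh(fit, 0, 10), 0)
  zero <- fit
  zero$intercept <- 0; zero$age_coef <- 0; zero$height_coef <- 0
  expect_equal(estimate_dbh(zero, 3, 300), 0)
})

test_that("dry mass follows the two power laws", {
  ap <- allometry_params()
  m1 <- dry_mass(1, ap)
  expect_equal(m1$woody, 0.01540)     # unit DBH exposes the coefficients
  expect_equal(m1$foliage, 0.01769)
  m0 <- dry_mass(0, ap)
  expect_equal(m0$woody, 0)
  expect_equal(m0$foliage, 0)
  # at the maximum estimated DBH reported for the species
  mm <- dry_mass(17.61, ap)
  expect_equal(mm$woody, 0.01540 * (17.61^2)^1.60906)
  expect_equal(mm$woody, 157.3, tolerance = 1e-3)
  expect_equal(mm$foliage, 1.549, tolerance = 1e-3)
  expect_equal(tree_carbon(17.61, ap), 0.48 * (mm$woody + mm$foliage))
  expect_equal(tree_carbon(17.61, ap), 76.2, tolerance = 1e-3)
  expect_error(dry_mass(-1, ap), "invalid input")
})

test_that("a mid-teens DBH stores carbon in the published per-tree band", {
  expect_equal(tree_carbon(14.16), 38.0, tolerance = 0.01)
})

test_that("dry mass is monotone and increasingly woody in DBH", {
  d <- seq(0.5, 25, by = 0.5)
  m <- dry_mass(d)
  expect_true(all(diff(m$woody) > 0))
  expect_true(all(diff(m$foliage) > 0))
  expect_true(all(diff(m$woody / m$foliage) > 0))  # b_w > b_f
})

test_that("tree carbon is linear in the carbon fraction", {
  a1 <- suppressWarnings(allometry_params(carbon_fraction = 0.24))
  a2 <- allometry_params(carbon_fraction = 0.48)
  expect_equal(2 * tree_carbon(c(5, 12, 18), a1), tree_carbon(c(5, 12, 18), a2))
  expect_warning(allometry_params(carbon_fraction = 0.55), "0.47-0.49")
  expect_error(allometry_params(carbon_fraction = 0), "carbon_fraction")
})

test_that("the subsample builder aggregates measured stems correctly", {
  rec <- generate_cohort(small_config(n_plants = 80), seed = 12)
  sub <- build_dbh_subsample(rec)
  expect_true(all(sub$dbh > 0))
  expect_true(all(sub$n_stems %in% 1:3))
  expect_true(all(sub$height >= 137))
  # equivalent DBH preserves total basal area of the recorded stems
  row <- which(sub$n_stems > 1)[1]
  skip_if(is.na(row), "no multi-stem tree in this fixture")
  rid <- sub$plant_id[row]
  rr <- rec[rec$plant_id == rid & !is.na(rec$stem_circumferences), ]
  radii <- stem_radii(rr$stem_circumferences)[[1]]
  expect_equal(pi * (sub$dbh[row] / 2)^2, sum(pi * radii^2))
})

test_that("fitted correlations on a default cohort approximate the field ones", {
  rec <- generate_cohort(seed = 31)
  fit <- fit_dbh_model(build_dbh_subsample(rec), rec)
  expect_equal(fit$r_height, 0.967, tolerance = 0.02)
  expect_equal(fit$r_age, 0.919, tolerance = 0.02)
  expect_true(abs(fit$r_height) <= 1 && abs(fit$r_age) <= 1)
})
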