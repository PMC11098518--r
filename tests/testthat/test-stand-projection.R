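ref_dbh_fit <- function() {
  # a fixed DBH plane close to the default calibration, so projection tests
  # do not depend on a generated cohort
  fit <- fit_dbh_model(exact_dbh_data())
  fit$intercept <- 0.284; fit$age_coef <- 0.74; fit$height_coef <- 0.008
  fit
}

test_that("per-tree trajectories start at zero and never decrease", {
  tree <- per_tree_trajectory(dbh_fit = ref_dbh_fit())
  expect_equal(nrow(tree), 41)
  expect_equal(tree$carbon_kg[1], 0)  # seedlings are below breast height
  expect_true(all(diff(tree$carbon_kg) >= 0))
  expect_true(all(diff(tree$height) > 0))
  # year-10 value sits at or above the published per-tree lower end
  expect_gte(tree$carbon_kg[41], 37)
})

test_that("per-tree carbon is proportional to the carbon fraction", {
  a1 <- suppressWarnings(allometry_params(carbon_fraction = 0.24))
  t1 <- per_tree_trajectory(dbh_fit = ref_dbh_fit(), allom = a1)
  t2 <- per_tree_trajectory(dbh_fit = ref_dbh_fit())
  expect_equal(2 * t1$carbon_kg, t2$carbon_kg)
})

test_that("Brownian noise paths are mean-one with the pinned horizon SD", {
  set.seed(4)
  expect_equal(brownian_noise_path(40, 0), rep(1, 41))
  one <- brownian_noise_path(40, 0.2)
  expect_equal(one[1], 1)
  expect_length(one, 41)
  expect_true(all(one > 0))
  ends <- replicate(10000, brownian_noise_path(40, 0.2)[41])
  expect_lt(abs(mean(ends) - 1), 0.006)
  expect_lt(abs(sd(ends) - 0.2), 0.015)
})

test_that("with noise off the projection equals the closed-form product", {
  cfg <- projection_config(noise_level = 0, n_replicates = 3, seed = 2)
  fx <- survival_fixed_effects()
  tree <- per_tree_trajectory(dbh_fit = ref_dbh_fit())
  pr <- project_stand(cfg, fx, tree)
  oracle <- 530 * predict_survival(fx, "all-data", pr$times) *
    tree$carbon_kg / 1000
  expect_equal(pr$mean_carbon, oracle, tolerance = 1e-12)
  expect_equal(pr$se_carbon, rep(0, 41))
  # and is invariant under grid refinement at shared times
  cfg2 <- projection_config(noise_level = 0, n_replicates = 3, step = 0.125)
  tree2 <- per_tree_trajectory(dbh_fit = ref_dbh_fit(), step = 0.125)
  pr2 <- project_stand(cfg2, fx, tree2)
  expect_equal(pr2$mean_carbon[81], pr$mean_carbon[41], tolerance = 1e-12)
})

test_that("degenerate projections collapse as expected", {
  tree <- per_tree_trajectory(dbh_fit = ref_dbh_fit())
  fx <- survival_fixed_effects()
  zero <- project_stand(projection_config(density = 0, n_replicates = 5), fx, tree)
  expect_equal(zero$mean_carbon, rep(0, 41))
  # survival forced to ~0 after planting: flat-zero trajectory
  dead <- survival_fixed_effects(contrasts = c("Doomed" = -1e6))
  prd <- project_stand(projection_config(treatment = "Doomed", n_replicates = 5),
                       dead, tree)
  expect_true(all(prd$mean_carbon[-1] < 1e-6))
  expect_error(project_stand(projection_config(), fx, tree[1:10, ]),
               "grid mismatch")
})

test_that("replicate standard errors shrink like one over root n", {
  fx <- survival_fixed_effects()
  tree <- per_tree_trajectory(dbh_fit = ref_dbh_fit())
  se100 <- project_stand(projection_config(n_replicates = 100, seed = 5),
                         fx, tree)$se_carbon[41]
  se400 <- project_stand(projection_config(n_replicates = 400, seed = 6),
                         fx, tree)$se_carbon[41]
  expect_lt(abs(se400 / se100 - 0.5), 0.125)
})

test_that("higher survival contrasts dominate pointwise with noise off", {
  fx <- survival_fixed_effects()
  tree <- per_tree_trajectory(dbh_fit = ref_dbh_fit())
  cfg <- function(tr) projection_config(noise_level = 0, n_replicates = 1,
                                        treatment = tr)
  hi <- project_stand(cfg("Cocoon+Hydrogel"), fx, tree)
  lo <- project_stand(cfg("Control"), fx, tree)
  expect_true(all(hi$mean_carbon >= lo$mean_carbon))
})

test_that("treatment comparison reproduces the ~21 Mg/ha stand estimates", {
  fx <- survival_fixed_effects()
  tree <- per_tree_trajectory(dbh_fit = ref_dbh_fit())
  tab <- compare_treatments(projection_config(n_replicates = 200, seed = 9),
                            fx, tree,
                            treatments = c("Control", "Waterboxx", "all-data"))
  expect_equal(nrow(tab), 3)
  ctl <- tab$mean_carbon[tab$treatment == "Control"]
  wbx <- tab$mean_carbon[tab$treatment == "Waterboxx"]
  expect_equal(ctl, 21, tolerance = 0.15)
  expect_equal(wbx, 21, tolerance = 0.15)
  # ordering follows the survival contrasts
  expect_gt(wbx, ctl)
})
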