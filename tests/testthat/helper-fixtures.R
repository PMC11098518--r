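# Small cohort configurations used across tests (kept little so fits are fast)

small_config <- function(n_plants = 40, n_sites = 3, ...) {
  cohort_config(n_plants = n_plants, n_sites = n_sites,
                planting_start = "2019-01-01", planting_end = "2020-06-30",
                census_end = "2022-12-31",
                island_split = c("Santa Cruz" = 2 / 3, "Floreana" = 1 / 3),
                ...)
}

# one-arm-per-plant exact linear DBH data
exact_dbh_data <- function(n = 50, b0 = 1, b_age = 0.8, b_height = 0.01,
                           seed = 11) {
  set.seed(seed)
  age <- runif(n, 0, 10)
  height <- runif(n, 100, 900)
  data.frame(age = age, height = height,
             dbh = b0 + b_age * age + b_height * height)
}

# hand-built survival fit with a chosen coefficient vector and covariance,
# for algebra-level Wald checks
fake_fit <- function(coef, vcov) {
  structure(list(coef = coef, vcov = vcov, converged = TRUE),
            class = "survival_fit")
}
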