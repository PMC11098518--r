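#' Configuration of a stand-level carbon projection
#'
#' @param density Stand density in trees/ha (default 530, the mean planting
#'   density of the restoration sites).
#' @param horizon Projection horizon in years (default 10, a realistic
#'   restoration time frame).
#' @param step Time step in years (default quarterly, matching the census
#'   interval).
#' @param noise_level Standard deviation of the multiplicative Brownian
#'   noise factor at the horizon (default 0.20); must lie in [0, 1).
#' @param n_replicates Number of stochastic replicates (default 500).
#' @param treatment Survival scenario: a treatment level or
#'   \code{"all-data"}.
#' @param seed Integer seed for the noise paths.
#' @return A list of class \code{"projection_config"}.
#' @export
projection_config <- function(density = 530, horizon = 10, step = 0.25,
                              noise_level = 0.20, n_replicates = 500,
                              treatment = "all-data", seed = 1) {
  if (density < 0) stop("'density' must be >= 0", call. = FALSE)
  if (horizon <= 0 || step <= 0)
    stop("'horizon' and 'step' must be positive", call. = FALSE)
  if (noise_level < 0 || noise_level >= 1)
    stop("'noise_level' must lie in [0, 1)", call. = FALSE)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(list(density = density, horizon = horizon, step = step,
                 noise_level = noise_level,
                 n_replicates = as.integer(n_replicates),
                 treatment = treatment, seed = as.integer(seed)),
            class = "projection_config")
}

#' Per-tree carbon trajectory
#'
#' Composes the mean height growth curve, the linear DBH estimator and the
#' allometric carbon equations into the expected cumulative aboveground
#' carbon of one surviving tree over time. Trees still below breast height
#' carry DBH 0 by convention, so the series starts at 0.
#'
#' @param growth A \code{\link{growth_params}} set (mean curve, unit
#'   growth factor, no noise).
#' @param dbh_fit A fitted \code{\link{fit_dbh_model}}.
#' @param allom An \code{\link{allometry_params}} set.
#' @param horizon,step Time grid in years.
#' @return data.frame with columns \code{age} (years), \code{height} (cm),
#'   \code{dbh} (cm) and \code{carbon_kg} (kg C per surviving tree).
#' @export
per_tree_trajectory <- function(growth = growth_params(), dbh_fit,
                                allom = allometry_params(),
                                horizon = 10, step = 0.25) {
  stopifnot(horizon > 0, step > 0)
  age <- seq(0, horizon, by = step)
  height <- height_at_age(age, growth)
  dbh <- ifelse(height < growth$breast_height, 0,
                estimate_dbh(dbh_fit, age, height))
  data.frame(age = age, height = height, dbh = dbh,
             carbon_kg = tree_carbon(dbh, allom))
}

#' Multiplicative Brownian noise path
#'
#' Mean-one geometric random-walk factors on a regular grid: the log factor
#' accumulates i.i.d. Gaussian increments with a variance-compensating
#' drift, so that every factor has expectation 1 and the factor at the last
#' step has standard deviation \code{noise_level} (lognormal construction:
#' terminal log-variance \eqn{v = \log(1 + noise^2)}). Factors are strictly
#' positive and the path starts at exactly 1.
#'
#' @param n_steps Number of increments (>= 1); the returned path has
#'   \code{n_steps + 1} points including the initial 1.
#' @param noise_level Target standard deviation of the terminal factor.
#' @return Numeric vector of length \code{n_steps + 1}.
#' @export
brownian_noise_path <- function(n_steps, noise_level) {
  stopifnot(n_steps >= 1, noise_level >= 0, noise_level < 1)
  if (noise_level == 0) return(rep(1, n_steps + 1))
  v <- log(1 + noise_level^2)
  s2 <- v / n_steps
  inc <- stats::rnorm(n_steps, mean = -s2 / 2, sd = sqrt(s2))
  c(1, exp(cumsum(inc)))
}

#' Project stand-level carbon sequestration
#'
#' The carbon sequestration model proper: for each stochastic replicate,
#' stand carbon at time \eqn{t} is
#' \deqn{C(t) = density \times S(t) \times c(t) \times F(t) / 1000}
#' in Mg C/ha, where \eqn{S(t)} is the population-level survival
#' probability of the configured scenario, \eqn{c(t)} the per-tree carbon
#' (kg) of a surviving tree, and \eqn{F(t)} a mean-one multiplicative
#' Brownian noise path. Survival enters as the expected surviving fraction
#' (a continuous projection, not Bernoulli thinning of discrete trees).
#' Means and standard errors are taken across replicates.
#'
#' @param config A \code{\link{projection_config}}.
#' @param survival_fixed A \code{\link{survival_fixed_effects}} set.
#' @param tree_curve A \code{\link{per_tree_trajectory}} data.frame; its
#'   age grid must match the projection grid.
#' @param arm_weights Optional arm weights for the \code{"all-data"}
#'   scenario.
#' @param keep_replicates Keep the replicate matrix in the result.
#' @return An object of class \code{"projection_result"}: list with
#'   \code{times}, \code{survival}, \code{mean_carbon}, \code{se_carbon}
#'   (Mg C/ha), \code{config} and optionally \code{replicates}
#'   (replicates x times matrix).
#' @export
project_stand <- function(config = projection_config(),
                          survival_fixed = survival_fixed_effects(),
                          tree_curve,
                          arm_weights = NULL,
                          keep_replicates = FALSE) {
  times <- seq(0, config$horizon, by = config$step)
  if (nrow(tree_curve) != length(times) ||
      max(abs(tree_curve$age - times)) > 1e-9)
    stop("grid mismatch: tree_curve ages do not match the projection grid",
         call. = FALSE)
  surv <- predict_survival(survival_fixed, config$treatment, times,
                           arm_weights)
  det <- config$density * surv * tree_curve$carbon_kg / 1000
  set.seed(config$seed)
  n_steps <- length(times) - 1
  reps <- matrix(NA_real_, nrow = config$n_replicates, ncol = length(times))
  for (r in seq_len(config$n_replicates))
    reps[r, ] <- det * brownian_noise_path(n_steps, config$noise_level)
  mean_c <- colMeans(reps)
  se_c <- apply(reps, 2, stats::sd) / sqrt(config$n_replicates)
  structure(list(times = times, survival = surv, mean_carbon = mean_c,
                 se_carbon = se_c, config = config,
                 replicates = if (keep_replicates) reps else NULL),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  k <- length(x$times)
  cat("Stand carbon projection\n")
  cat(sprintf("  scenario: %s; %g trees/ha; %g-year horizon; %d replicates; noise %.0f%%\n",
              x$config$treatment, x$config$density, x$config$horizon,
              x$config$n_replicates, 100 * x$config$noise_level))
  cat(sprintf("  carbon at year %g: %.2f +/- %.2f Mg C/ha (survival %.3f)\n",
              x$times[k], x$mean_carbon[k], x$se_carbon[k], x$survival[k]))
  invisible(x)
}

#' Tidy a projection result into a data.frame
#'
#' @param result A \code{"projection_result"}.
#' @return data.frame with columns \code{time}, \code{survival},
#'   \code{mean_carbon}, \code{se_carbon}.
#' @export
as.data.frame.projection_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(time = x$times, survival = x$survival,
             mean_carbon = x$mean_carbon, se_carbon = x$se_carbon)
}

#' Compare stand projections across treatments
#'
#' Runs \code{\link{project_stand}} for each requested treatment plus the
#' pooled \code{"all-data"} scenario, on a shared grid and with the same
#' seed policy, and tabulates the horizon-year means and standard errors.
#'
#' @param config A \code{\link{projection_config}} (its \code{treatment}
#'   field is overridden per scenario).
#' @param survival_fixed A \code{\link{survival_fixed_effects}} set.
#' @param tree_curve A \code{\link{per_tree_trajectory}} data.frame.
#' @param treatments Character vector of scenarios.
#' @param arm_weights Optional arm weights for \code{"all-data"}.
#' @return data.frame with one row per scenario: \code{treatment},
#'   \code{survival_horizon}, \code{mean_carbon}, \code{se_carbon}.
#' @export
compare_treatments <- function(config = projection_config(),
                               survival_fixed = survival_fixed_effects(),
                               tree_curve,
                               treatments = c(names(survival_fixed$contrasts),
                                              "all-data"),
                               arm_weights = NULL) {
  rows <- lapply(treatments, function(tr) {
    cfg <- config
    cfg$treatment <- tr
    pr <- project_stand(cfg, survival_fixed, tree_curve, arm_weights)
    k <- length(pr$times)
    data.frame(treatment = tr, survival_horizon = pr$survival[k],
               mean_carbon = pr$mean_carbon[k], se_carbon = pr$se_carbon[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
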