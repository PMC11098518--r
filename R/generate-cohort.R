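#' Conditional death probability for a census interval
#'
#' Converts two consecutive values of a survival-probability curve into the
#' conditional probability of dying during the interval, the quantity needed
#' to generate an absorbing death process whose survivor fraction follows
#' the curve in expectation: \eqn{h = 1 - p_t / p_{prev}}, clipped to
#' \eqn{[0, 1]}.
#'
#' @param p_t Survival probability at the end of the interval.
#' @param p_prev Survival probability at the previous census (> 0).
#' @return Conditional death probability in \eqn{[0, 1]} (vectorised).
#' @export
#' @examples
#' death_hazard_from_marginal(0.9, 0.95)
death_hazard_from_marginal <- function(p_t, p_prev) {
  if (any(p_prev <= 0))
    stop("undefined conditional: 'p_prev' must be > 0", call. = FALSE)
  if (any(p_prev > 1) || any(p_t < 0) || any(p_t > 1))
    stop("'p_t' and 'p_prev' must be probabilities", call. = FALSE)
  pmin(pmax(1 - p_t / p_prev, 0), 1)
}

#' Generate a synthetic monitoring cohort
#'
#' Simulates quarterly monitoring records for a cohort of planted
#' \emph{Scalesia pedunculata} seedlings: site and island membership,
#' treatment assignment, staggered planting dates, per-census alive status
#' governed by the logistic mixed survival model (fixed effects plus
#' plant- and site-level Gaussian random intercepts), heights along a
#' saturating growth curve, and breast-height stem circumferences at the
#' final census for trees tall enough to carry a DBH.
#'
#' By default the \code{alive} flag is the \emph{scored} census status,
#' drawn per census as an independent Bernoulli trial given the plant and
#' site effects -- exactly the repeated-measures model that
#' \code{\link{fit_survival_glmm}} estimates, so parameter-recovery
#' simulations are well posed. Occasional dead-then-alive sequences mimic
#' field scoring of defoliated plants. With
#' \code{config$drop_after_death = TRUE} the generator instead draws an
#' absorbing death time from interval hazards
#' (\code{\link{death_hazard_from_marginal}}) applied to the same
#' survival curve and truncates the record stream at death.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param growth A \code{\link{growth_params}}.
#' @param fixed A \code{\link{survival_fixed_effects}} set (generating
#'   survival coefficients).
#' @param random A \code{\link{survival_random_effects}} set (generating
#'   variances).
#' @param seed Integer seed; runs with equal seed are identical.
#' @return A data.frame with one row per monitoring record and columns
#'   \code{plant_id}, \code{site_id}, \code{island}, \code{treatment},
#'   \code{planting_date}, \code{census_date}, \code{age} (years),
#'   \code{alive}, \code{height} (cm, \code{NA} when not alive),
#'   \code{n_stems} and \code{stem_circumferences}
#'   (semicolon-separated cm, measured once at the final census).
#' @export
generate_cohort <- function(config = cohort_config(),
                            growth = growth_params(),
                            fixed = survival_fixed_effects(),
                            random = survival_random_effects(),
                            seed = 1) {
  stopifnot(inherits(config, "cohort_config"), inherits(growth, "growth_params"))
  if (!all(is.finite(c(fixed$intercept, fixed$contrasts, fixed$age_slope))))
    stop("survival parameters must be finite", call. = FALSE)
  set.seed(as.integer(seed))
  n <- config$n_plants
  n_sites <- config$n_sites

  ## sites: assign islands by the configured split, plants uniformly to sites
  n_isl <- round(config$island_split * n_sites)
  n_isl[1] <- n_sites - sum(n_isl[-1])
  site_island <- rep(names(config$island_split), n_isl)
  site <- sample.int(n_sites, n, replace = TRUE)
  trt <- sample(names(config$treatment_allocation), n, replace = TRUE,
                prob = config$treatment_allocation)

  ## staggered planting: density increasing quadratically towards the end
  span <- as.numeric(config$planting_end - config$planting_start)
  pdate <- config$planting_start + round(span * stats::runif(n)^(1 / 3))

  b_site <- stats::rnorm(n_sites, 0, sqrt(random$var_site))
  b_plant <- stats::rnorm(n, 0, sqrt(random$var_plant))
  h0 <- pmax(stats::rnorm(n, config$init_height_mean, config$init_height_sd), 5)
  gf <- exp(stats::rnorm(n, -growth$plant_growth_sdlog^2 / 2,
                         growth$plant_growth_sdlog))

  contr <- fixed$contrasts[trt]
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    dates <- seq(pdate[i], config$census_end,
                 by = paste(config$monitoring_interval, "months"))
    age <- as.numeric(dates - pdate[i]) / 365.25
    eta <- fixed$intercept + contr[i] + fixed$age_slope * age +
      b_plant[i] + b_site[site[i]]
    p <- stats::plogis(eta)
    m <- length(age)
    if (config$drop_after_death) {
      alive <- logical(m)
      alive[1] <- stats::runif(1) < p[1]
      if (m > 1) for (j in 2:m) {
        if (!alive[j - 1]) { alive[j] <- FALSE; next }
        alive[j] <- stats::runif(1) >= death_hazard_from_marginal(p[j], p[j - 1])
      }
      if (any(!alive)) {
        k <- which(!alive)[1]
        dates <- dates[1:k]; age <- age[1:k]; alive <- alive[1:k]; m <- k
      }
    } else {
      alive <- stats::runif(m) < p
    }
    h_true <- height_at_age(age, growth, h0[i], gf[i])
    height <- pmax(pmin(h_true * (1 + stats::rnorm(m, 0, growth$height_noise_cv)),
                        growth$max_height), 5)
    height[!alive] <- NA_real_

    ## breast-height stem measurement at the final census
    n_stems <- rep(NA_integer_, m)
    circ <- rep(NA_character_, m)
    if (alive[m] && !is.na(height[m]) && height[m] >= growth$breast_height) {
      dbh <- max(growth$dbh_intercept + growth$dbh_age_coef * age[m] +
                   growth$dbh_height_coef * height[m] +
                   stats::rnorm(1, 0, growth$dbh_noise_sd), 0.3)
      if (stats::runif(1) < growth$multi_stem_prob) {
        k <- sample(2:3, 1)
        w <- stats::runif(k, 0.2, 1); w <- w / sum(w)
        r <- sqrt(w) * dbh / 2        # split basal area among stems
      } else {
        r <- dbh / 2
      }
      n_stems[m] <- length(r)
      circ[m] <- paste(sprintf("%.4f", 2 * pi * r), collapse = ";")
    }
    recs[[i]] <- data.frame(
      plant_id = sprintf("P%04d", i), site_id = sprintf("S%02d", site[i]),
      island = site_island[site[i]], treatment = trt[i],
      planting_date = pdate[i], census_date = dates, age = age, alive = alive,
      height = height, n_stems = n_stems, stem_circumferences = circ,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write / read a monitoring table
#'
#' Plain-CSV serialisation of the monitoring record table with a fixed
#' header; \code{read_monitoring_csv} restores column types (dates, logical
#' alive flag) so that a round trip reproduces the table exactly.
#'
#' @param records Monitoring record data.frame from
#'   \code{\link{generate_cohort}}.
#' @param path File path.
#' @return \code{read_monitoring_csv} returns the records data.frame.
#' @export
write_monitoring_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_monitoring_csv
#' @export
read_monitoring_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  d$planting_date <- as.Date(d$planting_date)
  d$census_date <- as.Date(d$census_date)
  d$alive <- as.logical(d$alive)
  d$height <- as.numeric(d$height)
  d$n_stems <- as.integer(d$n_stems)
  if (!is.character(d$stem_circumferences))
    d$stem_circumferences <- as.character(d$stem_circumferences)
  d
}

#' Parse a semicolon-separated stem circumference field into radii
#'
#' Circumferences (cm) are converted to radii by dividing by \eqn{2\pi}.
#'
#' @param x Character vector of semicolon-separated circumferences.
#' @return List of numeric radius vectors (cm).
#' @export
stem_radii <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    as.numeric(v) / (2 * pi)
  })
}
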