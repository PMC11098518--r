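#' Build the DBH calibration subsample from a monitoring table
#'
#' Extracts, for every plant whose final census is alive and carries a
#' breast-height stem measurement, one row with the plant's age, height and
#' equivalent DBH at that census. Circumferences are converted to radii
#' (division by \eqn{2\pi}) and multi-stem trees aggregated with
#' \code{\link{aggregate_multistem}}.
#'
#' @param records Monitoring data.frame from \code{\link{generate_cohort}}
#'   or \code{\link{read_monitoring_csv}}.
#' @return data.frame with columns \code{plant_id}, \code{age},
#'   \code{height}, \code{n_stems}, \code{dbh}.
#' @export
build_dbh_subsample <- function(records) {
  keep <- !is.na(records$stem_circumferences) & records$alive
  d <- records[keep, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no records with stem measurements found", call. = FALSE)
  radii <- stem_radii(d$stem_circumferences)
  data.frame(plant_id = d$plant_id, age = d$age, height = d$height,
             n_stems = lengths(radii),
             dbh = vapply(radii, aggregate_multistem, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Fit the linear DBH estimator
#'
#' Ordinary least squares of DBH on age and height over the calibration
#' subsample: \code{dbh ~ age + height}. When the full monitoring table is
#' also supplied, the Pearson correlations of the model-estimated DBH with
#' age and with height are computed over all alive records (the published
#' quality check for the estimator), otherwise over the subsample.
#'
#' @param subsample data.frame with columns \code{dbh}, \code{age},
#'   \code{height} (>= 3 rows), e.g. from \code{\link{build_dbh_subsample}}.
#' @param records Optional full monitoring table for the correlation check.
#' @return An object of class \code{"dbh_fit"}: list with
#'   \code{intercept} (cm), \code{age_coef} (cm/year), \code{height_coef}
#'   (cm/cm), \code{residual_sd} (cm), \code{r_age}, \code{r_height},
#'   \code{n}, and \code{lm} (the underlying fit).
#' @export
fit_dbh_model <- function(subsample, records = NULL) {
  need <- c("dbh", "age", "height")
  if (!all(need %in% names(subsample)))
    stop("subsample must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(subsample) < 3)
    stop("need at least 3 observations to fit the DBH model", call. = FALSE)
  if (stats::sd(subsample$age) == 0 || stats::sd(subsample$height) == 0 ||
      abs(stats::cor(subsample$age, subsample$height)) > 1 - 1e-12)
    stop("rank-deficient design: age and height are constant or collinear",
         call. = FALSE)
  m <- stats::lm(dbh ~ age + height, data = subsample)
  cf <- stats::coef(m)
  fit <- structure(list(
    intercept = cf[["(Intercept)"]], age_coef = cf[["age"]],
    height_coef = cf[["height"]],
    residual_sd = sqrt(sum(stats::resid(m)^2) / stats::df.residual(m)),
    r_age = NA_real_, r_height = NA_real_,
    n = nrow(subsample), lm = m), class = "dbh_fit")
  corset <- if (is.null(records)) subsample else
    records[records$alive & !is.na(records$height), c("age", "height")]
  est <- estimate_dbh(fit, corset$age, corset$height)
  fit$r_age <- stats::cor(est, corset$age)
  fit$r_height <- stats::cor(est, corset$height)
  fit
}

#' @export
print.dbh_fit <- function(x, ...) {
  cat("Linear DBH estimator: dbh ~ age + height\n")
  cat(sprintf("  dbh = %.4f + %.4f * age + %.5f * height   (n = %d, residual SD %.3f cm)\n",
              x$intercept, x$age_coef, x$height_coef, x$n, x$residual_sd))
  cat(sprintf("  Pearson r of estimated DBH: age %.3f, height %.3f\n",
              x$r_age, x$r_height))
  invisible(x)
}

#' Estimate DBH from age and height
#'
#' Linear prediction from a fitted \code{\link{fit_dbh_model}}, floored at
#' 0 cm (the fitted plane can dip below zero for very young, short plants).
#'
#' @param fit A \code{"dbh_fit"} object.
#' @param age Age in years (>= 0, vectorised).
#' @param height Height in cm (> 0, vectorised).
#' @return Estimated DBH in cm.
#' @export
estimate_dbh <- function(fit, age, height) {
  stopifnot(all(age >= 0), all(height > 0))
  pmax(fit$intercept + fit$age_coef * age + fit$height_coef * height, 0)
}

#' Write a fitted DBH model as CSV
#'
#' One-row CSV of coefficients and diagnostics; \code{read_dbh_fit_csv}
#' restores a usable \code{"dbh_fit"} object (without the underlying
#' \code{lm}).
#'
#' @param fit A \code{"dbh_fit"} object.
#' @param path File path.
#' @export
write_dbh_fit_csv <- function(fit, path) {
  utils::write.csv(data.frame(
    intercept = fit$intercept, age_coef = fit$age_coef,
    height_coef = fit$height_coef, residual_sd = fit$residual_sd,
    r_age = fit$r_age, r_height = fit$r_height, n = fit$n),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dbh_fit_csv
#' @export
read_dbh_fit_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(c(as.list(d[1, ]), list(lm = NULL)), class = "dbh_fit")
}
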