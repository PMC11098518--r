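#' Treatment arms used in the restoration trials
#'
#' The six planting treatments: passive irrigation boxes (Waterboxx, a
#' refillable 20 L reservoir; Cocoon, a biodegradable cardboard analogue),
#' water-retaining hydrogel mixed into the planting hole, the two
#' box-plus-hydrogel combinations, and a watered control.
#'
#' @return Character vector of the six treatment levels. \code{"Cocoon"} is
#'   the reference level of the survival model.
#' @export
treatment_levels <- function() {
  c("Cocoon", "Cocoon+Hydrogel", "Control", "Hydrogel",
    "Waterboxx", "Waterboxx+Hydrogel")
}

#' Configuration of a synthetic monitoring cohort
#'
#' Describes the observational design of a restoration cohort: how many
#' seedlings are planted, across how many sites and islands, how they are
#' allocated to treatments, over which planting window, and on what census
#' schedule. Defaults reproduce the structure of the Galapagos Verde trials:
#' 426 seedlings across 10 sites on Santa Cruz and Floreana, planted between
#' May 2013 and September 2021, censused every 3 months until April 2023,
#' with initial seedling heights of 35.52 +/- 14.63 cm.
#'
#' @param n_plants Number of seedlings planted.
#' @param n_sites Number of study sites (farms).
#' @param island_split Named proportions of sites per island; must sum to 1.
#' @param treatment_allocation Named proportions of plants per treatment arm;
#'   must cover a subset of \code{treatment_levels()} and sum to 1. The
#'   default weights the control and Waterboxx arms most heavily, matching
#'   the arms with the most field data.
#' @param planting_start,planting_end Planting window (coercible to Date).
#'   Planting dates are drawn with density increasing quadratically towards
#'   the end of the window, reflecting the staggered addition of new sites.
#' @param monitoring_interval Census interval in months.
#' @param census_end Last census date.
#' @param init_height_mean,init_height_sd Initial seedling height (cm),
#'   drawn normal and truncated below at 5 cm.
#' @param drop_after_death If \code{TRUE}, a plant's record stream stops at
#'   the census where death is first recorded. The default \code{FALSE}
#'   keeps the status panel complete (dead plants contribute
#'   \code{alive = FALSE} rows until \code{census_end}), which is the design
#'   under which the logistic-in-age survival model is the correct marginal
#'   model of census status.
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_plants = 426,
                          n_sites = 10,
                          island_split = c("Santa Cruz" = 0.8, "Floreana" = 0.2),
                          treatment_allocation = c(
                            "Cocoon" = 0.15, "Cocoon+Hydrogel" = 0.10,
                            "Control" = 0.25, "Hydrogel" = 0.15,
                            "Waterboxx" = 0.25, "Waterboxx+Hydrogel" = 0.10),
                          planting_start = "2013-05-01",
                          planting_end = "2021-09-30",
                          monitoring_interval = 3,
                          census_end = "2023-04-30",
                          init_height_mean = 35.52,
                          init_height_sd = 14.63,
                          drop_after_death = FALSE) {
  if (length(n_plants) != 1 || is.na(n_plants) || n_plants < 1)
    stop("invalid cohort config: 'n_plants' must be a positive count", call. = FALSE)
  if (n_sites < 2)
    stop("invalid cohort config: need at least 2 sites", call. = FALSE)
  if (length(treatment_allocation) == 0)
    stop("invalid cohort config: 'treatment_allocation' is empty", call. = FALSE)
  if (!all(names(treatment_allocation) %in% treatment_levels()))
    stop("invalid cohort config: unknown treatment level(s): ",
         paste(setdiff(names(treatment_allocation), treatment_levels()),
               collapse = ", "), call. = FALSE)
  if (abs(sum(treatment_allocation) - 1) > 1e-8)
    stop("invalid cohort config: treatment allocation must sum to 1", call. = FALSE)
  if (abs(sum(island_split) - 1) > 1e-8)
    stop("invalid cohort config: island split must sum to 1", call. = FALSE)
  if (monitoring_interval <= 0)
    stop("invalid cohort config: monitoring interval must be positive", call. = FALSE)
  if (init_height_sd < 0)
    stop("invalid cohort config: 'init_height_sd' must be >= 0", call. = FALSE)
  planting_start <- as.Date(planting_start)
  planting_end <- as.Date(planting_end)
  census_end <- as.Date(census_end)
  if (planting_end <= planting_start || census_end <= planting_start)
    stop("invalid cohort config: dates out of order", call. = FALSE)
  structure(list(
    n_plants = as.integer(n_plants), n_sites = as.integer(n_sites),
    island_split = island_split, treatment_allocation = treatment_allocation,
    planting_start = planting_start, planting_end = planting_end,
    monitoring_interval = monitoring_interval, census_end = census_end,
    init_height_mean = init_height_mean, init_height_sd = init_height_sd,
    drop_after_death = isTRUE(drop_after_death)
  ), class = "cohort_config")
}

#' Parameters of the height growth and DBH generating process
#'
#' Height follows a monotone saturating (von Bertalanffy type) curve from
#' the initial seedling height towards an asymptote, with a lognormal
#' per-plant growth factor and per-census measurement noise. The "true"
#' diameter at breast height (DBH) of a tree is generated as a linear
#' function of age and height plus noise; a fraction of trees fork into 2-3
#' stems at breast height, splitting the basal area.
#'
#' Defaults are calibrated so that (i) the mean tree reaches about 9.2 m and
#' an estimated DBH of about 15 cm at age 10, placing per-tree carbon where
#' the stand-level projection reaches ~21 Mg C/ha at 530 trees/ha, and
#' (ii) estimated DBH correlates with height at ~0.97 and with age at ~0.92
#' over a default cohort's records.
#'
#' @param asymptotic_height Height asymptote of the mean growth curve (cm);
#'   must exceed the initial seedling height and stay at or below 15 m.
#' @param growth_rate von Bertalanffy rate constant (per year).
#' @param plant_growth_sdlog SD (log scale) of the mean-one lognormal
#'   per-plant growth factor applied to the height increment.
#' @param height_noise_cv Per-census height measurement noise,
#'   proportional to true height (coefficient of variation).
#' @param max_height Hard cap on generated heights (cm); the species does
#'   not exceed about 15 m.
#' @param dbh_intercept,dbh_age_coef,dbh_height_coef Coefficients (cm,
#'   cm/year, cm/cm) of the generating DBH plane.
#' @param dbh_noise_sd Residual SD of generated DBH (cm).
#' @param multi_stem_prob Probability that a measured tree has forked into
#'   multiple stems at breast height.
#' @param breast_height Breast height (cm); plants shorter than this carry
#'   no DBH.
#' @return A list of class \code{"growth_params"}.
#' @export
growth_params <- function(asymptotic_height = 1000,
                          growth_rate = 0.25,
                          plant_growth_sdlog = 0.35,
                          height_noise_cv = 0.04,
                          max_height = 1500,
                          dbh_intercept = 0.284,
                          dbh_age_coef = 0.74,
                          dbh_height_coef = 0.008,
                          dbh_noise_sd = 1.0,
                          multi_stem_prob = 0.15,
                          breast_height = 137) {
  if (asymptotic_height <= 35.52 || asymptotic_height > 1500)
    stop("'asymptotic_height' must lie between the seedling height and 1500 cm",
         call. = FALSE)
  if (growth_rate <= 0) stop("'growth_rate' must be positive", call. = FALSE)
  if (height_noise_cv < 0 || dbh_noise_sd < 0 || plant_growth_sdlog < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (multi_stem_prob < 0 || multi_stem_prob > 1)
    stop("'multi_stem_prob' must be a probability", call. = FALSE)
  structure(list(
    asymptotic_height = asymptotic_height, growth_rate = growth_rate,
    plant_growth_sdlog = plant_growth_sdlog, height_noise_cv = height_noise_cv,
    max_height = max_height,
    dbh_intercept = dbh_intercept, dbh_age_coef = dbh_age_coef,
    dbh_height_coef = dbh_height_coef, dbh_noise_sd = dbh_noise_sd,
    multi_stem_prob = multi_stem_prob, breast_height = breast_height
  ), class = "growth_params")
}

#' Mean height growth curve
#'
#' Expected height at a given age under a \code{\link{growth_params}} set,
#' for a plant with the mean initial height and unit growth factor:
#' \deqn{h(a) = h_0 + f (H_\infty - h_0) (1 - e^{-k a})}
#'
#' @param age Age in years (vectorised).
#' @param growth A \code{\link{growth_params}} object.
#' @param init_height Initial height (cm).
#' @param factor Per-plant growth factor (1 = population mean).
#' @return Heights in cm, capped at \code{growth$max_height}.
#' @export
height_at_age <- function(age, growth = growth_params(),
                          init_height = 35.52, factor = 1) {
  stopifnot(all(age >= 0))
  h <- init_height + factor * (growth$asymptotic_height - init_height) *
    (1 - exp(-growth$growth_rate * age))
  pmin(h, growth$max_height)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d plants, %d sites, planting %s .. %s, censuses every %g months until %s\n",
              x$n_plants, x$n_sites, x$planting_start, x$planting_end,
              x$monitoring_interval, x$census_end))
  cat(sprintf("  initial height %.2f +/- %.2f cm; records %s at death\n",
              x$init_height_mean, x$init_height_sd,
              if (x$drop_after_death) "stop" else "continue"))
  alloc <- paste(sprintf("%s %.0f%%", names(x$treatment_allocation),
                         100 * x$treatment_allocation), collapse = ", ")
  cat("  allocation:", alloc, "\n")
  invisible(x)
}
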