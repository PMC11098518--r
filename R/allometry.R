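#' Allometric dry-mass parameters
#'
#' Coefficients of the two power laws that decompose aboveground dry
#' biomass into hard woody structures (trunk plus branches) and foliage,
#' both driven by squared DBH (cm^2), together with the carbon fraction of
#' dry biomass. Defaults are the published \emph{Scalesia pedunculata}
#' equations and the 48\% carbon content typical of tropical broad-leaved
#' species (plausible band 0.47-0.49; values outside it are accepted with
#' a warning).
#'
#' @param woody_a,woody_b Woody-compartment coefficient and exponent.
#' @param foliage_a,foliage_b Foliage-compartment coefficient and exponent.
#' @param carbon_fraction Proportion of dry biomass that is carbon.
#' @return A list of class \code{"allometry_params"}.
#' @export
allometry_params <- function(woody_a = 0.01540, woody_b = 1.60906,
                             foliage_a = 0.01769, foliage_b = 0.77946,
                             carbon_fraction = 0.48) {
  if (any(c(woody_a, woody_b, foliage_a, foliage_b) <= 0))
    stop("allometric coefficients must be positive", call. = FALSE)
  if (carbon_fraction <= 0 || carbon_fraction >= 1)
    stop("'carbon_fraction' must lie in (0, 1)", call. = FALSE)
  if (carbon_fraction < 0.47 || carbon_fraction > 0.49)
    warning("carbon_fraction ", carbon_fraction,
            " is outside the 0.47-0.49 band typical of tropical broad-leaved species")
  structure(list(woody_a = woody_a, woody_b = woody_b,
                 foliage_a = foliage_a, foliage_b = foliage_b,
                 carbon_fraction = carbon_fraction),
            class = "allometry_params")
}

#' Equivalent DBH of a multi-stemmed tree
#'
#' For trees forked below breast height, the stem cross-sectional areas are
#' summed, the sum divided by pi, and the square root taken to obtain one
#' representative radius, which is doubled to a diameter:
#' \eqn{DBH = 2 \sqrt{\sum_i r_i^2}}.
#'
#' @param stem_radii Numeric vector of stem radii at breast height (cm),
#'   all positive.
#' @return Equivalent DBH in cm.
#' @export
#' @examples
#' aggregate_multistem(c(3, 4))  # 10
aggregate_multistem <- function(stem_radii) {
  if (length(stem_radii) == 0 || any(!is.finite(stem_radii)) ||
      any(stem_radii <= 0))
    stop("invalid measurement: stem radii must be a non-empty set of positive values",
         call. = FALSE)
  2 * sqrt(sum(stem_radii^2))
}

#' Aboveground dry mass of one tree
#'
#' Two-compartment power-law allometry on squared DBH:
#' \eqn{M_w = a_w (DBH^2)^{b_w}}, \eqn{M_f = a_f (DBH^2)^{b_f}}, in kg.
#'
#' @param dbh Diameter at breast height (cm, >= 0; vectorised).
#' @param params An \code{\link{allometry_params}} set.
#' @return data.frame with columns \code{woody} and \code{foliage} (kg).
#' @export
dry_mass <- function(dbh, params = allometry_params()) {
  if (any(dbh < 0)) stop("invalid input: 'dbh' must be >= 0", call. = FALSE)
  d2 <- dbh^2
  data.frame(woody = params$woody_a * d2^params$woody_b,
             foliage = params$foliage_a * d2^params$foliage_b)
}

#' Carbon stored in one tree
#'
#' Carbon fraction times total (woody + foliage) dry mass.
#'
#' @inheritParams dry_mass
#' @return Carbon in kg (vectorised).
#' @export
tree_carbon <- function(dbh, params = allometry_params()) {
  m <- dry_mass(dbh, params)
  params$carbon_fraction * (m$woody + m$foliage)
}
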