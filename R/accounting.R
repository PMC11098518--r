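#' Inputs for archipelago-scale offset accounting
#'
#' @param per_ha_carbon Carbon stored per hectare over the horizon
#'   (Mg C/ha), e.g. the horizon-year mean of a stand projection.
#' @param area Planted area in ha (default 723, the Galapagos coffee area).
#' @param annual_footprint Archipelago CO2 footprint in Mg/year (default
#'   523000).
#' @param horizon Accounting horizon in years (default 10).
#' @param co2_per_c Mass ratio converting carbon to CO2 (default 44/12,
#'   the molecular ratio).
#' @return A list of class \code{"offset_inputs"}.
#' @export
offset_inputs <- function(per_ha_carbon, area = 723,
                          annual_footprint = 523000, horizon = 10,
                          co2_per_c = 44 / 12) {
  if (any(c(per_ha_carbon, area, annual_footprint, horizon) < 0))
    stop("offset inputs must be >= 0", call. = FALSE)
  if (co2_per_c < 1)
    stop("'co2_per_c' must be >= 1 (CO2 is heavier than C)", call. = FALSE)
  structure(list(per_ha_carbon = per_ha_carbon, area = area,
                 annual_footprint = annual_footprint, horizon = horizon,
                 co2_per_c = co2_per_c), class = "offset_inputs")
}

#' Total carbon storage over an area
#'
#' @param per_ha_carbon Mg C/ha accumulated over the horizon.
#' @param area Area in ha.
#' @return Total storage in Mg C.
#' @export
#' @examples
#' total_storage(21, 723)  # ~15 thousand Mg C
total_storage <- function(per_ha_carbon, area) {
  stopifnot(per_ha_carbon >= 0, area >= 0)
  per_ha_carbon * area
}

#' Footprint reduction percentage
#'
#' Expresses the CO2-equivalent of the carbon stored over the horizon as a
#' (negative) percentage of the cumulative archipelago footprint:
#' \deqn{-100 \frac{C_{ha} \cdot (44/12) \cdot area}
#'       {footprint \cdot horizon}}
#' Reductions are negative by convention.
#'
#' @param inputs An \code{\link{offset_inputs}} set.
#' @return Percentage (negative = reduction).
#' @export
footprint_reduction <- function(inputs) {
  if (inputs$annual_footprint <= 0 || inputs$horizon <= 0)
    stop("division error: footprint and horizon must be positive", call. = FALSE)
  -100 * (inputs$per_ha_carbon * inputs$co2_per_c * inputs$area) /
    (inputs$annual_footprint * inputs$horizon)
}

#' One-page offset report
#'
#' @param inputs An \code{\link{offset_inputs}} set.
#' @return data.frame with total carbon (Mg C), total CO2-equivalent (Mg)
#'   and the footprint percentage.
#' @export
offset_report <- function(inputs) {
  tc <- total_storage(inputs$per_ha_carbon, inputs$area)
  data.frame(per_ha_carbon_Mg = inputs$per_ha_carbon,
             area_ha = inputs$area,
             total_carbon_Mg = tc,
             total_co2e_Mg = tc * inputs$co2_per_c,
             footprint_Mg_per_yr = inputs$annual_footprint,
             horizon_yr = inputs$horizon,
             footprint_reduction_pct = footprint_reduction(inputs))
}
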