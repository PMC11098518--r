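#' Plot predicted survival curves by treatment
#'
#' @param fixed A \code{\link{survival_fixed_effects}} set.
#' @param horizon Curve end in years.
#' @param treatments Treatment levels to draw.
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(fixed = survival_fixed_effects(),
                                 horizon = 10,
                                 treatments = names(fixed$contrasts)) {
  d <- do.call(rbind, lapply(treatments, function(tr) {
    cbind(treatment = tr, survival_curve(fixed, tr, horizon = horizon))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = age, y = survival, colour = treatment)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (years)", y = "Predicted survival probability",
                  colour = "Treatment") +
    ggplot2::theme_minimal()
}

#' Plot a stand carbon projection with its uncertainty band
#'
#' @param result A \code{"projection_result"} from
#'   \code{\link{project_stand}}.
#' @return A ggplot object with the replicate mean and a +/- SE ribbon.
#' @export
plot_projection <- function(result) {
  d <- as.data.frame(result)
  ggplot2::ggplot(d, ggplot2::aes(x = time, y = mean_carbon)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_carbon - se_carbon,
                                      ymax = mean_carbon + se_carbon),
                         fill = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (years)", y = "Stand carbon (Mg C/ha)") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("age", "survival", "treatment", "time",
                         "mean_carbon", "se_carbon"))
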