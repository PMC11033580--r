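# ggplot2 views of the package's result types.

#' Plot fluence depth profiles
#'
#' Depth profiles of the configured fluence models at one or more spatial
#' frequencies, optionally normalized to the total depth integral of each
#' profile so shapes are comparable across models and frequencies.
#'
#' @param props Single-medium optical-properties frame.
#' @param fx Spatial frequencies, mm^-1.
#' @param z Depth grid, mm.
#' @param models Model names, default all three.
#' @param normalize Normalize each profile to unit depth integral
#'   (default TRUE).
#' @return A ggplot object.
#' @export
plot_fluence_profiles <- function(props, fx = c(0, 0.2, 0.4),
                                  z = seq(0, 5, length.out = 300),
                                  models = fluence_models(),
                                  normalize = TRUE) {
  prof <- fluence_profile(props, fx, z = z, models = models)
  if (normalize) {
    prof <- dplyr::group_by(prof, .data$model, .data$fx)
    prof <- dplyr::mutate(
      prof, phi = .data$phi / base::sum(.data$phi * mean(diff(z))))
    prof <- dplyr::ungroup(prof)
  }
  ggplot2::ggplot(prof,
                  ggplot2::aes(.data$z, .data$phi,
                               colour = factor(.data$fx))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "depth z (mm)",
                  y = if (normalize) "normalized fluence" else
                    expression(phi / P[0]),
                  colour = expression(f[x] ~ (mm^-1))) +
    ggplot2::theme_minimal()
}

#' @describeIn model_curve Plot a two-layer model curve: modeled
#'   `mu_s_mod'(<fx>)` with the top- and bottom-layer scattering
#'   coefficients as horizontal reference lines.
#' @param object An `sfdi_model_curve`.
#' @param ... Unused.
#' @export
autoplot.sfdi_model_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fx_mean, .data$mu_s_mod)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$mu_s_top[1]),
                        colour = "orange") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$mu_s_bot[1]),
                        colour = "navy") +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("<" * f[x] * ">" ~ (mm^-1)),
                  y = expression(mu[s]^"'" ~ (mm^-1)),
                  title = paste0(object$phantom_label[1], " (",
                                 object$model[1], ", d = ", object$d[1],
                                 " mm)")) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_models Plot a comparison table as grouped RMSPE
#'   bars, one panel per contrast (wavelength), models side by side over
#'   thickness.
#' @param object An `sfdi_comparison`.
#' @param ... Unused.
#' @export
autoplot.sfdi_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$d), .data$rmspe,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~wavelength) +
    ggplot2::labs(x = "top-layer thickness d (mm)", y = "RMSPE (%)",
                  fill = "fluence model") +
    ggplot2::theme_minimal()
}

#' @describeIn process_stack Plot a measurement series: per-sub-set
#'   homogeneous-equivalent `mu_s'` against the sub-set mean frequency.
#' @param object An `sfdi_measurement_series`.
#' @param ... Unused.
#' @export
autoplot.sfdi_measurement_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fx_mean, .data$mu_s_prime)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression("<" * f[x] * ">" ~ (mm^-1)),
                  y = expression(mu[s]^"'" ~ (mm^-1))) +
    ggplot2::theme_minimal()
}
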