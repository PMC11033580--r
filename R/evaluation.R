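# Model-vs-measurement scoring: root mean square percentage error over the
# sub-set frequency means, and the comparison table across models,
# thicknesses and scattering contrasts.

#' Root mean square percentage error
#'
#' `RMSPE = sqrt( (1/N) sum_i ((meas_i - mod_i) / meas_i)^2 ) * 100`,
#' with the percent factor applied outside the square root. Scale-invariant
#' and permutation-invariant over aligned pairs.
#'
#' @param measured Measured values (non-zero), e.g. `mu_s_meas'(<fx>)`.
#' @param modeled Modeled values, aligned with `measured`.
#' @return RMSPE in percent (scalar, >= 0).
#' @examples
#' rmspe(c(2, 2), c(1, 1)) # 50
#' @export
rmspe <- function(measured, modeled) {
  if (length(measured) == 0 || length(measured) != length(modeled)) {
    stop_domain("`measured` and `modeled` must be non-empty, equal length")
  }
  if (any(!is.finite(measured)) || any(!is.finite(modeled))) {
    stop_domain("`measured` and `modeled` must be finite")
  }
  if (any(measured == 0)) {
    stop_domain("`measured` values must be non-zero for a percentage error")
  }
  sqrt(mean(((measured - modeled) / measured)^2)) * 100
}

#' Scattering contrast between two layers
#'
#' The ratio `mu_s_top' / mu_s_bot'` of the reduced scattering coefficients
#' of the top and bottom layers.
#'
#' @param top,bottom Single-medium optical-properties frames.
#' @return The contrast ratio, dimensionless.
#' @examples
#' scattering_contrast(optical_properties(0.0322, 3.4319),
#'                     optical_properties(0.0215, 0.8675))
#' @export
scattering_contrast <- function(top, bottom) {
  validate_optical_properties(top)
  validate_optical_properties(bottom)
  if (any(bottom$mu_s_prime == 0)) {
    stop_domain("bottom-layer `mu_s_prime` must be non-zero")
  }
  top$mu_s_prime / bottom$mu_s_prime
}

#' Compare fluence models against measured scattering curves
#'
#' Scores every fluence model against every measured `mu_s'(<fx>)` series:
#' for each (phantom, wavelength) series the two-layer model curve is
#' computed per model via [model_curve()] and reduced to one RMSPE record.
#'
#' @param measurements A data frame with one row per sub-set per series:
#'   columns `phantom_label`, `wavelength`, `fx_mean`, `mu_a`, `mu_s_prime`
#'   (the homogeneous-equivalent estimates measured on the layered target)
#'   and `mu_s_meas` (the measured scattering the models are scored
#'   against; defaults to `mu_s_prime` when absent).
#' @param phantoms A named list of [two_layer_phantom()] objects keyed
#'   `"<phantom_label>|<wavelength>"`, or a function
#'   `(phantom_label, wavelength) -> two_layer_phantom`.
#' @param models Character vector of model names, default all three.
#' @return A tibble of class `sfdi_comparison`, one row per model x phantom
#'   x wavelength: columns `model`, `phantom_label`, `wavelength`, `d`,
#'   `contrast`, `rmspe`, `n_points`.
#' @export
compare_models <- function(measurements, phantoms,
                           models = fluence_models()) {
  needed <- c("phantom_label", "wavelength", "fx_mean", "mu_a", "mu_s_prime")
  if (!is.data.frame(measurements) || !all(needed %in% names(measurements))) {
    stop_domain(paste0("`measurements` needs columns: ",
                       paste(needed, collapse = ", ")))
  }
  if (!"mu_s_meas" %in% names(measurements)) {
    measurements$mu_s_meas <- measurements$mu_s_prime
  }
  lookup <- if (is.function(phantoms)) {
    phantoms
  } else {
    function(phantom_label, wavelength) {
      key <- paste(phantom_label, wavelength, sep = "|")
      ph <- phantoms[[key]]
      if (is.null(ph)) {
        stop_domain(paste0("no phantom registered under key `", key, "`"))
      }
      ph
    }
  }
  series <- dplyr::group_split(
    dplyr::group_by(measurements, .data$phantom_label, .data$wavelength))
  out <- purrr::map(series, function(ser) {
    ser <- dplyr::arrange(ser, .data$fx_mean)
    ph <- lookup(ser$phantom_label[1], ser$wavelength[1])
    purrr::map(models, function(m) {
      curve <- model_curve(ser, ph, m)
      tibble(model = m,
             phantom_label = ser$phantom_label[1],
             wavelength = ser$wavelength[1],
             d = ph$d,
             contrast = scattering_contrast(ph$top, ph$bottom),
             rmspe = rmspe(ser$mu_s_meas, curve$mu_s_mod),
             n_points = nrow(ser))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(out))
  class(out) <- c("sfdi_comparison", class(out))
  out
}
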