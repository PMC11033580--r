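# The two-layer modeled scattering coefficient: mu_s_mod'(<fx>) as a linear
# combination of the top- and bottom-layer reduced scattering coefficients,
# weighted by the partial-volume fraction alpha computed from a homogeneous
# fluence model at the sub-set mean frequency.

#' Describe a two-layer phantom
#'
#' A thin top layer of thickness `d` over a semi-infinite bottom layer, with
#' matched refractive index between the layers (index mismatch would add
#' internal reflections the model does not account for).
#'
#' @param d Top-layer thickness, mm (> 0).
#' @param top,bottom Single-medium optical-properties frames for the two
#'   layers (see [optical_properties()]). Must share the same `n`.
#' @param label Free-text label for reporting.
#' @return A list of class `two_layer_phantom` with elements `d`, `top`,
#'   `bottom`, `label`.
#' @examples
#' two_layer_phantom(
#'   d = 0.269,
#'   top = optical_properties(0.0370, 2.9269),
#'   bottom = optical_properties(0.0226, 0.8322))
#' @export
two_layer_phantom <- function(d, top, bottom, label = "") {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0) {
    stop_domain("`d` must be a single positive thickness in mm")
  }
  validate_optical_properties(top)
  validate_optical_properties(bottom)
  if (nrow(top) != 1 || nrow(bottom) != 1) {
    stop_domain("`top` and `bottom` must each describe one medium")
  }
  if (!isTRUE(all.equal(top$n, bottom$n))) {
    stop_domain("the two layers must share the same refractive index `n`")
  }
  structure(list(d = d, top = top, bottom = bottom, label = label),
            class = "two_layer_phantom")
}

#' @export
print.two_layer_phantom <- function(x, ...) {
  cat("<two_layer_phantom> ", x$label, "\n", sep = "")
  cat("  d =", x$d, "mm\n")
  cat("  top:    mu_a =", x$top$mu_a, " mu_s' =", x$top$mu_s_prime, "mm^-1\n")
  cat("  bottom: mu_a =", x$bottom$mu_a, " mu_s' =", x$bottom$mu_s_prime,
      "mm^-1\n")
  invisible(x)
}

#' Two-layer modeled scattering at one sub-set frequency
#'
#' Evaluates the two-layer scattering model at one sub-set mean frequency:
#' the fluence is computed with the chosen model from the
#' homogeneous-equivalent properties measured (or simulated) on the layered
#' target for that sub-set -- not from the layer properties -- the
#' partial-volume weight `alpha` follows from integrating the fluence
#' squared over the top layer, and the modeled coefficient is the mixture
#' `mu_s_mod' = alpha mu_s_top' + (1 - alpha) mu_s_bot'`.
#'
#' @param phantom A [two_layer_phantom()] supplying `d` and the layer
#'   scattering coefficients.
#' @param homog_props Single-medium homogeneous-equivalent optical
#'   properties for this sub-set.
#' @param fx_mean Sub-set mean spatial frequency, mm^-1 (>= 0).
#' @param model One of [fluence_models()].
#' @return A one-row tibble with columns `fx_mean`, `alpha`, `mu_s_mod`,
#'   `model`.
#' @export
modeled_scattering <- function(phantom, homog_props, fx_mean,
                               model = c("sda", "delta_p1", "mod_delta_p1")) {
  model <- match_fluence_model(match.arg(model))
  s <- fluence(homog_props, fx_mean, model)
  a <- alpha_partial_volume(s, phantom$d)$alpha
  tibble(fx_mean = fx_mean, alpha = a,
         mu_s_mod = a * phantom$top$mu_s_prime +
           (1 - a) * phantom$bottom$mu_s_prime,
         model = model)
}

#' Two-layer model curve over a measurement series
#'
#' Applies [modeled_scattering()] across a per-sub-set measurement series:
#' for each sub-set the fluence uses that sub-set's homogeneous-equivalent
#' `(mu_a, mu_s_prime)` (with `g` and `n` taken from `g` / `n` arguments,
#' since neither is measurable by SFDI), producing the modeled
#' `mu_s_mod'(<fx>)` curve aligned 1:1 with the measurement entries.
#'
#' @param measurement A data frame with one row per sub-set, columns
#'   `fx_mean`, `mu_a`, `mu_s_prime` (the homogeneous-equivalent estimates).
#' @param phantom A [two_layer_phantom()].
#' @param model One of [fluence_models()].
#' @param g,n Anisotropy and refractive index assumed for the fluence
#'   calculation; defaults follow the phantom's top layer.
#' @return A tibble of class `sfdi_model_curve`, one row per sub-set:
#'   columns `fx_mean`, `alpha`, `mu_s_mod`, `model`, plus `mu_s_top`,
#'   `mu_s_bot`, `d`, `phantom_label` carried for plotting and export.
#' @examples
#' ph <- two_layer_phantom(0.269,
#'   top = optical_properties(0.0370, 2.9269),
#'   bottom = optical_properties(0.0226, 0.8322))
#' meas <- tibble::tibble(fx_mean = c(0.075, 0.425),
#'                        mu_a = 0.03, mu_s_prime = 1.5)
#' model_curve(meas, ph, "mod_delta_p1")
#' @export
model_curve <- function(measurement, phantom,
                        model = c("sda", "delta_p1", "mod_delta_p1"),
                        g = phantom$top$g, n = phantom$top$n) {
  model <- match_fluence_model(match.arg(model))
  if (!is.data.frame(measurement) || nrow(measurement) == 0) {
    stop_domain("`measurement` must be a non-empty data frame")
  }
  needed <- c("fx_mean", "mu_a", "mu_s_prime")
  if (!all(needed %in% names(measurement))) {
    stop_domain(paste0("`measurement` needs columns: ",
                       paste(needed, collapse = ", ")))
  }
  rows <- purrr::pmap(
    measurement[needed],
    function(fx_mean, mu_a, mu_s_prime) {
      hp <- optical_properties(mu_a, mu_s_prime, g = g, n = n)
      modeled_scattering(phantom, hp, fx_mean, model)
    })
  out <- dplyr::bind_rows(rows)
  out$mu_s_top <- phantom$top$mu_s_prime
  out$mu_s_bot <- phantom$bottom$mu_s_prime
  out$d <- phantom$d
  out$phantom_label <- phantom$label
  lo <- min(phantom$top$mu_s_prime, phantom$bottom$mu_s_prime)
  hi <- max(phantom$top$mu_s_prime, phantom$bottom$mu_s_prime)
  # mixture boundedness is structural; violation signals a broken alpha
  stopifnot(all(out$mu_s_mod >= lo - 1e-12), all(out$mu_s_mod <= hi + 1e-12))
  class(out) <- c("sfdi_model_curve", class(out))
  out
}
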