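# The layer-contribution weight alpha(d, fx): the fraction of the
# fluence-squared (photon-hitting-density) integral contained in the top
# layer of thickness d, computed analytically from the exponential-sum
# representation.

# integral_0^d phi^2 dz for phi(z) = sum_i a_i exp(-k_i z):
# phi^2 = sum_ij a_i a_j exp(-(k_i + k_j) z), each pair integrating to
# a_i a_j (1 - exp(-(k_i + k_j) d)) / (k_i + k_j). d = Inf gives the total.
phi_squared_integral <- function(sum, d) {
  a <- sum$amplitude
  k <- sum$rate
  aa <- outer(a, a)
  kk <- outer(k, k, `+`) # pair rates summed before exponentiation
  keep <- abs(aa) / kk >= 1e-300
  if (is.infinite(d)) {
    return(base::sum((aa / kk)[keep]))
  }
  base::sum((aa * (1 - exp(-kk * d)) / kk)[keep])
}

#' Partial-volume weight of a thin top layer
#'
#' Computes `alpha(d, fx)`, the fraction of the depth-integrated photon
#' hitting density (fluence squared, for a co-located planar source and
#' wide-field detector) contained within the top layer:
#' `alpha = integral_0^d phi^2 dz / integral_0^inf phi^2 dz`,
#' evaluated in closed form from the exponential-sum representation. This is
#' the mixing weight of the two-layer scattering model. `alpha` is invariant
#' under uniform rescaling of the amplitudes, is 0 at `d = 0`, tends to 1 as
#' `d` grows, and is non-decreasing in `fx` on the certified parameter grid
#' (higher frequencies have a lower penetration depth).
#'
#' @param sum An [exp_sum()] fluence profile (all rates > 0).
#' @param d Top-layer thickness, mm (>= 0), vectorized.
#' @return A tibble with one row per `d`: columns `alpha`, `d`, `fx`,
#'   `model`, `numerator`, `denominator`.
#' @examples
#' optical_properties(0.05, 5) |>
#'   mod_delta_p1_fluence(fx = 0.2) |>
#'   alpha_partial_volume(d = c(0.13, 0.5))
#' @export
alpha_partial_volume <- function(sum, d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_domain("`d` must be finite and >= 0")
  }
  denominator <- phi_squared_integral(sum, Inf)
  if (denominator <= 0) {
    stop_invalid_fluence(
      paste0("total fluence-squared integral is not positive; the ",
             "exponential sum does not describe a physical fluence"))
  }
  numerator <- vapply(d, function(di) phi_squared_integral(sum, di),
                      numeric(1))
  tibble(alpha = pmin(1, pmax(0, numerator / denominator)),
         d = d,
         fx = attr(sum, "fx") %||% NA_real_,
         model = attr(sum, "model") %||% NA_character_,
         numerator = numerator,
         denominator = denominator)
}

#' Quadrature oracle for the partial-volume weight
#'
#' Independent check of [alpha_partial_volume()]: adaptive numerical
#' quadrature of `phi^2` on `[0, d]` and `[0, z_max]` for an arbitrary
#' fluence function of depth. The infinite upper limit is truncated at
#' `z_max` (default `40 / k_min` when the smallest decay rate `k_min` is
#' supplied; the neglected tail is below 1e-12 of the total for
#' exponential-sum profiles).
#'
#' @param phi A function of depth `z` (mm) returning fluence values.
#' @param d Top-layer thickness, mm (>= 0).
#' @param z_max Truncation depth standing in for infinity, mm.
#' @return The fraction `integral_0^d phi^2 / integral_0^z_max phi^2`.
#' @export
alpha_quadrature_oracle <- function(phi, d, z_max = 40) {
  if (!is.finite(d) || d < 0) stop_domain("`d` must be finite and >= 0")
  phi2 <- function(z) phi(z)^2
  quad <- function(lo, hi) {
    res <- tryCatch(
      integrate(phi2, lo, hi, rel.tol = 1e-10, abs.tol = 0,
                subdivisions = 500L),
      error = function(e) stop_numerical(paste0(
        "quadrature of phi^2 on [", lo, ", ", hi, "] failed: ",
        conditionMessage(e))))
    res$value
  }
  d_eff <- min(d, z_max)
  total <- quad(0, d_eff) + if (z_max > d_eff) quad(d_eff, z_max) else 0
  if (total <= 0) stop_invalid_fluence("total fluence-squared integral is not positive")
  quad(0, d_eff) / total
}

#' Tabulate the partial-volume weight over a parameter grid
#'
#' Crosses models, frequencies and thicknesses for one medium and returns a
#' tidy table of `alpha(d, fx)` (columns `model`, `mu_a`, `mu_s_prime`, `g`,
#' `n`, `fx`, `d`, `alpha`), ready for CSV export or plotting.
#'
#' @param props Single-medium optical-properties frame.
#' @param fx Spatial frequencies, mm^-1.
#' @param d Thicknesses, mm.
#' @param models Model names, default all three.
#' @return A tibble, one row per model x fx x d combination.
#' @export
alpha_table <- function(props, fx, d, models = fluence_models()) {
  grid <- tidyr::expand_grid(model = models, fx = fx)
  out <- purrr::pmap(grid, function(model, fx) {
    s <- fluence(props, fx, model)
    a <- alpha_partial_volume(s, d)
    tibble(model = model,
           mu_a = props$mu_a, mu_s_prime = props$mu_s_prime,
           g = props$g, n = props$n,
           fx = fx, d = d, alpha = a$alpha)
  })
  dplyr::bind_rows(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
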