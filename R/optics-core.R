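# Domain types and derived radiative-transport coefficients shared by every
# fluence model. All coefficients are in mm^-1, frequencies in mm^-1, depths
# in mm, everywhere, no exceptions.

#' Optical properties of a turbid medium
#'
#' Builds a one-row-per-medium tibble holding the absorption coefficient
#' `mu_a`, the reduced scattering coefficient `mu_s_prime`, the scattering
#' anisotropy `g` and the refractive index `n` at one wavelength band.
#' All downstream functions (fluence models, forward reflectance, the
#' two-layer model) consume this tibble, so several media can be described
#' in one frame and processed row-wise.
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param mu_s_prime Reduced scattering coefficient, mm^-1 (> 0).
#' @param g Scattering anisotropy, mean cosine of the single-scattering
#'   deflection angle, in `[0, 1)`. Default 0.8, a common soft-tissue value.
#' @param n Refractive index (>= 1). Default 1.4, a common soft-tissue value.
#' @param label Optional wavelength-band or medium label, recycled.
#' @return A tibble with columns `mu_a`, `mu_s_prime`, `g`, `n` (and `label`
#'   when supplied), one row per medium.
#' @examples
#' optical_properties(mu_a = 0.05, mu_s_prime = 5)
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.8, n = 1.4,
                               label = NULL) {
  props <- tibble(mu_a = as.numeric(mu_a),
                  mu_s_prime = as.numeric(mu_s_prime),
                  g = as.numeric(g), n = as.numeric(n))
  if (!is.null(label)) props$label <- label
  validate_optical_properties(props)
  props
}

#' Validate an optical-properties frame
#'
#' Checks the physical invariants of [optical_properties()] columns and
#' raises a domain error naming the offending field. Used internally by
#' every operation that consumes optical properties.
#'
#' @param props A data frame with columns `mu_a`, `mu_s_prime`, `g`, `n`.
#' @return `props`, invisibly, when valid.
#' @export
validate_optical_properties <- function(props) {
  required <- c("mu_a", "mu_s_prime", "g", "n")
  missing <- setdiff(required, names(props))
  if (length(missing) > 0) {
    stop_domain(paste0("optical properties are missing field(s): ",
                       paste(missing, collapse = ", ")))
  }
  for (f in required) {
    if (any(!is.finite(props[[f]]))) {
      stop_domain(paste0("optical property `", f, "` must be finite"))
    }
  }
  if (any(props$mu_a < 0)) stop_domain("`mu_a` must be >= 0")
  if (any(props$mu_s_prime <= 0)) stop_domain("`mu_s_prime` must be > 0")
  if (any(props$g < 0 | props$g >= 1)) stop_domain("`g` must be in [0, 1)")
  if (any(props$n < 1)) stop_domain("`n` must be >= 1")
  invisible(props)
}

#' Effective reflection coefficient from the refractive index
#'
#' Rational polynomial approximation of the effective reflection coefficient
#' of a refractive-index-mismatched boundary,
#' `Reff = 0.0636 n + 0.668 + 0.710 / n - 1.440 / n^2`,
#' the standard fit used with diffusion-theory boundary conditions. At
#' `n = 1` the fit evaluates to 0.0016 (its documented matched-boundary
#' value, not exactly zero). Kept behind this one function so an alternate
#' approximation can be swapped in.
#'
#' @param n Refractive index (>= 1), vectorized.
#' @return Effective reflection coefficient, dimensionless.
#' @export
reff_approx <- function(n) {
  if (any(!is.finite(n)) || any(n < 1)) stop_domain("`n` must be >= 1")
  0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
}

# Unpolarized Fresnel reflectance for light travelling inside a medium of
# index n and hitting the boundary to index 1 at internal angle acos(mu).
# Total internal reflection beyond the critical angle.
fresnel_unpolarized_internal <- function(mu, n) {
  sin_i <- sqrt(pmax(0, 1 - mu^2))
  sin_t <- n * sin_i
  r <- rep(1, length(mu)) # total internal reflection
  ok <- sin_t < 1
  if (any(ok)) {
    cos_t <- sqrt(1 - sin_t[ok]^2)
    cos_i <- mu[ok]
    rs <- (n * cos_i - cos_t) / (n * cos_i + cos_t)
    rp <- (n * cos_t - cos_i) / (n * cos_t + cos_i)
    r[ok] <- 0.5 * (rs^2 + rp^2)
  }
  r
}

#' First moment of the Fresnel reflection coefficient
#'
#' Computes `R1 = 2 * integral_0^1 mu * RF(mu) dmu`, the first angular moment
#' of the unpolarized Fresnel reflection coefficient for internal incidence
#' (total internal reflection included), by adaptive quadrature of the
#' defining integral. This is the moment entering the delta-P1 boundary
#' constant `R' = (1 + R1) / (1 - R1)`. Evaluated from the definition rather
#' than a polynomial fit so it is exact at every `n`; `R1(1) = 0` identically
#' (matched boundary). Behind this one function so a fitted approximation can
#' be swapped in.
#'
#' @param n Refractive index (>= 1), vectorized.
#' @return First Fresnel moment, dimensionless in `[0, 1)`.
#' @export
fresnel_moment_r1 <- function(n) {
  if (any(!is.finite(n)) || any(n < 1)) stop_domain("`n` must be >= 1")
  vapply(n, function(ni) {
    if (ni == 1) return(0)
    # split at the critical cosine where RF hits 1, for quadrature accuracy
    mu_c <- sqrt(1 - 1 / ni^2)
    f <- function(mu) 2 * mu * fresnel_unpolarized_internal(mu, ni)
    i1 <- integrate(f, 0, mu_c, rel.tol = 1e-12, abs.tol = 1e-14)
    i2 <- integrate(f, mu_c, 1, rel.tol = 1e-12, abs.tol = 1e-14)
    i1$value + i2$value
  }, numeric(1))
}

#' Derive radiative-transport coefficients
#'
#' Appends to an optical-properties frame the derived coefficients used by
#' all fluence models: the transport coefficient `mu_tr = mu_a + mu_s_prime`,
#' the effective attenuation `mu_eff = sqrt(3 mu_a mu_tr)`, the delta-P1
#' reduced scattering `mu_s_star = mu_s (1 - g^2)` (with
#' `mu_s = mu_s_prime / (1 - g)`), the delta-P1 transport
#' `mu_tr_star = mu_a + mu_s_star`, the delta-P1 anisotropy
#' `g_star = g / (g + 1)`, and the boundary-condition constants: `R_eff`
#' (via [reff_approx()]), `R1` (via [fresnel_moment_r1()]),
#' `R_sda = (1 - R_eff) / (2 (1 + R_eff))` and
#' `R_prime = (1 + R1) / (1 - R1)`.
#'
#' @param props Optical-properties frame, see [optical_properties()].
#' @return The input tibble with the derived coefficient columns appended.
#' @examples
#' optical_properties(0.05, 5) |> derive_transport_coefficients()
#' @export
derive_transport_coefficients <- function(props) {
  validate_optical_properties(props)
  out <- as_tibble(props)
  mu_s <- out$mu_s_prime / (1 - out$g)
  out$mu_tr <- out$mu_a + out$mu_s_prime
  out$mu_eff <- sqrt(3 * out$mu_a * out$mu_tr)
  out$mu_s_star <- mu_s * (1 - out$g^2)
  out$mu_tr_star <- out$mu_a + out$mu_s_star
  out$g_star <- out$g / (out$g + 1)
  out$R_eff <- reff_approx(out$n)
  out$R1 <- fresnel_moment_r1(out$n)
  out$R_sda <- (1 - out$R_eff) / (2 * (1 + out$R_eff))
  out$R_prime <- (1 + out$R1) / (1 - out$R1)
  out
}

#' Frequency-modified effective attenuation coefficient
#'
#' The attenuation rate governing decay of the AC fluence with depth,
#' `mu_eff'(fx) = sqrt(mu_eff^2 + (2 pi fx)^2)`. The projected patterns are
#' one-dimensional sinusoids, so the wavenumber is `kx = 2 pi fx`, `ky = 0`.
#' Strictly increasing in `fx`; equals `mu_eff` at `fx = 0`.
#'
#' @param mu_eff Effective attenuation coefficient, mm^-1.
#' @param fx Spatial frequency, mm^-1 (>= 0), vectorized.
#' @return Attenuation rate, mm^-1.
#' @export
mu_eff_prime <- function(mu_eff, fx) {
  if (any(!is.finite(fx)) || any(fx < 0)) {
    stop_domain("`fx` must be finite and >= 0")
  }
  sqrt(mu_eff^2 + (2 * pi * fx)^2)
}

# Single-row convenience: derived coefficients as a plain named list, used
# internally by the fluence models (avoids repeated tibble overhead).
derived_row <- function(props) {
  if (nrow(props) != 1) {
    stop_domain("expected exactly one medium (one row of optical properties)")
  }
  as.list(derive_transport_coefficients(props))
}
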