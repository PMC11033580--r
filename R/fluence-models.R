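# Closed-form depth-fluence models in the spatial frequency domain. Every
# model returns the same representation -- a finite sum of decaying
# exponentials phi(z) = sum_i a_i exp(-k_i z) -- so the partial-volume
# weight can integrate phi^2 analytically.

# Relative tolerance under which (mu_eff' - rate) is treated as a singular
# configuration (degenerate denominator in the particular solution).
SINGULAR_EPS <- 1e-9

#' Available fluence models
#'
#' @return Character vector of the three model names: `"sda"` (standard
#'   diffusion approximation), `"delta_p1"` (original delta-P1) and
#'   `"mod_delta_p1"` (modified delta-P1).
#' @export
fluence_models <- function() c("sda", "delta_p1", "mod_delta_p1")

match_fluence_model <- function(model) {
  if (!is.character(model) || length(model) != 1 ||
      !model %in% fluence_models()) {
    stop_domain(paste0("`model` must be one of: ",
                       paste(fluence_models(), collapse = ", ")))
  }
  model
}

#' Construct an exponential-sum fluence profile
#'
#' A fluence depth-profile represented as `phi(z) = sum_i a_i exp(-k_i z)`
#' for `z >= 0`: a tibble with one term per row (columns `amplitude`,
#' dimensionless per unit incident power, and `rate`, mm^-1) carrying the
#' generating model and spatial frequency as attributes.
#'
#' @param amplitude Term amplitudes (dimensionless).
#' @param rate Term decay rates, mm^-1, all > 0.
#' @param model Optional model name attribute.
#' @param fx Optional spatial frequency attribute, mm^-1.
#' @return A tibble of class `exp_sum` with columns `amplitude` and `rate`.
#' @examples
#' exp_sum(amplitude = c(1, -0.5), rate = c(1, 2))
#' @export
exp_sum <- function(amplitude, rate, model = NA_character_, fx = NA_real_) {
  if (length(amplitude) == 0 || length(amplitude) != length(rate)) {
    stop_domain("`amplitude` and `rate` must be non-empty and equal length")
  }
  if (any(!is.finite(amplitude)) || any(!is.finite(rate)) || any(rate <= 0)) {
    stop_domain("all rates must be finite and > 0, amplitudes finite")
  }
  out <- tibble(amplitude = as.numeric(amplitude), rate = as.numeric(rate))
  class(out) <- c("exp_sum", class(out))
  attr(out, "model") <- model
  attr(out, "fx") <- fx
  out
}

#' Evaluate an exponential-sum fluence profile at depth
#'
#' @param sum An [exp_sum()] profile.
#' @param z Depths, mm (>= 0), vectorized.
#' @return Fluence values `sum_i a_i exp(-k_i z)`, per unit incident power.
#' @examples
#' evaluate_fluence(exp_sum(1, 1), z = log(2))
#' @export
evaluate_fluence <- function(sum, z) {
  if (any(!is.finite(z)) || any(z < 0)) {
    stop_domain("`z` must be finite and >= 0")
  }
  drop(exp(-outer(z, sum$rate)) %*% sum$amplitude)
}

check_not_singular <- function(rate_num, rate_den, what) {
  if (abs(rate_num - rate_den) <= SINGULAR_EPS * abs(rate_den)) {
    stop_singular(paste0(
      "singular configuration in ", what, ": mu_eff'(fx) coincides with ",
      "the source decay rate (", format(rate_den), " mm^-1); perturb fx ",
      "slightly (e.g. by 1e-6 mm^-1) to move off the degenerate point"))
  }
}

#' Standard diffusion approximation fluence
#'
#' Depth-resolved fluence (normalized to incident power) of a sinusoidally
#' modulated planar source under the standard diffusion approximation:
#' `phi(z)/P0 = A exp(-mu_tr z) + C exp(-mu_eff'(fx) z)` with
#' `A = (3 mu_s'/mu_tr) / ((mu_eff'/mu_tr)^2 - 1)`,
#' `C = -A (1 + 3R) / (mu_eff'/mu_tr + 3R)` and the partial-current boundary
#' constant `R = (1 - Reff) / (2 (1 + Reff))`.
#'
#' @param props Single-medium optical-properties frame.
#' @param fx Spatial frequency, mm^-1 (>= 0).
#' @return An [exp_sum()] with two terms, rates `mu_tr` and `mu_eff'(fx)`.
#' @examples
#' optical_properties(0.05, 5) |> sda_fluence(fx = 0.1)
#' @export
sda_fluence <- function(props, fx) {
  d <- derived_row(props)
  mep <- mu_eff_prime(d$mu_eff, fx)
  check_not_singular(mep, d$mu_tr, "sda_fluence")
  A <- (3 * d$mu_s_prime / d$mu_tr) / ((mep / d$mu_tr)^2 - 1)
  C <- -A * (1 + 3 * d$R_sda) / (mep / d$mu_tr + 3 * d$R_sda)
  exp_sum(amplitude = c(A, C), rate = c(d$mu_tr, mep),
          model = "sda", fx = fx)
}

#' Original delta-P1 fluence
#'
#' Depth-resolved AC fluence (normalized to incident power) of the original
#' delta-P1 model with spatial-frequency dependence:
#' `phi(z)/P0 = C*/(mu_eff' - mu_tr*) [exp(-mu_tr* z) - exp(-mu_eff' z)]
#'  + C*/(mu_eff' + mu_tr*) [exp(-mu_tr* z) - exp(-mu_eff' (z + 2 zb))]`
#' with `C* = 3 mu_tr mu_s* / (2 mu_eff')` and the extrapolated boundary
#' `zb = (2 / (3 mu_tr)) R'`, `R' = (1 + R1)/(1 - R1)`. The four brackets
#' are collected into two terms: amplitude
#' `C*/(mu_eff'-mu_tr*) + C*/(mu_eff'+mu_tr*)` at rate `mu_tr*` and
#' `-C*/(mu_eff'-mu_tr*) - C* exp(-2 mu_eff' zb)/(mu_eff'+mu_tr*)` at rate
#' `mu_eff'`. No separate collimated term is added: the model is used
#' exactly in its published AC form.
#'
#' @inheritParams sda_fluence
#' @return An [exp_sum()] with two terms, rates `mu_tr*` and `mu_eff'(fx)`.
#' @export
delta_p1_fluence <- function(props, fx) {
  d <- derived_row(props)
  mep <- mu_eff_prime(d$mu_eff, fx)
  check_not_singular(mep, d$mu_tr_star, "delta_p1_fluence")
  c_star <- 3 * d$mu_tr * d$mu_s_star / (2 * mep)
  zb <- (2 / (3 * d$mu_tr)) * d$R_prime
  a_fast <- c_star / (mep - d$mu_tr_star) + c_star / (mep + d$mu_tr_star)
  a_slow <- -c_star / (mep - d$mu_tr_star) -
    c_star * exp(-2 * mep * zb) / (mep + d$mu_tr_star)
  exp_sum(amplitude = c(a_fast, a_slow), rate = c(d$mu_tr_star, mep),
          model = "delta_p1", fx = fx)
}

#' Modified delta-P1 fluence
#'
#' Depth-resolved fluence (normalized to incident power) of the modified
#' delta-P1 model: the delta-P1 governing equation driven by a sinusoidally
#' modulated source with a diffuse-flux boundary condition, plus the
#' collimated component `exp(-mu_tr* z)`:
#' `phi(z)/P0 = (1 + A') exp(-mu_tr* z) + C' exp(-mu_eff' z)` with
#' `A' = 3 mu_s* (mu_tr* + g* mu_a) / (mu_eff'^2 - mu_tr*^2)` and `C'`
#' fixed by the boundary condition
#' `[phi_d - (2/(3 mu_tr)) R' dphi_d/dz]_(z=0) = -(2/mu_tr) R' g* mu_s*`:
#' `C' = -(A' (1 + (2 R' mu_tr*)/(3 mu_tr)) + (2/mu_tr) R' g* mu_s*) /
#'        (1 + (2 R' mu_eff')/(3 mu_tr))`.
#' Normalization is per delivered (post-specular) power.
#'
#' @inheritParams sda_fluence
#' @return An [exp_sum()] with two terms, rates `mu_tr*` and `mu_eff'(fx)`.
#' @export
mod_delta_p1_fluence <- function(props, fx) {
  d <- derived_row(props)
  mep <- mu_eff_prime(d$mu_eff, fx)
  check_not_singular(mep, d$mu_tr_star, "mod_delta_p1_fluence")
  a_prime <- 3 * d$mu_s_star * (d$mu_tr_star + d$g_star * d$mu_a) /
    (mep^2 - d$mu_tr_star^2)
  b <- (2 / (3 * d$mu_tr)) * d$R_prime
  c_prime <- -(a_prime * (1 + b * d$mu_tr_star) +
                 (2 / d$mu_tr) * d$R_prime * d$g_star * d$mu_s_star) /
    (1 + b * mep)
  exp_sum(amplitude = c(1 + a_prime, c_prime), rate = c(d$mu_tr_star, mep),
          model = "mod_delta_p1", fx = fx)
}

#' Compute a fluence profile by model name
#'
#' Dispatches to [sda_fluence()], [delta_p1_fluence()] or
#' [mod_delta_p1_fluence()].
#'
#' @inheritParams sda_fluence
#' @param model One of [fluence_models()].
#' @return An [exp_sum()].
#' @export
fluence <- function(props, fx, model = c("sda", "delta_p1", "mod_delta_p1")) {
  model <- match_fluence_model(match.arg(model))
  switch(model,
         sda = sda_fluence(props, fx),
         delta_p1 = delta_p1_fluence(props, fx),
         mod_delta_p1 = mod_delta_p1_fluence(props, fx))
}

#' Tabulate fluence depth profiles
#'
#' Evaluates one or more fluence models over a depth grid and returns a tidy
#' table ready for plotting or CSV export (columns `z`, `phi`, `model`,
#' `fx`). Raises a warning if any profile goes negative on the grid (the
#' models are only certified positive on the physiological parameter grid).
#'
#' @param props Single-medium optical-properties frame.
#' @param fx Spatial frequencies, mm^-1 (vectorized).
#' @param z Depth grid, mm; default 400 points over 0--10 mm.
#' @param models Character vector of model names, default all three.
#' @return A tibble with columns `model`, `fx`, `z`, `phi`.
#' @examples
#' optical_properties(0.05, 5) |> fluence_profile(fx = c(0, 0.2))
#' @export
fluence_profile <- function(props, fx, z = seq(0, 10, length.out = 400),
                            models = fluence_models()) {
  grid <- tidyr::expand_grid(model = models, fx = fx)
  out <- purrr::pmap(grid, function(model, fx) {
    s <- fluence(props, fx, model)
    phi <- evaluate_fluence(s, z)
    if (any(phi < 0)) {
      warn(paste0("fluence profile for model `", model, "` at fx = ", fx,
                  " mm^-1 is negative at some depths; parameters are ",
                  "outside the certified grid"))
    }
    tibble(model = model, fx = fx, z = z, phi = phi)
  })
  dplyr::bind_rows(out)
}

#' Depth containing half of the photon-hitting-density mass
#'
#' The depth at which the cumulative integral of fluence squared reaches
#' 50% of its total -- a scalar summary of how superficially a model
#' concentrates its sensitivity. Decreases as the spatial frequency grows.
#'
#' @param sum An [exp_sum()] fluence profile.
#' @return Depth, mm.
#' @export
half_mass_depth <- function(sum) {
  total <- phi_squared_integral(sum, Inf)
  if (total <= 0) stop_invalid_fluence("fluence-squared integral is not positive")
  f <- function(z) phi_squared_integral(sum, z) / total - 0.5
  upper <- 1 / min(sum$rate)
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = 1e-12)$root
}
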