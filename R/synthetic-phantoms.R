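# Synthetic fixtures emulating the layered-phantom suite and the three-phase
# SFDI acquisition, so every pipeline stage runs and is testable with no
# instrument data.

# Default layer optical properties per wavelength band: a TiO2-like thin-top
# batch over an Al2O3-like bottom batch, measured on thick homogeneous
# phantoms (absorption from India ink in both).
phantom_suite_defaults <- function() {
  tibble(
    wavelength = c("458", "536", "626"),
    mu_a_top = c(0.0322, 0.0370, 0.0427),
    mu_s_top = c(3.4319, 2.9269, 2.3436),
    mu_a_bot = c(0.0215, 0.0226, 0.0242),
    mu_s_bot = c(0.8675, 0.8322, 0.7830)
  )
}

#' Build the layered-phantom suite
#'
#' The default suite: five thin TiO2-like top layers with thicknesses
#' `d = 0.130, 0.269, 0.490, 0.675, 1.149` mm over a semi-infinite
#' Al2O3-like bottom layer, characterized at three wavelength bands
#' (458, 536, 626 nm). Anisotropy and refractive index are configuration
#' defaults (`g = 0.8`, `n = 1.4`), not measured values.
#'
#' @param thicknesses Top-layer thicknesses, mm; default the five above.
#' @param optical Optional replacement for the per-band layer properties:
#'   a data frame with columns `wavelength`, `mu_a_top`, `mu_s_top`,
#'   `mu_a_bot`, `mu_s_bot`.
#' @param g,n Anisotropy and refractive index shared by both layers.
#' @return A list of class `phantom_suite`: `phantoms` (a tibble, one row
#'   per thickness x band, with a list-column `phantom` of
#'   [two_layer_phantom()] objects), `optical`, `thicknesses`,
#'   `wavelengths`, `g`, `n`.
#' @examples
#' suite <- make_phantom_suite()
#' suite$phantoms
#' @export
make_phantom_suite <- function(thicknesses = c(0.130, 0.269, 0.490, 0.675,
                                               1.149),
                               optical = NULL, g = 0.8, n = 1.4) {
  if (any(!is.finite(thicknesses)) || any(thicknesses <= 0) ||
      is.unsorted(thicknesses, strictly = TRUE)) {
    stop_domain("`thicknesses` must be positive and strictly increasing")
  }
  optical <- if (is.null(optical)) phantom_suite_defaults() else
    as_tibble(optical)
  needed <- c("wavelength", "mu_a_top", "mu_s_top", "mu_a_bot", "mu_s_bot")
  if (!all(needed %in% names(optical))) {
    stop_domain(paste0("`optical` needs columns: ",
                       paste(needed, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    phantom_label = paste0("phantom", seq_along(thicknesses)),
    wavelength = optical$wavelength)
  grid$d <- rep(thicknesses, each = nrow(optical))
  grid <- dplyr::left_join(grid, optical, by = "wavelength")
  grid$phantom <- purrr::pmap(grid, function(phantom_label, wavelength, d,
                                             mu_a_top, mu_s_top, mu_a_bot,
                                             mu_s_bot) {
    two_layer_phantom(
      d = d,
      top = optical_properties(mu_a_top, mu_s_top, g = g, n = n),
      bottom = optical_properties(mu_a_bot, mu_s_bot, g = g, n = n),
      label = paste0(phantom_label, "@", wavelength, "nm"))
  })
  structure(list(phantoms = grid, optical = optical,
                 thicknesses = thicknesses,
                 wavelengths = optical$wavelength, g = g, n = n),
            class = "phantom_suite")
}

#' @export
print.phantom_suite <- function(x, ...) {
  cat("<phantom_suite>", length(x$thicknesses), "thicknesses x",
      length(x$wavelengths), "wavelength bands\n")
  cat("  d =", paste(x$thicknesses, collapse = ", "), "mm\n")
  print(x$optical)
  invisible(x)
}

#' Look up one phantom from a suite
#'
#' @param suite A [make_phantom_suite()] result.
#' @param phantom_label Label such as `"phantom2"`.
#' @param wavelength Band label such as `"536"`.
#' @return A [two_layer_phantom()].
#' @export
suite_phantom <- function(suite, phantom_label, wavelength) {
  hit <- suite$phantoms$phantom_label == phantom_label &
    suite$phantoms$wavelength == wavelength
  if (base::sum(hit) != 1) {
    stop_domain(paste0("no phantom `", phantom_label, "` at band `",
                       wavelength, "` in the suite"))
  }
  suite$phantoms$phantom[[which(hit)]]
}

#' Noise specification for synthetic acquisitions
#'
#' @param multiplicative_sigma Relative (multiplicative Gaussian) noise
#'   fraction; default 0 (noise-free).
#' @param additive_sigma Additive Gaussian noise, intensity units.
#' @param seed Integer seed recorded in every output generated under this
#'   spec.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(multiplicative_sigma = 0, additive_sigma = 0,
                       seed = 1L) {
  if (multiplicative_sigma < 0 || additive_sigma < 0) {
    stop_domain("noise sigmas must be >= 0")
  }
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 additive_sigma = additive_sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# Fixed point of the generator closure at one mean frequency: the
# homogeneous-equivalent pair (mu_a, mu_s') that, fed through the chosen
# fluence model and the two-layer mixture, reproduces itself.
fixed_point_homog <- function(phantom, fx_mean, model,
                              homog_props_rule = NULL, tol = 1e-8,
                              max_iter = 100) {
  g <- phantom$top$g
  n <- phantom$top$n
  if (!is.null(homog_props_rule)) {
    pair <- homog_props_rule(fx_mean)
    hp <- optical_properties(pair[1], pair[2], g = g, n = n)
    ms <- modeled_scattering(phantom, hp, fx_mean, model)
    return(tibble(fx_mean = fx_mean, mu_a = pair[1], mu_s_prime = pair[2],
                  alpha = ms$alpha, mu_s_mod = ms$mu_s_mod))
  }
  mu_a <- (phantom$top$mu_a + phantom$bottom$mu_a) / 2
  mu_s <- (phantom$top$mu_s_prime + phantom$bottom$mu_s_prime) / 2
  for (it in seq_len(max_iter)) {
    hp <- optical_properties(mu_a, mu_s, g = g, n = n)
    ms <- modeled_scattering(phantom, hp, fx_mean, model)
    a <- ms$alpha
    mu_a_new <- a * phantom$top$mu_a + (1 - a) * phantom$bottom$mu_a
    mu_s_new <- ms$mu_s_mod
    moved <- max(abs(mu_a_new - mu_a), abs(mu_s_new - mu_s))
    mu_a <- mu_a_new
    mu_s <- mu_s_new
    if (moved < tol) {
      return(tibble(fx_mean = fx_mean, mu_a = mu_a, mu_s_prime = mu_s,
                    alpha = a, mu_s_mod = mu_s_new))
    }
  }
  abort(paste0("fixed-point generator did not converge at <fx> = ", fx_mean,
               " mm^-1 after ", max_iter, " iterations"),
        class = "sfdilayers_generator_error")
}

#' Simulate a per-sub-set measurement series for a layered phantom
#'
#' Self-consistent generator of the homogeneous-equivalent measurement
#' series a multi-frequency acquisition would produce on a two-layer
#' phantom. For each sub-set mean frequency the default rule closes the
#' two-layer model on itself by fixed-point iteration: starting from the
#' mean layer properties, the fluence is computed from the current
#' homogeneous-equivalent pair, `alpha` follows, and the pair is updated to
#' `mu_s' = alpha mu_s_top' + (1 - alpha) mu_s_bot'` and
#' `mu_a = alpha mu_a_top + (1 - alpha) mu_a_bot` until both move by less
#' than `tol`. The fixed point makes the series exactly reproducible by
#' [model_curve()] under the same fluence model. The rule is a synthetic
#' closure, not a physical layered-transport solution; a user-supplied
#' `homog_props_rule(fx_mean) -> c(mu_a, mu_s_prime)` (e.g. backed by
#' layered Monte Carlo output) can replace it.
#'
#' @param phantom A [two_layer_phantom()].
#' @param frequencies Acquisition frequency grid, mm^-1; default
#'   [default_frequency_grid()].
#' @param model Fluence model used by the generator.
#' @param window,stride Sub-set window size and stride.
#' @param homog_props_rule Optional function `fx_mean -> c(mu_a,
#'   mu_s_prime)` overriding the fixed-point rule.
#' @param tol,max_iter Fixed-point tolerance (on both coefficients, mm^-1)
#'   and iteration cap.
#' @return A tibble of class `sfdi_measurement_series`: columns `subset`,
#'   `fx_mean`, `mu_a`, `mu_s_prime`, plus the generating `alpha` and
#'   `mu_s_mod` (at the fixed point `mu_s_mod == mu_s_prime`).
#' @export
simulate_measurement_series <- function(phantom,
                                        frequencies =
                                          default_frequency_grid(),
                                        model = c("sda", "delta_p1",
                                                  "mod_delta_p1"),
                                        window = 4, stride = 1,
                                        homog_props_rule = NULL,
                                        tol = 1e-8, max_iter = 100) {
  model <- match_fluence_model(match.arg(model))
  subsets <- split_subsets(frequencies, window = window, stride = stride)
  rows <- purrr::map(subsets$fx_mean, function(fxm) {
    fixed_point_homog(phantom, fxm, model, homog_props_rule = homog_props_rule,
                      tol = tol, max_iter = max_iter)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, subset = dplyr::row_number(), .before = 1)
  attr(out, "model") <- model
  attr(out, "phantom_label") <- phantom$label
  class(out) <- c("sfdi_measurement_series", class(out))
  out
}

#' Synthesize a raw three-phase pattern stack
#'
#' Emulates one multi-frequency SFDI acquisition of a target with known
#' per-frequency diffuse reflectance: for each nonzero frequency, three
#' images at phase offsets 0, 120, 240 degrees with
#' `I_k(x) = S/2 * Rd * (1 + cos(2 pi fx x + phi_k))` (modulation along
#' image columns, `x = (col - 1) * pitch` mm); planar (`fx = 0`) frames are
#' emitted unmodulated as `I = S * Rd`. Noise is applied per the
#' [noise_spec()] under its recorded seed (multiplicative then additive
#' Gaussian). The source intensity `S` is in normalized units so that
#' noise-free intensities stay in `[0, 1]` for TIFF storage.
#'
#' @param rd Diffuse reflectance per frequency: a numeric vector aligned
#'   with `frequencies`, or a list of matrices (per-pixel maps).
#' @param frequencies Strictly increasing spatial frequencies, mm^-1.
#' @param noise A [noise_spec()].
#' @param shape Image shape `c(rows, cols)`, default `c(64, 64)`.
#' @param pitch Pixel pitch, mm, default 0.4 (so a 64-pixel row spans 25.6
#'   mm, one full period of the lowest nonzero default frequency, while the
#'   highest default frequency stays below the Nyquist limit `1/(2 pitch)`).
#' @param source Source intensity `S` in normalized units, default 1.
#' @return A list of class `sfdi_stack`: `images` (list over frequency of
#'   `[rows, cols, 3]` arrays), `frequencies`, `phases_deg`, `pitch`,
#'   `source`, `truth` (the generating `rd`, `frequencies` and seed),
#'   `noise`.
#' @export
synthesize_pattern_stack <- function(rd, frequencies =
                                       default_frequency_grid(),
                                     noise = noise_spec(),
                                     shape = c(64, 64), pitch = 0.4,
                                     source = 1) {
  validate_frequency_grid(frequencies)
  if (is.numeric(rd)) rd <- as.list(rd)
  if (length(rd) != length(frequencies)) {
    stop_domain("need one `rd` value or map per frequency")
  }
  nonzero <- frequencies[frequencies > 0]
  if (length(nonzero) > 0) {
    min_period_px <- 1 / (min(nonzero) * pitch)
    if (shape[2] < min_period_px) {
      stop_domain(paste0("image too small: ", shape[2], " columns cover ",
                         "less than one period of fx = ", min(nonzero),
                         " mm^-1 at pitch ", pitch, " mm"))
    }
  }
  phases <- c(0, 120, 240) * pi / 180
  x_mm <- (seq_len(shape[2]) - 1) * pitch
  set.seed(noise$seed)
  images <- purrr::map(seq_along(frequencies), function(i) {
    fx <- frequencies[i]
    rd_i <- rd[[i]]
    rd_img <- if (is.matrix(rd_i)) rd_i else
      matrix(rd_i, nrow = shape[1], ncol = shape[2])
    arr <- array(0, dim = c(shape[1], shape[2], 3))
    for (k in 1:3) {
      if (fx == 0) {
        frame <- source * rd_img
      } else {
        pattern <- 1 + cos(2 * pi * fx * x_mm + phases[k])
        frame <- 0.5 * source * rd_img *
          matrix(pattern, nrow = shape[1], ncol = shape[2], byrow = TRUE)
      }
      if (noise$multiplicative_sigma > 0) {
        frame <- frame * (1 + rnorm(length(frame),
                                    sd = noise$multiplicative_sigma))
      }
      if (noise$additive_sigma > 0) {
        frame <- frame + rnorm(length(frame), sd = noise$additive_sigma)
      }
      arr[, , k] <- frame
    }
    arr
  })
  structure(list(images = images, frequencies = frequencies,
                 phases_deg = c(0, 120, 240), pitch = pitch,
                 source = source,
                 truth = list(rd = rd, frequencies = frequencies,
                              seed = noise$seed),
                 noise = noise),
            class = "sfdi_stack")
}

check_stack <- function(stack) {
  if (!inherits(stack, "sfdi_stack") ||
      length(stack$images) != length(stack$frequencies)) {
    stop_domain("expected an `sfdi_stack` (see synthesize_pattern_stack(), ",
                "read_stack())")
  }
  invisible(stack)
}

#' @export
print.sfdi_stack <- function(x, ...) {
  dims <- dim(x$images[[1]])
  cat("<sfdi_stack>", length(x$frequencies), "frequencies x 3 phases,",
      dims[1], "x", dims[2], "px @", x$pitch, "mm\n")
  cat("  fx:", paste(x$frequencies, collapse = ", "), "mm^-1\n")
  invisible(x)
}
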