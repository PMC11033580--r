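# Orchestration: a validated run configuration and the end-to-end workflow
# (read stacks -> demodulate -> calibrate -> split -> invert -> two-layer
# model curves -> comparison table), with every artifact written as CSV
# carrying a provenance line.

#' Build and validate a run configuration
#'
#' Collects every knob of the processing workflow, validates it against the
#' module preconditions before any computation, and makes it serializable;
#' [run_pipeline()] echoes the configuration into its output directory.
#'
#' @param frequencies Acquisition frequency grid, mm^-1.
#' @param window,stride Sub-set window size and stride.
#' @param models Fluence models to evaluate.
#' @param g,n Anisotropy and refractive index assumed where not measurable.
#' @param roi_fraction Central region-of-interest area fraction.
#' @param noise [noise_spec()] used by `simulate` runs.
#' @param out_dir Output directory.
#' @param verbose Log progress to stderr.
#' @return A list of class `sfdi_run_config`.
#' @export
run_config <- function(frequencies = default_frequency_grid(), window = 4,
                       stride = 1, models = fluence_models(), g = 0.8,
                       n = 1.4, roi_fraction = 0.25, noise = noise_spec(),
                       out_dir = "sfdi-results", verbose = TRUE) {
  validate_frequency_grid(frequencies)
  if (window < 2 || length(frequencies) < window) {
    stop_domain("`window` must be >= 2 and <= the grid length")
  }
  for (m in models) match_fluence_model(m)
  if (g < 0 || g >= 1) stop_domain("`g` must be in [0, 1)")
  if (n < 1) stop_domain("`n` must be >= 1")
  if (roi_fraction <= 0 || roi_fraction > 1) {
    stop_domain("`roi_fraction` must be in (0, 1]")
  }
  if (!inherits(noise, "noise_spec")) stop_domain("`noise` must be a noise_spec()")
  structure(list(frequencies = frequencies, window = as.integer(window),
                 stride = as.integer(stride), models = models, g = g, n = n,
                 roi_fraction = roi_fraction, noise = unclass(noise),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "sfdi_run_config")
}

config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

# Dependency-free stable content hash (31-bit polynomial) for provenance.
# Only the scientific configuration is hashed: where results are written
# (and how chatty the run is) does not change what is computed.
config_hash <- function(config) {
  sci <- unclass(config)
  sci$out_dir <- NULL
  sci$verbose <- NULL
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(sci, auto_unbox = TRUE,
                                                   digits = NA)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pipeline_log <- function(config, ...) {
  if (config$verbose) message("[sfdilayers] ", ...)
}

#' Run the depth-resolved processing workflow end to end
#'
#' Executes the full multi-frequency workflow on one sample/reference pair:
#' per-sub-set homogeneous-equivalent properties via [process_stack()], a
#' two-layer model curve per configured fluence model via [model_curve()]
#' (when a phantom description is supplied), and the RMSPE comparison table
#' via [compare_models()]. Writes `subset_properties.csv`,
#' `model_curve_<model>.csv`, `comparison.csv`, the echoed `config.json`
#' and a `run.log` (package version, config hash, seed) into
#' `config$out_dir`. Deterministic given config + inputs.
#'
#' @param config An [run_config()].
#' @param sample,reference `sfdi_stack` objects or on-disk stack paths
#'   readable by [read_stack()].
#' @param ref_props Reference-phantom optical properties (frame or path to
#'   JSON/CSV readable by [read_optical_properties()]).
#' @param phantom Optional [two_layer_phantom()] enabling the model-curve
#'   and comparison stages.
#' @param rd_model Forward reflectance model, default [forward_rd()].
#' @return Invisibly, a list with `measurement` (the per-sub-set series),
#'   `curves` (named list of model curves) and `comparison` (or `NULL`).
#' @export
run_pipeline <- function(config, sample, reference, ref_props,
                         phantom = NULL, rd_model = forward_rd) {
  stopifnot(inherits(config, "sfdi_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  if (is.character(sample)) sample <- read_stack(sample)
  if (is.character(reference)) reference <- read_stack(reference)
  if (is.character(ref_props)) ref_props <- read_optical_properties(ref_props)
  if (!isTRUE(all.equal(sample$frequencies, config$frequencies))) {
    stop_domain("sample stack frequencies do not match the configuration")
  }
  pipeline_log(config, "processing stack (", length(config$frequencies),
               " frequencies, window ", config$window, ")")
  measurement <- process_stack(sample, reference, ref_props,
                               window = config$window,
                               stride = config$stride,
                               g = config$g, n = config$n,
                               roi_fraction = config$roi_fraction,
                               rd_model = rd_model)
  write_result_csv(measurement, file.path(config$out_dir,
                                          "subset_properties.csv"),
                   run_id = hash)
  curves <- NULL
  comparison <- NULL
  if (!is.null(phantom)) {
    curves <- purrr::map(setNames(config$models, config$models),
                         function(m) {
      pipeline_log(config, "model curve: ", m)
      curve <- model_curve(measurement, phantom, m,
                           g = config$g, n = config$n)
      write_result_csv(curve, file.path(config$out_dir,
                                        paste0("model_curve_", m, ".csv")),
                       run_id = hash)
      curve
    })
    meas <- dplyr::mutate(measurement,
                          phantom_label = phantom$label, wavelength = "",
                          mu_s_meas = .data$mu_s_prime)
    comparison <- compare_models(meas, function(...) phantom,
                                 models = config$models)
    write_result_csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     run_id = hash)
  }
  writeLines(c(paste0("sfdilayers ",
                      as.character(utils::packageVersion("sfdilayers"))),
               paste0("config_hash ", hash),
               paste0("seed ", config$noise$seed),
               paste0("config ", config_json(config))),
             file.path(config$out_dir, "run.log"))
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(config, "done: ", config$out_dir)
  invisible(list(measurement = measurement, curves = curves,
                 comparison = comparison))
}

#' Simulate a layered acquisition to disk
#'
#' Generates the synthetic counterpart of one acquisition session: a
#' reference stack of a known homogeneous phantom and a sample stack whose
#' per-frequency diffuse reflectance follows the homogeneous-equivalent
#' series of the supplied layered phantom (per-sub-set series interpolated
#' to the full grid through the generating model's fixed point at each
#' frequency). Both stacks and their ground truth are written in the format
#' [read_stack()] consumes.
#'
#' @param config An [run_config()].
#' @param phantom A [two_layer_phantom()].
#' @param ref_props Reference-phantom optical properties.
#' @param model Generating fluence model.
#' @param shape Image shape in pixels.
#' @return Invisibly, a list with the written `sample` and `reference`
#'   stack path prefixes and the generating series.
#' @export
simulate_acquisition <- function(config, phantom, ref_props,
                                 model = "mod_delta_p1", shape = c(64, 64)) {
  stopifnot(inherits(config, "sfdi_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  freqs <- config$frequencies
  model <- match_fluence_model(model)
  # homogeneous-equivalent pair at each acquisition frequency: the same
  # fixed-point closure the measurement-series generator uses per sub-set
  per_freq <- purrr::map(freqs, function(f) {
    fixed_point_homog(phantom, f, model)
  })
  rd <- vapply(seq_along(freqs), function(i) {
    row <- per_freq[[i]]
    props <- optical_properties(row$mu_a, row$mu_s_prime,
                                g = config$g, n = config$n)
    forward_rd(props, freqs[i])
  }, numeric(1))
  noise <- noise_spec(config$noise$multiplicative_sigma,
                      config$noise$additive_sigma, config$noise$seed)
  sample <- synthesize_pattern_stack(rd, freqs, noise = noise, shape = shape)
  rd_ref <- forward_rd(ref_props, freqs)
  ref_noise <- noise_spec(config$noise$multiplicative_sigma,
                          config$noise$additive_sigma,
                          config$noise$seed + 1L)
  reference <- synthesize_pattern_stack(rd_ref, freqs, noise = ref_noise,
                                        shape = shape)
  sample_path <- file.path(config$out_dir, "sample")
  ref_path <- file.path(config$out_dir, "reference")
  write_stack(sample, sample_path)
  write_stack(reference, ref_path)
  write_optical_properties(ref_props,
                           file.path(config$out_dir, "reference_props.json"))
  series <- dplyr::bind_rows(per_freq)
  series$fx <- freqs
  write_result_csv(series, file.path(config$out_dir, "ground_truth.csv"),
                   run_id = config_hash(config))
  invisible(list(sample = sample_path, reference = ref_path,
                 series = series))
}
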