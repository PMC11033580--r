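# Readers and writers for the on-disk acquisition format: a multi-page TIFF
# (page order frequency-major, phase-minor) plus a JSON sidecar naming the
# frequencies, phase offsets and band, and flat JSON/CSV serialization of
# optical properties.

#' Write an acquisition stack to disk
#'
#' Writes the stack as a 32-bit-float multi-page TIFF (`stack.tif`, page
#' order frequency-major then phase) plus a JSON sidecar (`stack.json`) with
#' keys `frequencies_mm^-1`, `phases_deg`, `pixel_pitch_mm`, `source`,
#' `wavelength_nm` and, when present, the generator ground truth (including
#' its seed). Intensities are clipped to `[0, 1]` for storage; the number of
#' clipped samples is reported in a warning.
#'
#' @param stack An `sfdi_stack`.
#' @param path Output path prefix or directory; `"<path>.tif"` and
#'   `"<path>.json"` are written (a directory gets `stack.tif/.json`).
#' @param wavelength_nm Optional band label stored in the sidecar.
#' @return The TIFF path, invisibly.
#' @export
write_stack <- function(stack, path, wavelength_nm = NA) {
  check_stack(stack)
  if (dir.exists(path)) path <- file.path(path, "stack")
  tif <- paste0(path, ".tif")
  sidecar <- paste0(path, ".json")
  pages <- list()
  n_clip <- 0L
  for (i in seq_along(stack$images)) {
    for (k in 1:3) {
      img <- stack$images[[i]][, , k]
      n_clip <- n_clip + base::sum(img < 0 | img > 1)
      pages[[length(pages) + 1L]] <- pmin(pmax(img, 0), 1)
    }
  }
  if (n_clip > 0) {
    warn(paste0(n_clip, " intensity sample(s) outside [0, 1] were clipped ",
                "for TIFF storage"))
  }
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  meta <- list(`frequencies_mm^-1` = stack$frequencies,
               phases_deg = stack$phases_deg,
               pixel_pitch_mm = stack$pitch,
               source = stack$source,
               wavelength_nm = wavelength_nm)
  if (!is.null(stack$truth)) {
    meta$truth <- list(rd = unlist(lapply(stack$truth$rd, function(r) {
      if (is.matrix(r)) mean(r) else r
    })), seed = stack$truth$seed)
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(tif)
}

#' Read an acquisition stack from disk
#'
#' Reads a multi-page TIFF plus JSON sidecar written by [write_stack()] (or
#' by an instrument exporter following the same convention: page order
#' frequency-major, phase-minor; sidecar keys `frequencies_mm^-1`,
#' `phases_deg`, `pixel_pitch_mm`).
#'
#' @param path Path prefix (without extension), the `.tif` path, or a
#'   directory containing `stack.tif` / `stack.json`.
#' @return An `sfdi_stack`.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "stack")
  path <- sub("\\.(tif|tiff|json)$", "", path)
  tif <- paste0(path, ".tif")
  sidecar <- paste0(path, ".json")
  if (!file.exists(tif)) stop_format(paste0("missing TIFF stack: ", tif))
  if (!file.exists(sidecar)) {
    stop_format(paste0("missing JSON sidecar: ", sidecar, " (expected keys: ",
                       "frequencies_mm^-1, phases_deg, pixel_pitch_mm)"))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  needed <- c("frequencies_mm^-1", "phases_deg", "pixel_pitch_mm")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    stop_format(paste0("sidecar ", sidecar, " is missing key(s): ",
                       paste(missing, collapse = ", ")))
  }
  freqs <- as.numeric(meta[["frequencies_mm^-1"]])
  phases <- as.numeric(meta[["phases_deg"]])
  if (length(phases) != 3 || !isTRUE(all.equal(phases, c(0, 120, 240)))) {
    stop_format("sidecar phases_deg must be [0, 120, 240]")
  }
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != 3 * length(freqs)) {
    stop_format(paste0("TIFF has ", length(pages), " pages; expected ",
                       3 * length(freqs),
                       " (frequency-major, 3 phases each)"))
  }
  images <- purrr::map(seq_along(freqs), function(i) {
    arr <- array(0, dim = c(dim(pages[[1]]), 3))
    for (k in 1:3) arr[, , k] <- pages[[(i - 1) * 3 + k]]
    arr
  })
  structure(list(images = images, frequencies = freqs,
                 phases_deg = c(0, 120, 240),
                 pitch = as.numeric(meta$pixel_pitch_mm),
                 source = meta$source %||% NA_real_,
                 truth = meta$truth, noise = NULL),
            class = "sfdi_stack")
}

#' Serialize optical properties
#'
#' Writes an optical-properties frame as flat JSON (single medium: one
#' object with keys `mu_a`, `mu_s_prime`, `g`, `n`; several media: an array
#' of such objects) or as CSV rows keyed by a `label` column.
#'
#' @param props Optical-properties frame.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_optical_properties <- function(props, path) {
  validate_optical_properties(props)
  if (grepl("\\.json$", path)) {
    x <- if (nrow(props) == 1) as.list(props) else props
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    readr::write_csv(as_tibble(props), path)
  }
  invisible(path)
}

#' Read optical properties
#'
#' Reads the flat JSON or CSV written by [write_optical_properties()].
#'
#' @param path `.json` or `.csv` file path.
#' @return An optical-properties tibble.
#' @export
read_optical_properties <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  props <- if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    as_tibble(as.list(x)[intersect(c("mu_a", "mu_s_prime", "g", "n", "label"),
                                   names(x))])
  } else {
    readr::read_csv(path, show_col_types = FALSE, comment = "#")
  }
  if (!"g" %in% names(props)) props$g <- 0.8
  if (!"n" %in% names(props)) props$n <- 1.4
  validate_optical_properties(props)
  as_tibble(props)
}

#' Write a result table as CSV with a provenance header
#'
#' All pipeline CSV outputs carry a commented provenance line (tool version
#' and run identifier) above the header row.
#'
#' @param x A data frame.
#' @param path Output CSV path.
#' @param run_id Free-text run identifier (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, run_id = "") {
  version <- as.character(utils::packageVersion("sfdilayers"))
  header <- paste0("# sfdilayers ", version,
                   if (nzchar(run_id)) paste0(" run=", run_id) else "")
  writeLines(header, path)
  # drop list-columns, which have no CSV representation
  x <- x[!vapply(x, is.list, logical(1))]
  readr::write_csv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
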