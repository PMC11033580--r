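test_that("the default phantom suite reproduces the characterization tables", {
  suite <- make_phantom_suite()
  expect_equal(suite$thicknesses, c(0.130, 0.269, 0.490, 0.675, 1.149))
  expect_equal(suite$wavelengths, c("458", "536", "626"))
  expect_equal(nrow(suite$phantoms), 15)
  ph <- suite_phantom(suite, "phantom2", "536")
  expect_equal(ph$d, 0.269)
  expect_equal(ph$top$mu_a, 0.0370)
  expect_equal(ph$top$mu_s_prime, 2.9269)
  expect_equal(ph$bottom$mu_a, 0.0226)
  expect_equal(ph$bottom$mu_s_prime, 0.8322)
  expect_equal(scattering_contrast(ph$top, ph$bottom), 3.5170,
               tolerance = 1e-4)
  expect_error(suite_phantom(suite, "phantom9", "536"),
               class = "sfdilayers_domain_error")
})

test_that("suite overrides are reflected without disturbing the defaults", {
  suite <- make_phantom_suite(thicknesses = c(0.2, 0.5))
  expect_equal(nrow(suite$phantoms), 6)
  expect_equal(suite_phantom(suite, "phantom1", "458")$d, 0.2)
  # optical defaults untouched by a thickness override
  expect_equal(suite_phantom(suite, "phantom1", "458")$top$mu_s_prime,
               3.4319)
  expect_error(make_phantom_suite(thicknesses = c(0.5, 0.2)),
               class = "sfdilayers_domain_error")
})

test_that("simulated series respect the two-layer mixture bounds", {
  ph <- table2_suite_phantom()
  for (m in fluence_models()) {
    series <- simulate_measurement_series(ph, model = m)
    expect_equal(nrow(series), 8)
    expect_true(all(series$mu_s_prime >= ph$bottom$mu_s_prime))
    expect_true(all(series$mu_s_prime <= ph$top$mu_s_prime))
    # at the fixed point the series equals its own model curve
    expect_equal(series$mu_s_prime, series$mu_s_mod, tolerance = 1e-7)
  }
  # zero contrast collapses to the common coefficient
  flat <- two_layer_phantom(0.4, optical_properties(0.03, 1.2),
                            optical_properties(0.03, 1.2))
  series <- simulate_measurement_series(flat, model = "sda")
  expect_equal(series$mu_s_prime, rep(1.2, 8), tolerance = 1e-8)
})

test_that("a user-supplied homogeneous rule bypasses the fixed point", {
  ph <- table2_suite_phantom()
  series <- simulate_measurement_series(
    ph, model = "sda",
    homog_props_rule = function(fxm) c(0.03, 1.5))
  expect_true(all(series$mu_a == 0.03))
  expect_true(all(series$mu_s_prime == 1.5))
})

test_that("synthetic stacks close the demodulate-calibrate loop exactly", {
  props <- optical_properties(0.0370, 2.9269)
  ref_props <- optical_properties(0.0226, 0.8322)
  freqs <- default_frequency_grid()
  rd_true <- forward_rd(props, freqs)
  stacks <- homog_stack_pair(props, ref_props)
  for (i in seq_along(freqs)) {
    demod <- if (freqs[i] == 0) demodulate_dc else demodulate_ac
    rd <- calibrate_rd(demod(stacks$sample$images[[i]]),
                       demod(stacks$reference$images[[i]]),
                       ref_props, freqs[i])
    expect_equal(roi_mean(rd), rd_true[i], tolerance = 1e-6)
  }
})

test_that("calibration cancels the source intensity", {
  props <- optical_properties(0.03, 1.5)
  ref_props <- optical_properties(0.0226, 0.8322)
  freqs <- c(0, 0.1, 0.2)
  rd_true <- forward_rd(props, freqs)
  for (source in c(0.5, 1)) {
    s <- synthesize_pattern_stack(rd_true, freqs, shape = c(24, 24), pitch = 1,
                                  source = source)
    r <- synthesize_pattern_stack(forward_rd(ref_props, freqs), freqs, pitch = 1,
                                  shape = c(24, 24), source = source)
    rd <- calibrate_rd(demodulate_ac(s$images[[2]]),
                       demodulate_ac(r$images[[2]]), ref_props, 0.1)
    expect_equal(roi_mean(rd), rd_true[2], tolerance = 1e-8)
  }
})

test_that("planar frames follow the DC convention", {
  s <- synthesize_pattern_stack(c(0.6, 0.5), c(0, 0.1), shape = c(16, 16),
                                pitch = 1, source = 0.8)
  # fx = 0: three identical unmodulated frames at source * Rd
  expect_equal(s$images[[1]][, , 1], s$images[[1]][, , 2])
  expect_equal(demodulate_dc(s$images[[1]]),
               matrix(0.8 * 0.6, 16, 16))
  # and no AC content
  expect_equal(max(demodulate_ac(s$images[[1]])), 0)
})

test_that("stacks too small for one pattern period are rejected", {
  expect_error(synthesize_pattern_stack(c(0.5, 0.5), c(0, 0.05),
                                        shape = c(8, 8)),
               class = "sfdilayers_domain_error")
})

test_that("noisy synthesis is reproducible from its recorded seed", {
  freqs <- c(0, 0.1, 0.3)
  mk <- function() synthesize_pattern_stack(
    c(0.6, 0.5, 0.4), freqs, noise = noise_spec(0.01, 1e-4, seed = 99),
    shape = c(16, 16), pitch = 1)
  s1 <- mk()
  s2 <- mk()
  expect_identical(s1$images, s2$images)
  expect_equal(s1$truth$seed, 99)
  s3 <- synthesize_pattern_stack(c(0.6, 0.5, 0.4), freqs,
                                 noise = noise_spec(0.01, 1e-4, seed = 100),
                                 shape = c(16, 16), pitch = 1)
  expect_false(identical(s1$images, s3$images))
})

test_that("stacks survive a disk round trip with sidecar metadata", {
  dir <- withr::local_tempdir()
  s <- synthesize_pattern_stack(c(0.6, 0.5, 0.4), c(0, 0.1, 0.3),
                                shape = c(16, 16), pitch = 1)
  write_stack(s, file.path(dir, "acq"))
  back <- read_stack(file.path(dir, "acq"))
  expect_equal(back$frequencies, s$frequencies)
  expect_equal(back$pitch, s$pitch)
  for (i in 1:3) {
    expect_equal(back$images[[i]], s$images[[i]], tolerance = 1e-6)
  }
  # a missing sidecar is a format error naming the expected keys
  file.remove(file.path(dir, "acq.json"))
  expect_error(read_stack(file.path(dir, "acq")), "frequencies_mm",
               class = "sfdilayers_format_error")
})

test_that("optical properties round-trip through JSON and CSV", {
  dir <- withr::local_tempdir()
  props <- optical_properties(0.0226, 0.8322, g = 0.8, n = 1.4)
  for (ext in c("json", "csv")) {
    path <- file.path(dir, paste0("ref.", ext))
    write_optical_properties(props, path)
    back <- read_optical_properties(path)
    expect_equal(back$mu_a, props$mu_a)
    expect_equal(back$mu_s_prime, props$mu_s_prime)
    expect_equal(back$g, props$g)
    expect_equal(back$n, props$n)
  }
})
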