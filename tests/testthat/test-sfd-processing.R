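test_that("sub-set windows tile the frequency grid", {
  grid <- default_frequency_grid()
  expect_length(grid, 11)
  subsets <- split_subsets(grid, window = 4)
  expect_equal(nrow(subsets), 8)
  expect_equal(subsets$fx_mean[1], mean(c(0, 0.05, 0.10, 0.15)))
  expect_equal(subsets$fx_mean[1], 0.075)
  # window count formula over assorted grids and windows
  for (len in c(5, 8, 11, 16)) {
    g <- seq(0, 0.5, length.out = len)
    for (w in c(2, 4, len)) {
      s <- split_subsets(g, window = w)
      expect_equal(nrow(s), len - w + 1)
      expect_true(all(vapply(s$indices, function(i) {
        all(diff(i) == 1)
      }, logical(1))))
    }
  }
  # degenerate window covering the whole grid
  s1 <- split_subsets(grid, window = 11)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$fx_mean, mean(grid))
  expect_error(split_subsets(grid[1:3], window = 4),
               class = "sfdilayers_domain_error")
  expect_error(split_subsets(c(0.1, 0.1, 0.2), window = 2),
               class = "sfdilayers_domain_error")
})

synth_phases <- function(A, O, fx, shape = c(20, 30), pitch = 0.1) {
  x <- (seq_len(shape[2]) - 1) * pitch
  lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(p) {
    matrix(O + A * cos(2 * pi * fx * x + p), nrow = shape[1],
           ncol = shape[2], byrow = TRUE)
  })
}

test_that("three-phase demodulation recovers the pattern amplitude exactly", {
  imgs <- synth_phases(A = 0.3, O = 0.5, fx = 0.2)
  ac <- demodulate_ac(imgs)
  expect_equal(max(abs(ac - 0.3)), 0, tolerance = 1e-10)
  # invariant to the DC offset
  imgs2 <- synth_phases(A = 0.3, O = 5, fx = 0.2)
  expect_equal(demodulate_ac(imgs2), ac, tolerance = 1e-10)
  # no modulation -> zero amplitude
  const <- replicate(3, matrix(0.7, 10, 10), simplify = FALSE)
  expect_equal(demodulate_ac(const), matrix(0, 10, 10))
  expect_equal(demodulate_dc(const), matrix(0.7, 10, 10))
  expect_error(demodulate_ac(const[1:2]),
               class = "sfdilayers_domain_error")
  expect_error(demodulate_ac(list(matrix(1, 2, 2), matrix(1, 2, 2),
                                  matrix(1, 3, 3))),
               class = "sfdilayers_domain_error")
})

test_that("demodulation is unbiased under additive Gaussian noise", {
  set.seed(42)
  n <- 1e4
  A <- 0.4
  O <- 0.5
  theta <- runif(n, 0, 2 * pi)
  sigma <- 0.01 * A
  imgs <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(p) {
    matrix(O + A * cos(theta + p) + rnorm(n, sd = sigma), nrow = 100)
  })
  mac <- demodulate_ac(imgs)
  se <- sd(mac) / sqrt(n)
  expect_lt(abs(mean(mac) - A), 3 * se)
})

test_that("calibration transfers the reference reflectance", {
  ref_props <- optical_properties(0.0226, 0.8322)
  ref_img <- matrix(0.4, 16, 16)
  rd_ref <- forward_rd(ref_props, 0.1)
  # sample == reference -> model Rd of the reference everywhere
  rd <- calibrate_rd(ref_img, ref_img, ref_props, 0.1)
  expect_equal(rd, matrix(rd_ref, 16, 16), ignore_attr = TRUE)
  # linear in the amplitude ratio, clipped into [0, 1] with a warning
  expect_warning(
    rd2 <- calibrate_rd(ref_img * 2 / rd_ref, ref_img, ref_props, 0.1),
    "clipped")
  expect_true(all(rd2 == 1))
  expect_equal(attr(rd2, "clipped"), 256)
  expect_error(calibrate_rd(matrix(1, 2, 2), matrix(1, 3, 3), ref_props, 0),
               class = "sfdilayers_domain_error")
  expect_error(calibrate_rd(ref_img, ref_img * 0, ref_props, 0.1),
               class = "sfdilayers_calibration_error")
})

test_that("forward reflectance behaves like diffuse reflectance", {
  props <- ref_props_visible()
  expect_lt(forward_rd(props, 0.5), forward_rd(props, 0))
  fx <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(forward_rd(props, fx)) < 0))
  expect_true(all(forward_rd(props, fx) > 0 & forward_rd(props, fx) < 1))
  # brighter with more scattering
  expect_gt(forward_rd(optical_properties(0.05, 6), 0.1),
            forward_rd(optical_properties(0.05, 5), 0.1))
  # dual transcription: same closed form written in unreduced coefficients
  rd_alt <- function(props, fx) {
    mu_tr <- props$mu_a + props$mu_s_prime
    mu_eff <- sqrt(3 * props$mu_a * mu_tr)
    mep <- sqrt(mu_eff^2 + (2 * pi * fx)^2)
    reff <- 0.0636 * props$n + 0.668 + 0.710 / props$n - 1.440 / props$n^2
    A <- (1 - reff) / (2 * (1 + reff))
    3 * A * props$mu_s_prime * mu_tr / ((mep + mu_tr) * (mep + 3 * A * mu_tr))
  }
  for (f in fx) {
    expect_equal(forward_rd(props, f), rd_alt(props, f), tolerance = 1e-12)
  }
})

test_that("inversion recovers generating properties from noise-free reflectance", {
  props <- optical_properties(0.0226, 0.8322)
  window <- c(0, 0.05, 0.10, 0.15)
  d <- tibble::tibble(fx = window, rd = forward_rd(props, window))
  fit <- invert_homogeneous(d)
  expect_equal(fit$mu_a, 0.0226, tolerance = 1e-6)
  expect_equal(fit$mu_s_prime, 0.8322, tolerance = 1e-6)
  expect_false(fit$boundary_pinned)
  # order invariance
  fit2 <- invert_homogeneous(d[c(3, 1, 4, 2), ])
  expect_equal(fit2$mu_a, fit$mu_a, tolerance = 1e-10)
  expect_equal(fit2$mu_s_prime, fit$mu_s_prime, tolerance = 1e-10)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$term, c("mu_a", "mu_s_prime"))
  expect_equal(td$estimate[2], fit$mu_s_prime)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_freq, 4)
  expect_error(invert_homogeneous(d[1, ]),
               class = "sfdilayers_domain_error")
  expect_error(invert_homogeneous(tibble::tibble(fx = c(0, 0.1),
                                                 rd = c(0.5, 1.2))),
               class = "sfdilayers_domain_error")
})

test_that("inversion stays accurate under 1% multiplicative noise", {
  set.seed(7)
  props <- optical_properties(0.0226, 0.8322)
  window <- c(0, 0.05, 0.10, 0.15)
  rd_true <- forward_rd(props, window)
  rel_err <- replicate(100, {
    rd_noisy <- pmin(0.999, pmax(1e-6, rd_true * (1 + rnorm(4, sd = 0.01))))
    fit <- invert_homogeneous(tibble::tibble(fx = window, rd = rd_noisy))
    abs(fit$mu_s_prime - 0.8322) / 0.8322
  })
  expect_lt(median(rel_err), 0.02)
})

test_that("penetration depth follows the inverse attenuation convention", {
  props <- ref_props_visible()
  d <- derive_transport_coefficients(props)
  expect_equal(penetration_depth(props, 0), 1 / d$mu_eff, tolerance = 1e-14)
  expect_equal(penetration_depth(props, 0.425),
               1 / sqrt(0.7575 + (2 * pi * 0.425)^2), tolerance = 1e-12)
  expect_equal(penetration_depth(props, 0.425), 0.356, tolerance = 1e-3)
  expect_lt(penetration_depth(props, 0.5), penetration_depth(props, 0.05))
})

test_that("the ROI average reads the image centre", {
  img <- matrix(0, 40, 40)
  img[11:30, 11:30] <- 2 # exactly the central 25% area
  expect_equal(roi_mean(img, 0.25), 2)
  expect_equal(roi_mean(img, 1), mean(img))
  expect_error(roi_mean(img, 0), class = "sfdilayers_domain_error")
})

test_that("a homogeneous acquisition is recovered through the full chain", {
  props <- optical_properties(0.0370, 2.9269)
  ref_props <- optical_properties(0.0226, 0.8322)
  stacks <- homog_stack_pair(props, ref_props)
  series <- process_stack(stacks$sample, stacks$reference, ref_props)
  expect_s3_class(series, "sfdi_measurement_series")
  expect_equal(nrow(series), 8)
  expect_true(all(abs(series$mu_a - 0.0370) / 0.0370 < 0.01))
  expect_true(all(abs(series$mu_s_prime - 2.9269) / 2.9269 < 0.01))
  expect_true(all(diff(series$penetration_depth) < 0))
  # the calibrated per-frequency reflectance matches the forward model
  rd_tab <- attr(series, "rd_table")
  expect_equal(rd_tab$rd, forward_rd(props, rd_tab$fx), tolerance = 1e-6)
})

test_that("a tabulated reflectance model can replace the closed form", {
  props <- optical_properties(0.03, 2)
  grid <- expand.grid(mu_a = seq(0.02, 0.04, by = 0.005),
                      mu_s_prime = seq(1, 3, by = 0.25))
  tab <- do.call(rbind, lapply(c(0, 0.1), function(f) {
    data.frame(mu_a = grid$mu_a, mu_s_prime = grid$mu_s_prime, fx = f,
               rd = mapply(function(a, s) {
                 forward_rd(optical_properties(a, s), f)
               }, grid$mu_a, grid$mu_s_prime))
  }))
  lut <- rd_lookup_model(tab)
  # exact at nodes, interpolated between
  expect_equal(lut(props, c(0, 0.1)), forward_rd(props, c(0, 0.1)),
               tolerance = 1e-12)
  mid <- optical_properties(0.027, 1.6)
  expect_equal(lut(mid, 0.1), forward_rd(mid, 0.1), tolerance = 5e-3)
  expect_error(lut(props, 0.3), class = "sfdilayers_domain_error")
})
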