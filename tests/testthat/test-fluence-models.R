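test_that("exponential-sum evaluation matches its closed form", {
  expect_equal(evaluate_fluence(exp_sum(1, 1), 0), 1)
  expect_equal(evaluate_fluence(exp_sum(1, 1), log(2)), 0.5)
  expect_equal(evaluate_fluence(exp_sum(c(1, -0.5), c(1, 2)), 0), 0.5)
  expect_error(evaluate_fluence(exp_sum(1, 1), -0.1),
               class = "sfdilayers_domain_error")
  expect_error(exp_sum(numeric(0), numeric(0)),
               class = "sfdilayers_domain_error")
  expect_error(exp_sum(1, -1), class = "sfdilayers_domain_error")
})

test_that("collected sums reproduce raw equation transcriptions to machine precision", {
  set.seed(101)
  for (i in 1:100) {
    props <- optical_properties(runif(1, 0.01, 0.1), runif(1, 0.5, 5),
                                g = runif(1, 0.7, 0.9), n = 1.4)
    fx <- runif(1, 0, 0.5)
    z <- runif(1, 0, 10)
    for (m in fluence_models()) {
      expect_equal(evaluate_fluence(fluence(props, fx, m), z),
                   raw_phi(m, props, fx, z), tolerance = 1e-13)
    }
  }
})

test_that("delta-P1 collected form equals the four-bracket form at fixed depths", {
  props <- ref_props_visible()
  s <- delta_p1_fluence(props, 0.1)
  for (z in c(0, 0.1, 1)) {
    expect_equal(evaluate_fluence(s, z), raw_delta_p1_phi(props, 0.1, z),
                 tolerance = 1e-14)
  }
  # positive over depth on a fine grid
  z <- seq(0, 20, length.out = 1000)
  expect_true(all(evaluate_fluence(s, z) > 0))
})

test_that("surface fluence equals the independently re-evaluated constants", {
  props <- ref_props_visible()
  d <- derive_transport_coefficients(props)
  # SDA: phi(0) = A + C from the printed constants
  R <- d$R_sda
  ratio <- d$mu_eff / d$mu_tr # fx = 0
  A <- (3 * props$mu_s_prime / d$mu_tr) / (ratio^2 - 1)
  C <- -A * (1 + 3 * R) / (ratio + 3 * R)
  expect_equal(evaluate_fluence(sda_fluence(props, 0), 0), A + C,
               tolerance = 1e-14)
  # mod-delta-P1: phi(0) = (1 + A') + C'
  a_p <- 3 * d$mu_s_star * (d$mu_tr_star + d$g_star * d$mu_a) /
    (d$mu_eff^2 - d$mu_tr_star^2)
  b <- (2 / (3 * d$mu_tr)) * d$R_prime
  c_p <- -(a_p * (1 + b * d$mu_tr_star) +
             (2 / d$mu_tr) * d$R_prime * d$g_star * d$mu_s_star) /
    (1 + b * d$mu_eff)
  expect_equal(evaluate_fluence(mod_delta_p1_fluence(props, 0), 0),
               (1 + a_p) + c_p, tolerance = 1e-14)
})

test_that("all models reduce to their planar form at zero frequency", {
  grid <- unique(certified_grid()[c("mu_a", "mu_s_prime", "g")])
  for (i in seq_len(nrow(grid))) {
    props <- optical_properties(grid$mu_a[i], grid$mu_s_prime[i],
                                g = grid$g[i])
    d <- derive_transport_coefficients(props)
    for (m in fluence_models()) {
      s <- fluence(props, 0, m)
      # the frequency-dependent rate collapses to mu_eff term-by-term
      expect_equal(sort(s$rate),
                   sort(c(if (m == "sda") d$mu_tr else d$mu_tr_star,
                          d$mu_eff)), tolerance = 1e-14)
      z <- c(0, 0.3, 2)
      expect_equal(evaluate_fluence(s, z), raw_phi(m, props, 0, z),
                   tolerance = 1e-13)
    }
  }
})

test_that("fluence is positive over the certified parameter grid", {
  grid <- certified_grid()
  z <- seq(0, 20, length.out = 400)
  for (i in seq_len(nrow(grid))) {
    props <- optical_properties(grid$mu_a[i], grid$mu_s_prime[i],
                                g = grid$g[i])
    for (m in fluence_models()) {
      phi <- evaluate_fluence(fluence(props, grid$fx[i], m), z)
      expect_true(all(phi > 0))
    }
  }
})

test_that("photon mass concentrates toward the surface as frequency grows", {
  grid <- unique(certified_grid()[c("mu_a", "mu_s_prime", "g")])
  fx <- c(0, 0.1, 0.3, 0.5)
  for (i in seq_len(nrow(grid))) {
    props <- optical_properties(grid$mu_a[i], grid$mu_s_prime[i],
                                g = grid$g[i])
    for (m in fluence_models()) {
      depths <- vapply(fx, function(f) half_mass_depth(fluence(props, f, m)),
                       numeric(1))
      expect_true(all(diff(depths) <= 0))
    }
  }
  # the qualitative published comparison at the visible-range property set:
  # both delta-P1 variants are shallower than SDA, and mod-delta-P1 is
  # shallower than SDA at every tested frequency
  props <- ref_props_visible()
  for (f in c(0, 0.2, 0.4)) {
    d_sda <- half_mass_depth(sda_fluence(props, f))
    expect_lt(half_mass_depth(delta_p1_fluence(props, f)), d_sda)
    expect_lt(half_mass_depth(mod_delta_p1_fluence(props, f)), d_sda)
  }
  # and delta-P1 decays faster near the surface at fx = 0: larger
  # normalized surface fluence than SDA
  norm_phi0 <- function(s) {
    evaluate_fluence(s, 0) / sum(s$amplitude / s$rate)
  }
  expect_gt(norm_phi0(delta_p1_fluence(props, 0)),
            norm_phi0(sda_fluence(props, 0)))
})

test_that("modified delta-P1 satisfies its boundary condition everywhere", {
  grid <- certified_grid()
  for (i in seq_len(nrow(grid))) {
    props <- optical_properties(grid$mu_a[i], grid$mu_s_prime[i],
                                g = grid$g[i])
    d <- derive_transport_coefficients(props)
    s <- mod_delta_p1_fluence(props, grid$fx[i])
    # diffuse part only: strip the collimated "1" from the mu_tr* term
    a_d <- s$amplitude - c(1, 0)
    k <- s$rate
    phi0 <- sum(a_d)
    dphi0 <- -sum(a_d * k)
    lhs <- phi0 - (2 / (3 * d$mu_tr)) * d$R_prime * dphi0
    rhs <- -(2 / d$mu_tr) * d$R_prime * d$g_star * d$mu_s_star
    expect_lt(abs(lhs - rhs) / abs(phi0), 1e-9)
  }
})

test_that("degenerate rate configurations raise a singular error", {
  props <- optical_properties(0.05, 5, g = 0.8)
  d <- derive_transport_coefficients(props)
  # pick fx so that mu_eff'(fx) == mu_tr exactly
  fx_sing <- sqrt(d$mu_tr^2 - d$mu_eff^2) / (2 * pi)
  expect_error(sda_fluence(props, fx_sing),
               class = "sfdilayers_singular_error")
  fx_sing_star <- sqrt(d$mu_tr_star^2 - d$mu_eff^2) / (2 * pi)
  expect_error(delta_p1_fluence(props, fx_sing_star),
               class = "sfdilayers_singular_error")
  expect_error(mod_delta_p1_fluence(props, fx_sing_star),
               class = "sfdilayers_singular_error")
  # a small perturbation moves off the degenerate point
  expect_s3_class(sda_fluence(props, fx_sing + 1e-4), "exp_sum")
})

test_that("fluence profiles tabulate tidily for export", {
  prof <- fluence_profile(ref_props_visible(), fx = c(0, 0.2),
                          z = seq(0, 5, length.out = 50))
  expect_named(prof, c("model", "fx", "z", "phi"))
  expect_equal(nrow(prof), 3 * 2 * 50)
  expect_true(all(prof$phi > 0))
})
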