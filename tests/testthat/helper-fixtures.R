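# Shared fixtures and independent oracles. The raw_* functions transcribe
# the published closed forms directly (un-collected, no exponential-sum
# bookkeeping) so they provide a second, independent path to the same
# fluence values.

ref_props_visible <- function() optical_properties(0.05, 5, g = 0.8, n = 1.4)

# the parameter grid on which the models are certified positive
certified_grid <- function() {
  expand.grid(mu_a = c(0.01, 0.05, 0.1),
              mu_s_prime = c(0.5, 1, 2, 5),
              g = c(0.7, 0.8, 0.9),
              fx = c(0, 0.1, 0.3, 0.5))
}

raw_derived <- function(props, fx) {
  mu_tr <- props$mu_a + props$mu_s_prime
  mu_eff <- sqrt(3 * props$mu_a * mu_tr)
  mu_s <- props$mu_s_prime / (1 - props$g)
  mu_s_star <- mu_s * (1 - props$g^2)
  list(mu_tr = mu_tr, mu_eff = mu_eff, mu_s_star = mu_s_star,
       mu_tr_star = props$mu_a + mu_s_star,
       g_star = props$g / (props$g + 1),
       reff = reff_approx(props$n),
       r1 = fresnel_moment_r1(props$n),
       mu_eff_p = sqrt(mu_eff^2 + (2 * pi * fx)^2))
}

# standard diffusion approximation, transcribed independently
raw_sda_phi <- function(props, fx, z) {
  d <- raw_derived(props, fx)
  R <- (1 - d$reff) / (2 * (1 + d$reff))
  A <- (3 * props$mu_s_prime / d$mu_tr) / ((d$mu_eff_p / d$mu_tr)^2 - 1)
  C <- -A * (1 + 3 * R) / (d$mu_eff_p / d$mu_tr + 3 * R)
  A * exp(-d$mu_tr * z) + C * exp(-d$mu_eff_p * z)
}

# original delta-P1 AC fluence, raw four-bracket form
raw_delta_p1_phi <- function(props, fx, z) {
  d <- raw_derived(props, fx)
  r_prime <- (1 + d$r1) / (1 - d$r1)
  c_star <- 3 * d$mu_tr * d$mu_s_star / (2 * d$mu_eff_p)
  zb <- (2 / (3 * d$mu_tr)) * r_prime
  c_star / (d$mu_eff_p - d$mu_tr_star) *
    (exp(-d$mu_tr_star * z) - exp(-d$mu_eff_p * z)) +
    c_star / (d$mu_eff_p + d$mu_tr_star) *
    (exp(-d$mu_tr_star * z) - exp(-d$mu_eff_p * (z + 2 * zb)))
}

# modified delta-P1 with collimated component, coefficients transcribed
raw_mod_delta_p1_phi <- function(props, fx, z) {
  d <- raw_derived(props, fx)
  r_prime <- (1 + d$r1) / (1 - d$r1)
  a_p <- 3 * d$mu_s_star * (d$mu_tr_star + d$g_star * props$mu_a) /
    (d$mu_eff_p^2 - d$mu_tr_star^2)
  c_p <- -(a_p * (1 + (2 * r_prime * d$mu_tr_star) / (3 * d$mu_tr)) +
             (2 / d$mu_tr) * r_prime * d$g_star * d$mu_s_star) /
    (1 + (2 * r_prime * d$mu_eff_p) / (3 * d$mu_tr))
  (1 + a_p) * exp(-d$mu_tr_star * z) + c_p * exp(-d$mu_eff_p * z)
}

raw_phi <- function(model, props, fx, z) {
  switch(model,
         sda = raw_sda_phi(props, fx, z),
         delta_p1 = raw_delta_p1_phi(props, fx, z),
         mod_delta_p1 = raw_mod_delta_p1_phi(props, fx, z))
}

# seeded random exponential sums with a dominant positive leading term;
# resampled until positive on a depth grid so alpha is well defined
random_positive_exp_sum <- function() {
  repeat {
    n_terms <- sample(2:3, 1)
    rate <- sort(runif(n_terms, 0.3, 10))
    amplitude <- c(runif(1, 0.5, 2), runif(n_terms - 1, -0.3, 1))
    # put the dominant positive amplitude on the slowest rate
    s <- exp_sum(amplitude = amplitude, rate = rate)
    z <- seq(0, 40 / min(rate), length.out = 400)
    if (all(evaluate_fluence(s, z) > 0)) return(s)
  }
}

# noise-free homogeneous acquisition pair (sample + reference stacks)
homog_stack_pair <- function(props, ref_props,
                             frequencies = default_frequency_grid(),
                             shape = c(64, 64), seed = 1L) {
  sample <- synthesize_pattern_stack(forward_rd(props, frequencies),
                                     frequencies,
                                     noise = noise_spec(seed = seed),
                                     shape = shape)
  reference <- synthesize_pattern_stack(forward_rd(ref_props, frequencies),
                                        frequencies,
                                        noise = noise_spec(seed = seed + 1L),
                                        shape = shape)
  list(sample = sample, reference = reference)
}

table2_suite_phantom <- function(label = "phantom2", band = "536") {
  suite_phantom(make_phantom_suite(), label, band)
}
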