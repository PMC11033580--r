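---
title: "Depth-resolved scattering from multi-frequency SFDI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved scattering from multi-frequency SFDI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdilayers)
```

## The problem

Spatial frequency domain imaging (SFDI) projects sinusoidal light patterns
onto tissue and, from the frequency-dependent damping of the remitted
diffuse reflectance, separates the absorption coefficient $\mu_a$ from the
reduced scattering coefficient $\mu_s'$. Conventional SFDI processing
assumes a homogeneous, semi-infinite medium. Skin is neither: thin layers
(a healing wound's new epithelium, for instance, at 0.05–0.5 mm) sit on
optically different tissue, and the single $\mu_s'$ a homogeneous inversion
returns is a depth-weighted blend of the layers.

This package implements a depth-resolved analysis of that blend. Because
higher spatial frequencies penetrate less deeply, processing *sub-sets* of
an acquisition grid with increasing mean frequency $\langle f_x \rangle$
yields a sequence of homogeneous-equivalent measurements
$\mu_{s,\mathrm{meas}}'(\langle f_x \rangle)$ that sample progressively
shallower volumes. A two-layer model predicts that sequence from three
parameters — top-layer thickness $d$ and the layer coefficients
$\mu_{s,\mathrm{top}}'$, $\mu_{s,\mathrm{bot}}'$ — via a linear mixture

$$\mu_{s,\mathrm{mod}}'(\langle f_x\rangle)
  = \alpha(d, f_x)\, \mu_{s,\mathrm{top}}'
  + \bigl(1 - \alpha(d, f_x)\bigr)\, \mu_{s,\mathrm{bot}}',$$

where the weight $\alpha$ is the top layer's share of the depth-integrated
*photon hitting density*. For planar illumination and wide-field detection
the source and detector sensitivity profiles coincide, so the hitting
density is the fluence squared and

$$\alpha(d, f_x) = \frac{\int_0^d \phi^2(z, f_x)\,dz}
                        {\int_0^\infty \phi^2(z, f_x)\,dz}.$$

The geometry is reduced to one dimension in depth $z$; the layers share a
refractive index (`two_layer_phantom()` enforces this), and only scattering
contrast between the layers is modeled — absorption layering is out of
scope.

## Fluence models

Three closed-form models of the depth fluence $\phi(z, f_x)/P_0$ are
provided, all returned in a common representation, a finite sum of decaying
exponentials $\phi(z) = \sum_i a_i e^{-k_i z}$ (`exp_sum`), which makes
$\int \phi^2$ analytic: the pairwise products integrate to
$a_i a_j / (k_i + k_j)$ terms.

* **SDA** (`sda_fluence()`): the standard diffusion approximation driven by
  a sinusoidally modulated source. Two rates, the transport coefficient
  $\mu_{tr} = \mu_a + \mu_s'$ and the frequency-modified attenuation
  $\mu_{eff}'(f_x) = \sqrt{\mu_{eff}^2 + (2\pi f_x)^2}$ with
  $\mu_{eff} = \sqrt{3\mu_a\mu_{tr}}$. The boundary constant is
  $R = (1-R_{eff})/(2(1+R_{eff}))$.
* **δ-P1** (`delta_p1_fluence()`): the δ-P1 closure with its published
  spatial-frequency AC solution, used exactly in that form (no separate
  collimated term). Rates $\mu_{tr}^* = \mu_a + \mu_s(1-g^2)$ and
  $\mu_{eff}'$; the extrapolated boundary $z_b = \tfrac{2}{3\mu_{tr}} R'$
  enters through a folded amplitude $e^{-2\mu_{eff}' z_b}$.
* **mod-δ-P1** (`mod_delta_p1_fluence()`): the δ-P1 governing equation
  re-solved for a sinusoidal source with a diffuse-flux boundary condition,
  plus the collimated component $e^{-\mu_{tr}^* z}$. Its $C'$ coefficient is
  fixed by
  $[\phi_d - \tfrac{2}{3\mu_{tr}} R' \,d\phi_d/dz]_{z=0}
   = -\tfrac{2}{\mu_{tr}} R' g^* \mu_s^*$,
  and the test suite asserts this residual is below $10^{-9}$ relative on
  the whole certified grid — the derivation's own acceptance surface.

The projected patterns are one-dimensional, so the wavenumber is
$k_x = 2\pi f_x$, $k_y = 0$. Normalization is per delivered (post-specular)
power: specular reflectance cancels in reference-phantom calibration, so it
is set to zero throughout.

### Boundary reflection terms

$R_{eff}$ uses the standard rational fit
$0.0636\,n + 0.668 + 0.710/n - 1.440/n^2$ (value $0.0016$ at $n=1$, its
documented matched-boundary value). The δ-P1 boundary ratio
$R' = (1+R_1)/(1-R_1)$ needs the first angular moment $R_1$ of the
unpolarized Fresnel reflection coefficient for internal incidence. Fitted
polynomials for $R_1$ circulate in several variants with no single
canonical coefficient set, so the package evaluates the defining integral
$R_1 = 2\int_0^1 \mu\,R_F(\mu)\,d\mu$ (total internal reflection included)
by adaptive quadrature instead: it is exact at every $n$, microseconds to
compute, and $R_1(1) = 0$ identically. Both terms sit behind single
functions (`reff_approx()`, `fresnel_moment_r1()`) so alternates can be
swapped in. $R'$ is implemented as a *ratio*: the printed product form that
sometimes appears is dimensionally inert and does not satisfy the boundary
condition role the constant plays; the ratio does, as the boundary-residual
test demonstrates.

### Certified parameter grid and numerical choices

The models are certified positive (and $\alpha$ monotone in $d$ and $f_x$)
on the physiological grid $\mu_a \in \{0.01, 0.05, 0.1\}$,
$\mu_s' \in \{0.5, 1, 2, 5\}$ mm⁻¹, $g \in \{0.7, 0.8, 0.9\}$,
$f_x \in \{0, 0.1, 0.3, 0.5\}$ mm⁻¹. Outside it, `fluence_profile()` checks
positivity at call time and warns. Isolated frequencies where
$\mu_{eff}'(f_x)$ coincides with the source decay rate make the particular
solution singular; the models raise a typed error there (relative gap below
$10^{-9}$) rather than silently perturbing — the caller decides whether to
nudge $f_x$ (a shift of $10^{-6}$ mm⁻¹ suffices). In the $\alpha$
integrals, pair rates are summed before exponentiation and pair terms below
$10^{-300}$ are dropped; the quadrature oracle truncates infinity at
$40/k_{\min}$, where the neglected tail is below $10^{-12}$ of the total.
$\alpha$ is computed from the full signed sum — the fluence is squared
as-is, with no clipping — and a sum whose squared integral is not positive
is rejected as non-physical.

Anisotropy and refractive index are not measurable by SFDI; defaults
$g = 0.8$, $n = 1.4$ are the usual soft-tissue conventions and are
user-overridable everywhere. All coefficients are mm⁻¹, frequencies mm⁻¹,
depths mm, with no exceptions.

## Sub-set processing

An acquisition of 11 frequencies, 0–0.5 mm⁻¹ in 0.05 steps
(`default_frequency_grid()`), is divided into 8 overlapping windows of 4
(`split_subsets()`). Per window the chain is: three-phase demodulation
$M_{AC} = \tfrac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}$
(exact for noise-free sinusoids, DC-offset invariant; planar $f_x = 0$
frames are averaged instead), calibration against a reference phantom of
known properties, a central-rectangle spatial average (25% of image area by
default), and a bounded Levenberg–Marquardt fit of $(\mu_a, \mu_s')$ to the
windowed reflectance. The forward reflectance is the closed-form diffusion
expression
$R_d = 3Aa' / \bigl((\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)\bigr)$;
a tabulated model (e.g. white Monte Carlo output) can be plugged in via
`rd_lookup_model()` wherever an `rd_model` argument is accepted, for
processing faithful to lookup-table practice. Because the shipped forward
model is diffusion-based, absolute inverted properties differ slightly from
what a Monte Carlo lookup would give; all quantitative checks in this
package are therefore self-consistency and recovery properties.

High-frequency windows carry little absorption information, so a single
fixed start can strand the optimizer in the wrong basin: `invert_homogeneous()`
falls back to a fixed grid of restarts (keeping the best residual,
deterministically), and `process_stack()` warm-starts each window from the
previous window's fit. Box bounds are $\mu_a \in [10^{-4}, 1]$,
$\mu_s' \in [0.05, 10]$ mm⁻¹; bound-pinned solutions are flagged in the
result. The per-window mean $\langle f_x\rangle$ is the frequency at which
the fluence (and hence $\alpha$) is evaluated, using that window's own
homogeneous-equivalent $(\mu_a, \mu_s')$ — both coefficients, since the
measurement supplies both. The reported penetration depth
$\delta = 1/\mu_{eff}'(\langle f_x\rangle)$ is a ranking convention for
sub-sets, not a uniquely defined physical quantity, and is never used in
any quantitative comparison.

Model performance is scored with the root mean square percentage error over
the sub-set means,
$\mathrm{RMSPE} = \sqrt{\tfrac1N \sum_i
 \bigl(\tfrac{\mu_{s,\mathrm{meas}}' - \mu_{s,\mathrm{mod}}'}
             {\mu_{s,\mathrm{meas}}'}\bigr)^2} \times 100$,
with the percent factor outside the root; $N$ is the number of sub-sets
actually present (8 on the default grid) and is recorded, never assumed.

## What the synthetic generator emulates — and what it does not

`make_phantom_suite()` reproduces a layered calibration-phantom suite: five
thin TiO₂-like top layers ($d$ = 0.130, 0.269, 0.490, 0.675, 1.149 mm) on a
semi-infinite Al₂O₃-like base, characterized at three visible bands with
scattering contrasts of about 4, 3.5 and 3. `synthesize_pattern_stack()`
emulates the acquisition: three-phase sinusoids per frequency, planar
frames at $f_x = 0$, optional multiplicative and additive Gaussian noise
under a recorded seed (re-running a seed is bit-identical). Images default
to 64×64 pixels at 0.4 mm pitch, chosen so one full period of the lowest
nonzero default frequency (20 mm) fits the field of view while the highest
frequency stays below the Nyquist limit of the pitch; the synthesis is
exact pixelwise at any frequency, but stacks too small to hold one period
are rejected as unrepresentative. Source intensity is in normalized units
(default 1) so noise-free intensities stay within the [0, 1] range of
float TIFF storage. No noise magnitudes are published for the emulated
imager; the 1% multiplicative default used in noisy tests is a testing
convention.

The generator's homogeneous-equivalent measurement series
(`simulate_measurement_series()`) closes the two-layer model on itself: at
each $\langle f_x\rangle$ a fixed-point iteration finds the pair where
$\mu_s'$ equals the resulting $\mu_{s,\mathrm{mod}}'$ and $\mu_a$ equals
the $\alpha$-weighted layer mean (the weight that plays the
thickness-weighting role for a semi-infinite base; tolerance $10^{-8}$,
at most 100 iterations). This is a *synthetic closure, not physics*: no
layered radiative-transport solution is shipped. Consequently, passing
round-trip tests demonstrate internal consistency of the pipeline — that
processing inverts synthesis, that each fluence model regenerates its own
curve to $10^{-6}$ and wins its own comparison — not that any model matches
a real layered medium. A hook (`homog_props_rule`) accepts externally
computed series, e.g. from layered Monte Carlo, for higher-fidelity
generation. Encouragingly, when the synthetic layered acquisition is pushed
through the full image chain, the homogeneous inversion reproduces two
behaviours known from real layered targets: the recovered series is biased
relative to the generating series (the homogeneous-fluence assumption at
work), and the recovered $\mu_a$ inflates with $\langle f_x\rangle$ where
absorption sensitivity collapses.

## Problem sizes

The test suite and the acceptance script run everything at desk scale as
the package's own defaults: 64×64-pixel stacks, the 11-frequency grid,
8 sub-sets, 200 random exponential sums for the $\alpha$ cross-validation,
100 noise replicates for the inversion accuracy summary. The full suite
completes in under three minutes on one core; the end-to-end synthetic
acquisition (simulate, write, read, process, model, compare) takes about
ten seconds.

## Known limitations

* The inverse problem — estimating $(\mu_{s,\mathrm{top}}',
  \mu_{s,\mathrm{bot}}', d)$ from a measured curve — is out of scope; the
  model predicts curves from known layer parameters.
* Absorption contrast between layers is not modeled, and the $\mu_a$
  inflation at high $\langle f_x\rangle$ is reported as-is, uncorrected.
* The homogeneous-fluence assumption biases $\alpha$ when layer contrast is
  large; the package follows the stated pipeline (per-sub-set
  homogeneous-equivalent properties feed the fluence) and inherits that
  bias deliberately.
* Matched refractive index between layers is assumed; index-mismatched
  stacks would add boundary reflections none of the models carry.

## A worked example

```{r, eval = FALSE}
suite <- make_phantom_suite()
ph <- suite_phantom(suite, "phantom2", "536")

series <- simulate_measurement_series(ph, model = "mod_delta_p1")
curve <- model_curve(series, ph, "mod_delta_p1")
autoplot(curve)

meas <- dplyr::mutate(series, phantom_label = "phantom2",
                      wavelength = "536")
compare_models(meas, function(...) ph)
```
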