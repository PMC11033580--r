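# sfdilayers

Depth-resolved scattering analysis for multi-frequency spatial frequency
domain imaging (SFDI).

SFDI projects sinusoidal light patterns at several spatial frequencies
f<sub>x</sub> and inverts the damping of the remitted diffuse reflectance
into tissue absorption (μ<sub>a</sub>) and reduced scattering (μ<sub>s</sub>′)
coefficients, assuming a homogeneous semi-infinite medium. Skin is layered:
a healing wound, for example, grows a thin (0.05–0.5 mm) epithelial layer
whose scattering differs from the bed below, and a homogeneous inversion
returns a depth-weighted blend of the two. This package is for researchers
in tissue optics and biomedical imaging who want to resolve that blend:
it processes a multi-frequency acquisition in overlapping frequency
sub-sets — higher frequencies penetrate less deeply, so each sub-set
samples a shallower volume — and interprets the resulting
μ<sub>s,meas</sub>′(⟨f<sub>x</sub>⟩) curve with a two-layer scattering
model.

## The model

The modeled scattering coefficient is a linear mixture of the layer
coefficients,

μ<sub>s,mod</sub>′(⟨f<sub>x</sub>⟩) = α(d, f<sub>x</sub>) μ<sub>s,top</sub>′ + (1 − α(d, f<sub>x</sub>)) μ<sub>s,bot</sub>′,

weighted by the top layer's share of the depth-integrated photon hitting
density. For co-located planar illumination and wide-field detection the
hitting density is the fluence squared, so

α(d, f<sub>x</sub>) = ∫₀^d φ²(z, f<sub>x</sub>) dz / ∫₀^∞ φ²(z, f<sub>x</sub>) dz,

with the fluence φ evaluated from the homogeneous-equivalent properties
measured per sub-set. Three closed-form fluence models are implemented —
the standard diffusion approximation (SDA), the δ-P1 approximation with
spatial-frequency dependence, and a modified δ-P1 re-derived with
sinusoidal-source boundary conditions plus its collimated component — all
expressed as exponential sums so α is analytic. Models are scored against
measured curves with the root mean square percentage error (RMSPE) over the
sub-set means. A synthetic layered-phantom generator (TiO₂-like thin layers
over an Al₂O₃-like base, three-phase pattern stacks with seeded noise)
exercises the whole pipeline without instrument data.

## A worked example

Predict and score the sub-set scattering curve of a 0.269 mm top layer
with roughly 3.5× scattering contrast, at the 536 nm band:

```r
library(sfdilayers)

suite <- make_phantom_suite()
ph <- suite_phantom(suite, "phantom2", "536")
ph
#> <two_layer_phantom> phantom2@536nm
#>   d = 0.269 mm
#>   top:    mu_a = 0.037  mu_s' = 2.9269 mm^-1
#>   bottom: mu_a = 0.0226  mu_s' = 0.8322 mm^-1

series <- simulate_measurement_series(ph, model = "mod_delta_p1")
series
#> # A tibble: 8 × 6
#>   subset fx_mean   mu_a mu_s_prime alpha mu_s_mod
#>    <int>   <dbl>  <dbl>      <dbl> <dbl>    <dbl>
#> 1      1   0.075 0.0249       1.16 0.159     1.16
#> 2      2   0.125 0.0258       1.30 0.223     1.30
#> 3      3   0.175 0.0267       1.43 0.283     1.43
#> 4      4   0.225 0.0275       1.54 0.338     1.54
#> 5      5   0.275 0.0282       1.65 0.388     1.65
#> 6      6   0.325 0.0288       1.74 0.434     1.74
#> 7      7   0.375 0.0294       1.83 0.475     1.83
#> 8      8   0.425 0.0300       1.91 0.513     1.91
```

Reading the series: as the sub-set mean frequency grows from 0.075 to
0.425 mm⁻¹ the sampled volume shrinks toward the surface, the
partial-volume weight α of the top layer rises from 0.16 to 0.51, and the
homogeneous-equivalent scattering climbs from 1.16 toward the top layer's
2.93 mm⁻¹, staying between the two layer coefficients throughout. Scoring
all three fluence models against this series:

```r
meas <- dplyr::mutate(series, phantom_label = "phantom2", wavelength = "536")
compare_models(meas, function(...) ph)
#> # A tibble: 3 × 7
#>   model        phantom_label wavelength     d contrast         rmspe n_points
#>   <chr>        <chr>         <chr>      <dbl>    <dbl>         <dbl>    <int>
#> 1 sda          phantom2      536        0.269     3.52 11.6                 8
#> 2 delta_p1     phantom2      536        0.269     3.52  4.65                8
#> 3 mod_delta_p1 phantom2      536        0.269     3.52  0.0000000683        8
```

The generating model reproduces its own curve essentially exactly (RMSPE
≈ 7 × 10⁻⁸ %), while the SDA — which places photons deeper than either
δ-P1 variant — misses this thin-layer case by 11.6%. `autoplot()` methods
plot model curves and comparison tables; `plot_fluence_profiles()` shows
how each model concentrates photons toward the surface as f<sub>x</sub>
grows.

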