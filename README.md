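# skindrs

Estimation of *in vivo* skin optical properties from probe-based diffuse
reflectance spectroscopy (DRS) with a three-layer skin model.

A contact probe injects broadband light (475–850 nm) into the skin and
records the diffusely backscattered intensity at two source–detector
separations (0.4 and 1.2 mm). Fitting a layered light-transport model to
both spectra recovers layer-resolved tissue properties that a homogeneous
model smears together: the melanin attenuation of the epidermis, the blood
tissue fraction of the upper (papillary) and lower dermis separately, the
shared hemoglobin oxygen saturation, and the reduced scattering spectrum.
This package implements that pipeline end to end for researchers in tissue
optics and microcirculation who need a reference implementation, a
validation harness, or tabulated sampling depths for short-separation DRS
probes.

## The model

Three layers — epidermis (thickness `t_epi`, fitted), upper dermis
(0.2 mm, fixed), semi-infinite lower dermis — with

- reduced scattering common to all layers:
  `μs′(λ) = α((1−γ)(λ/600)^−β + γ(λ/600)^−4)` (mm⁻¹), so `α = μs′(600)`;
- epidermal absorption `μa,epi = f_mel · 48.4(λ/550)^−β_mel`;
- dermal absorption
  `μa,n = f_blood,n · c_vp · (s·μa,oxy + (1−s)·μa,deoxy)`, with whole
  blood at hematocrit 43%, MCHC 345 g/L, and a cylindrical-vessel
  packaging factor `c_vp = (1−e^(−2μa,bl R))/(2μa,bl R)`.

Nine parameters are free: `α, β, γ, t_epi, f_mel, β_mel, f_blood,1,
f_blood,2, s`.

The forward model is *white Monte Carlo*: absorption-free layered photon
transport (Henyey–Greenstein scattering, Fresnel boundaries, annular fiber
detection) stores each detected photon's per-layer pathlength; any
absorption spectrum is then applied as a Beer–Lambert reweighting, and
reflectance is interpolated bilinearly in (epidermis thickness,
log scattering) over a simulation grid. The inverse solver is bounded
multi-start Levenberg–Marquardt on a relative least-squares objective with
per-detector scale factors profiled out. The *sampling depth* of each
detector is the depth above which 63% (1−1/e) of the detected photons'
weighted path points lie.

## Worked example

```r
library(skindrs)

# Monte Carlo basis over (epidermis thickness x scattering)
basis <- build_mc_basis(t_epi_levels = c(0.02, 0.06, 0.15),
                        musp_levels = c(0.8, 1.6, 3.2),
                        n_photons = 5e4, seed = 1)

# a subject: median-like skin
truth <- c(alpha = 1.8, beta = 0.8, gamma = 0.3, t_epi = 0.06,
           f_mel = 0.05, beta_mel = 4.3, f_blood1 = 0.011,
           f_blood2 = 0.0075, s = 0.5)
measured <- model_reflectance(skin_params_from_vector(truth), basis)

fit <- fit_spectrum(measured, basis, fit_config(n_probe = 400, seed = 2),
                    warm_start = truth)
fit
#> Three-layer skin model fit
#>   objective 0 (relative RMS 0), 12 starts / 2 passes
#>    alpha     beta    gamma    t_epi    f_mel beta_mel f_blood1 f_blood2
#>   1.8000   0.8000   0.3000   0.0600   0.0500   4.3000   0.0110   0.0075
#>        s
#>   0.5000
```

The fitted vector reproduces the generating parameters. Noiseless spectra
are recovered to numerical precision; at 1% measurement noise
`recovery_study()` puts the median recovery error near 1 percentage point
for the oxygen saturation and near 8% relative for the upper-dermis blood
fraction, with a heavy tail driven by the epidermis-thickness degeneracy
(the methods vignette quantifies it).

The `analysis/` directory holds the full workflow as numbered scripts:
`01_build_basis.R` (simulation grid), `02_synthetic_cohort.R` (cohort
draws and noisy spectra), `03_fit_cohort.R` (inverse solutions and
recovery errors), `04_sampling_depth.R` (wavelength-resolved sampling
depths), `05_cohort_stats.R` (median/IQR tables, Mann–Whitney and
Kruskal–Wallis/Dunn comparisons, age trend). Each writes its tables under
`results/`.

## Scientific background

The model structure, parameter ranges, and validation bounds follow the
published EPOS-style three-layer inverse Monte Carlo analysis of forearm
skin spectra; the methods vignette
(`vignettes/three-layer-skin-model.Rmd`) documents every equation,
assumption, default, and numerical choice, including where this
implementation had to invent what the source material does not print
(objective function, exclusion thresholds, vessel-packaging form, probe
geometry details, hemoglobin tables).
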