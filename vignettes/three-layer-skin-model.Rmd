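---
title: "A three-layer skin model for two-separation diffuse reflectance spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-layer skin model for two-separation diffuse reflectance spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skindrs)
```

## The measurement and the model

A fiber-optic probe in contact with the skin injects broadband light
(475–850 nm) and records the diffusely backscattered intensity at two
source–detector separations, 0.4 and 1.2 mm. The short separation
preferentially samples the upper few tenths of a millimetre; the long
separation reaches roughly twice as deep. Between 770 and 810 nm a notch
filter (protecting the spectrometers from a co-resident laser line)
suppresses the signal, so that band is carried through the pipeline but
masked out of all fitting.

The tissue model is three plane-parallel layers:

* an **epidermis** of variable thickness $t_{epi}$ whose absorption is
  melanin,
  $\mu_{a,epi}(\lambda) = f_{mel}\, 48.4 (\lambda/550)^{-\beta_{mel}}$
  (mm$^{-1}$), with $f_{mel}$ the melanin content fraction and
  $\beta_{mel}$ an adaptable spectral slope covering different melanin
  types;
* an **upper dermis** of fixed 0.2 mm thickness, roughly the depth of the
  upper vascular plexus; and
* a semi-infinite **lower dermis**.

Both dermis layers absorb through whole blood confined to vessels,

$$\mu_{a,n}(\lambda) = f_{blood,n}\; c_{vp}\;
 \bigl(s\,\mu_{a,oxy}(\lambda) + (1-s)\,\mu_{a,deoxy}(\lambda)\bigr),$$

with a blood tissue fraction $f_{blood,n}$ per layer and one shared oxygen
saturation $s$. Blood is modeled at hematocrit 43% and a mean cell
hemoglobin concentration of 345 g/L of red cells, i.e. 148.35 g/L of
hemoglobin in whole blood. The reduced scattering coefficient is common to
all layers,

$$\mu_s'(\lambda) = \alpha\bigl((1-\gamma)(\lambda/600)^{-\beta}
 + \gamma(\lambda/600)^{-4}\bigr),$$

so $\alpha$ is $\mu_s'$ at 600 nm, $\beta$ the Mie decay and $\gamma$ the
Rayleigh fraction. Nine parameters are free:
$\alpha, \beta, \gamma, t_{epi}, f_{mel}, \beta_{mel}, f_{blood,1},
f_{blood,2}, s$.

### Vessel packaging

Because hemoglobin sits in discrete vessels rather than being spread
through the tissue, the effective blood absorption is reduced — strongly so
where whole-blood absorption is high. The correction factor is not printed
in the source material, so this package adopts the standard
cylindrical-vessel mean-transmittance form

$$c_{vp} = \frac{1 - e^{-2\mu_{a,bl}R}}{2\mu_{a,bl}R},$$

the average of Beer–Lambert transmittance over traversal lengths uniform on
$(0, 2R)$, evaluated at the saturation-mixed whole-blood absorption with a
default mean vessel radius $R = 0.005$ mm (configurable). With the default
radius, $c_{vp}$ sits in the 0.6–0.95 range over the analysis band, which
keeps the dermal absorption magnitudes in line with the published
wavelength tables. Whether the original instrument evaluates the packaging
factor at the mixed absorption or per species is not documented;
mixed-absorption evaluation is assumed here.

### Hemoglobin tables

The oxy/deoxy whole-blood absorption spectra are compiled at load time from
a bundled extinction table
(`inst/extdata/hemoglobin_extinction_synthetic.tsv`). The original
literature compilations are not redistributable here, so the fixture is a
**synthetic** anchor-point approximation with the correct qualitative
anatomy — the 542/577 nm oxyhemoglobin double peak, the 555 nm
deoxyhemoglobin peak and its 760 nm shoulder, and a near-infrared
isosbestic point close to 800 nm — and realistic magnitudes (whole-blood
$\mu_{a,oxy} \approx 29$ mm$^{-1}$ at 575 nm). Conversion to absorption
uses the natural-log convention,
$\mu_a = \ln 10 \cdot \varepsilon \cdot C_{molar} / 10$ per mm, with the
64 500 g/mol tetramer mass. Anchors are interpolated in $\log \varepsilon$
with a monotone piecewise cubic onto a 1 nm grid; interpolation in log
space keeps the table strictly positive. All parameter-recovery
experiments use the same table in generation and fitting, so their results
do not depend on the fixture's absolute accuracy; wavelength-table
cross-checks against published dermal absorption magnitudes do, and are
asserted only as order-of-magnitude sanity bands.

## White Monte Carlo transport

The forward model rests on *white* (absorption-free) Monte Carlo
simulations: photons are transported with scattering only, the pathlength
each detected photon spent in each layer is stored, and absorption is
applied afterwards as the Beer–Lambert factor
$\exp(-\sum_\ell \mu_{a,\ell} L_\ell)$. One simulation therefore serves
every absorption spectrum.

Quantities the source material does not specify were fixed at standard
skin-optics values, all configurable: Henyey–Greenstein phase function with
$g = 0.8$ in every layer, tissue refractive index 1.4, external index 1.5
on the probe side (fiber contact). The probe is modeled from its published
separations only; fiber core radius 0.1 mm and numerical aperture 0.37 are
declared defaults, not inferred instrument values. Detection exploits
rotational symmetry: a photon exiting at radius $r$ with
$|r - \rho_{det}| <$ fiber radius, within the acceptance angle, is recorded
with its weight multiplied by the azimuthal arc fraction of its exit circle
covered by the fiber face — the variance-reduced equivalent of a discrete
fiber.

Photon termination: escape through the surface, a depth cutoff (default
20 mm, counted explicitly as lost weight so the energy ledger stays exact),
an event cap, and Russian roulette below weight $10^{-4}$ with survival
factor 10. In absorption-free transport the weight never falls, so
roulette is inactive by construction; the ledger test instead verifies that
every launched photon ends in exactly one accounting bucket, to machine
precision. The engine uses its own xoshiro256+ generator seeded by
splitmix64, making every run bit-reproducible from its seed and independent
of R's RNG state.

Two independent physics checks gate the engine. First, energy
conservation: in a matched-index semi-infinite medium with a deep cutoff,
at least 99.5% of launched weight returns through the surface. Second,
spatially resolved reflectance at the 1.2 mm separation is compared with
the diffusion-approximation closed form. The plain dipole
(Farrell-type) expression is a poor reference at
$\rho \approx 1$ transport mean free path, where it substantially
overestimates the near field for an index-mismatched boundary — a known
limitation of that variant, not an engine property. The test oracle is
therefore the partial-current variant — dipole fluence plus flux at the
boundary, weighted by Fresnel-integrated angular coefficients — against
which the engine agrees within 15% at 1.2 mm.

## Spectral synthesis and interpolation

A basis is a grid of simulations over epidermis thickness and reduced
scattering (the two quantities that change the *geometry* of photon paths;
absorption is handled by reweighting). For arbitrary parameters the model
reflectance is synthesized per wavelength at the four surrounding grid
cells and interpolated bilinearly in $(t_{epi}, \log \mu_s')$; the log axis
linearizes the dominant scattering dependence. At grid nodes the
interpolation reproduces the node evaluation exactly (tested). The
default grid spans $t_{epi}$ 0.025–0.3 mm and $\mu_s'$ 0.5–5 mm$^{-1}$ in
10 log-spaced levels; the cohort workflow uses a wider 0.45–6.7 mm$^{-1}$
span in 7 levels because the synthetic cohort's scattering spectra reach
both beyond 5 mm$^{-1}$ at 475 nm and below 0.5 mm$^{-1}$ at 850 nm.
Absorption is applied photon by photon (the reference path); a
histogram-style fast path was considered and rejected — the photon loop in
compiled code is already far from the bottleneck.

The basis lives in memory as a plain list-of-cells structure
(`cells[[i]][[j]]$detectors[[k]]` holding the pathlength matrix and
weights) and is cached with `saveRDS`. The cache is a runtime convenience:
rebuilding from the seed gives a bit-identical basis.

## The inverse problem

The objective is relative least squares with one multiplicative scale
factor per detector profiled out in closed form — the model predicts
detected weight per launched photon, while measurements are in arbitrary
calibrated units. Masked channels never enter. The relative RMS residual
doubles as the data-quality statistic: fits with RMS above 0.10, or with a
fitted upper-dermis blood fraction below 0.002, are flagged excluded
(both thresholds are this package's inventions; the source analysis
excludes on the same two grounds without printing its cutoffs).

The likelihood surface is genuinely multimodal. The dominant degeneracy is
the epidermal one — thickness and melanin fraction trade against each other
almost freely, so only their product $\mu_{a,epi} t_{epi}$ is well
determined — and it interacts with the scattering shape parameters to
produce families of local minima whose objectives differ by less than the
noise. Profile-likelihood experiments at 1% channel noise show the
curvature around the global basin still identifies $s$ to a few percentage
points and $f_{blood,1}$ to roughly ±10%, but only if the global basin is
actually found. Plain Latin-hypercube multi-start with a handful of starts
finds it unreliably. The solver therefore works in stages:

1. **Start library.** A large library (default 1200 points) is drawn
   mostly from quartile-matched log-normal/normal distributions of the
   nine parameters with 1.5× inflated spread — the optimizer's domain
   knowledge of where skin lives — plus a 25% Latin-hypercube fraction
   over the full bounds box for coverage, plus the previous subject's
   solution as a warm start when fitting sequences.
2. **Ranking.** The objective is evaluated at every library point on a
   thinned (every third channel) wavelength grid.
3. **Short polish.** The best 12 candidates — plus the best-ranked
   candidate from each epidermis-thickness stratum, which forces the
   search to visit competing thickness basins — get a bounded
   Levenberg–Marquardt run (35 iterations) in unit-box coordinates.
4. **Full polish.** The best 4 of those are run to convergence
   (tolerances $10^{-12}$); the lowest objective wins.
5. **Passes.** At least two full passes with independent libraries are
   always run (competing basins differ in objective by less than the noise
   floor, so a single library draw backs the wrong basin too often), and a
   third is added while the relative RMS exceeds `restart_rms` (default
   0.0105, just above the ~0.0096 residual floor that 1% channel noise
   leaves after profiling the scales). The best result over all passes is
   returned.

Optimization is done in unit-box coordinates (parameters scaled to
$[0,1]$) so the trust region treats all nine directions comparably.
During optimization, scattering values that stray off the basis grid are
clamped to the grid edge rather than erroring; user-facing forward
evaluation errors instead, naming the offending axis.

On noiseless self-consistent spectra the solver reaches objectives at
numerical zero and recovers the layer absorptions exactly; at 1% noise the
validation study below quantifies what survives.

## Sampling depth

For each detected photon, the same number of points (default 20) is drawn
uniformly along its path arc length; each point carries the photon's final
(absorption-scaled) weight. The sampling depth is the depth at which the
cumulative point weight first reaches $1 - e^{-1} \approx 63\%$ of the
total, with linear interpolation between adjacent points at the crossing —
the interpolation removes the discretization bias of small clouds and is
this package's choice where the source is silent. The statistic is, by
construction, the $1-e^{-1}$ weighted depth quantile, and the
implementation is tested against a brute-force cumulative-sum oracle.
Point weights use the absorption-scaled final weight at the evaluation
wavelength (the absorption-free alternative is not what the detected
signal samples). `depth_profile()` evaluates on the nearest basis cell in
$(t_{epi}, \log\mu_s')$ rather than interpolating point clouds across
cells; the depth statistic varies smoothly and slowly across the grid, so
nearest-cell evaluation is adequate at the grid densities used here.
Dedicated studies use `sampling_depth_mc()`, one direct simulation at the
exact optical properties.

## The synthetic cohort

No subject-level spectra are publicly available (the cohort data are
access-restricted), so the package ships a generator that stands in for
the cohort: each parameter is drawn independently from the two-parameter
distribution matching its published 25th/75th percentiles — log-normal for
the positive, right-skewed parameters, normal (truncated to $[0,1]$) for
the saturation. Matching the quartile pair exactly fixes both free
parameters in closed form; the implied median, $\sqrt{q_{25} q_{75}}$, sits
within ~5% of every published median (e.g. 2.06 vs. 1.99 mm$^{-1}$ for
$\alpha$), which is the price of a two-parameter family and is asserted
only at that tolerance. Draws are truncated by rejection to ranges a
cohort-covering basis can span; the epidermis-thickness distribution is
wide enough (quartiles 0.013–0.191 mm) that its upper tail is visibly
clipped at 0.28 mm — acceptable, since that spread itself largely reflects
the estimation uncertainty of thickness rather than anatomy. Covariates
(sex, age 50–65, BMI category, measurement month) are drawn alongside; an
optional month effect scales the melanin fraction by a seasonal multiplier
(minimum in late winter, maximum in early summer, roughly a factor of
three peak to trough) and is off by default. Parameters are drawn
independently because only marginal medians/IQRs are published; real skin
parameters are correlated, and no claim is made otherwise.

Measured spectra are the forward model plus multiplicative Gaussian
channel noise (default SD 1%) and an optional additive floor, with the
notch band masked. Generation and fitting share one basis, so recovery
errors isolate noise and solver behaviour — deliberately mirroring the
published validation, which was likewise simulation-based. What passing
recovery tests do **not** show: robustness to chromophores missing from
the model, to probe miscalibration, to phase-function mismatch, or to any
systematic difference between a real epidermis and a plane layer.

## Problem sizes and numerical choices

The shipped studies use sizes chosen to keep a laptop-class run
comfortable while leaving the statistics far from their tolerance floors:
basis grids of 5 × 7 cells at 1.2–1.5 × 10⁵ photons per cell (2000–6000
detected photons per cell at the short separation), 10⁶ launched photons
for each dedicated sampling-depth simulation (~10⁴ detected paths, giving
sub-percent depth precision at 20 points per photon), 50 synthetic
subjects at 1% noise for the recovery study, and a 600-photon per-cell cap
inside the inverse solver's forward evaluations. The depth cutoff is 12 mm
for basis building (detection at ≤1.3 mm separation is insensitive to
deeper paths) and 20 mm for sampling-depth studies; the energy-conservation
test uses 200 mm, where semi-infinite recurrence makes the criterion
strict. Quantiles everywhere are the linear-interpolation (type 7)
convention. Dunn's post hoc p-values are Bonferroni-multiplied and capped
at 1; the Mann–Whitney p uses the tie-corrected normal approximation,
which at $n = 6$ per group sits within ~0.06 of the exact permutation
value (the U statistic itself is exact).

## Known limitations

* The probe's true fiber radii, numerical apertures and index assumptions
  are unpublished; sampling-depth agreement within ±15% is the appropriate
  expectation, not exactness.
* The vessel-packaging expression and radius are adopted, not reproduced.
* The hemoglobin fixture is a labelled synthetic stand-in; absolute
  dermal-absorption comparisons against published tables are sanity bands
  only.
* Epidermis thickness and melanin fraction are reported individually by
  the fitter but only their product is trustworthy. The same coupling
  leaves a heavy tail in the blood-fraction recovery errors: at 1% noise
  the saturation stays within about 3 percentage points at the 90th
  percentile, while the upper-dermis blood fraction's 90th percentile sits
  near 30% relative even though its median error is below 10%.
* Cohort draws are independent across parameters; group-difference
  machinery (sex/age/BMI tests) is exercised on such draws, so observed
  "effects" in the synthetic workflow are null by construction.
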