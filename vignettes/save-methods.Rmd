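---
title: "Methods: RGB-to-spectrum calibration and narrow-band synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RGB-to-spectrum calibration and narrow-band synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saveHSI)
```

# The problem

White-light RGB photography integrates reflected light over three broad,
overlapping channel sensitivities; most spectral structure is lost. Hardware
narrow-band imaging recovers diagnostic contrast by illuminating at 415 nm,
where hemoglobin absorbs most strongly, and 540 nm, its secondary peak —
superficial vasculature and pigmented lesions darken sharply at these
wavelengths. `saveHSI` reproduces that contrast computationally: a one-time
calibration against a 24-patch colour checker yields a mapping from a
camera's linear RGB to a full reflectance spectrum per pixel, and narrow
bands extracted from the reconstructed cube are composited into an
NBI-style pseudo-colour image.

This vignette records the model, every tunable that matters, the design
choices made where the design was genuinely open, and what the synthetic
test bench does and does not demonstrate.

# Colorimetry

Tristimulus integration follows the CIE 1931 definition with the 2°
observer, trapezoid rule on the working grid, integration limits
400–700 nm, and the normalisation $k = 100 / \int S(\lambda)
\bar y(\lambda)\,d\lambda$, so a perfect reflector has $Y = 100$ under any
illuminant. The trapezoid rule was chosen because the model is stated as
continuous integrals with no rule attached; it is second-order accurate and
the tests verify that halving the grid step moves XYZ of smooth spectra by
less than 0.1 %.

Two deliberate approximations:

* **Colour-matching functions** are the analytic multi-lobe
  piecewise-Gaussian fits to the 2° observer, not the tabulated CIE data
  (accurate to roughly 1–2 % of peak). Every colorimetric quantity in the
  package — reference XYZ, calibration targets, ΔE00 — is computed with the
  same functions, so the pipeline is exactly self-consistent; only
  comparisons against externally measured XYZ would see the approximation
  error. A sanity check: these CMFs with the packaged D65 table put the
  equal-reflectance white at chromaticity (0.3129, 0.3294), against the
  standard (0.3127, 0.3291).
* **Illuminant D65** ships as the standard 10 nm relative-power tabulation,
  linearly interpolated to the working grid, normalised to 100 at 560 nm.

The working grid defaults to 380–780 nm at 1 nm: wider than the XYZ
integration window because the 780 nm auxiliary band must lie on the grid.

CIELAB uses the sRGB D65 white point. The white point of the Lab conversion
is an assumption, not something the calibration model pins down; D65 is the
only choice consistent with treating camera output as sRGB. CIEDE2000 is
implemented with $k_L = k_C = k_H = 1$ and is validated against the
standard 34-pair reference dataset to $10^{-4}$ (the package's fixture; the
ΔE00 column was independently recomputed with a reference implementation
before freezing).

Out-of-gamut values from `xyzToSrgb()` are returned unclipped with a flag:
the calibration regressions need unclipped residuals, and clipping is
deferred to export.

# Calibration model

**Variable matrix.** Each linear RGB triple expands to the complete
monomial basis of total degree ≤ 3 — 19 monomials in the fixed order
R, G, B, R², G², B², RG, GB, RB, R³, G³, B³, R²G, R²B, G²R, G²B, B²R, B²G,
RGB — plus a constant term that absorbs the dark current. The cap at third
order avoids over-correction (a near-interpolating fit of sensor noise);
the model itself names only "colour", "non-linear" and "dark" contributions,
and the complete degree-≤3 basis is the canonical reading. In-sample
residual is non-increasing in the order (least-squares nesting), which the
tests assert.

**Fits.** Both regressions are Moore–Penrose least squares:
$C = \mathrm{XYZ}_{\rm ref}\,V^+$ (3×20) and $M = \mathrm{Score}\,V^+$
(6×20). Singular values below $10^{-10}\sigma_{\max}$ are truncated — with
24 samples and 20 terms the design is close to square and this guards
against noise blow-up. Rank deficiency beyond that tolerance logs a warning
and proceeds: the pseudoinverse returns the minimum-norm solution, which is
the right behaviour for duplicated or degenerate patches.

Two points were genuinely open and are resolved as follows:

* **"Score"** is taken to be the matrix of PCA component scores of the
  patch reflectance spectra, because that is the only reading under which
  $M = \mathrm{Score} \cdot \mathrm{pinv}(V_{\rm color})$ yields a spectral
  reconstruction operator. The alternative reading of score as a
  transformation-accuracy similarity measure survives as a diagnostic (the
  per-patch ΔE00 columns of the fit report), not as the regression target.
* **What V is built from.** V is built directly from linear camera RGB for
  both regressions; the corrected XYZ of the first regression feeds
  diagnostics only. Routing corrected XYZ back into the second regression
  would make M depend on C without adding information — both are
  polynomial-in-RGB maps fitted to the same 24 samples.

**PCA basis.** Mean-centred PCA (SVD of the centred wavelength × sample
matrix), components ordered by descending eigenvalue, six retained.
Mean-centring is standard practice and makes the constant offset explicit
in the reconstruction $\hat R = \mu + L (M v)$; whether to centre was
unspecified and is recorded here as a choice. Six components capture
99.99 % of the packaged chart's variance (computed, not assumed — it is an
acceptance check), and reconstruction with all 23 non-trivial components is
exact to $10^{-8}$.

**Evaluation window.** Spectral RMSE and colour-difference diagnostics are
evaluated over 400–700 nm by default (configurable to 380–780). The
red-to-NIR end is the known weak spot of RGB-based reconstruction — three
broad channels carry almost no information beyond 700 nm — so quality
numbers quote the window the calibration actually constrains.

# Band synthesis and weight calibration

Band filters are unit-sum discrete Gaussians. Centres follow the
narrow-band convention (415, 540 nm) plus auxiliary 600, 700, 780 nm bands;
FWHM defaults are 30 nm for the two diagnostic bands — commercial NBI
filters are of that order — and 20 nm for the auxiliary ones. A FWHM at or
below the grid step degenerates to the nearest band slice. The display
mapping (415 → blue and green, 540 and auxiliaries → red) is the Olympus
pseudo-colour convention; the compositing is a weighted sum per channel,
clipped to [0, 1] at the end, and is positively homogeneous in the weights
before clipping.

Weight calibration minimises mean ΔE00 between composited patch colours and
target colours. Two stages are exposed as separate checkpoints, since their
exact hardware counterparts are not delineated: a linear 3×3 least-squares
colour alignment (`matchColorsLinear`), and fast simulated annealing over
the band weights plus a scalar gain on bands intersecting 450–540 nm, the
window where narrow-band hardware shows the largest intensity mismatch.

The annealer proposes $x' = x + \gamma_T\,\mathrm{Cauchy}(0,1)$ per
coordinate with $\gamma_T = \gamma_0 T$, accepts by Metropolis
$\exp(-\Delta/T)$, and cools multiplicatively. The model prescribes only
the Cauchy–Lorentz visiting distribution; the schedule is a package choice:
$T_0 = 1$, cooling 0.95 per 20-iteration block, $\gamma_0 = 0.5$, 2000
iterations. With these defaults the final proposal scale is
$\sim 3\times10^{-3}$, fine enough to settle a quadratic minimum to better
than 0.05 (a test, averaged over five seeds). At $T = 0$ the rule reduces
to greedy descent; the best-so-far trace is non-increasing by construction
and bitwise reproducible given the seed. Box constraints clamp weights to
$[10^{-6}, 10]$.

One identifiability caveat, deliberately left as is: the three auxiliary
bands all feed display red, and over smooth reflectances their responses
are strongly collinear, so only their weighted sum is well determined.
Recovery tests for hidden ground-truth weights therefore use a three-band
set with disjoint display channels; with the full five-band set the
*objective* is reliably minimised but individual red weights are not
unique.

# The synthetic bench

No measured chart spectra, camera images or spectrometer data ship with the
package; the synthetic module generates every input with known ground
truth, and is first-class tested code.

* **Reference chart** (`makeReferenceChecker`): 24 smooth reflectance
  spectra whose D65 colours match the classic chart's nominal sRGB values.
  Chromatic patches are spectrally upsampled into a fixed smooth basis
  (constant + 5 Gaussian bumps, σ = 55 nm, centres 420–700 nm) by
  minimum-norm inversion of the XYZ operator; the six neutrals are exactly
  flat. Real paint reflectances are smooth and close to a low-dimensional
  subspace — that compressibility is the property the construction
  emulates, and the reference XYZ is recomputed from the final clipped
  spectra so chart colours and spectra are exactly consistent. The set is
  synthetic and labelled as such; it reproduces the *structure* of a
  measured chart, not any physical chart's spectra.
* **Virtual camera** (`virtualCamera`): Gaussian sensitivities peaking at
  600/550/460 nm (σ 45/40/30 nm), exposure-normalised so a perfect
  reflector reads 1.0; gamma 1.05 and dark level 0.002 applied before
  seeded Gaussian readout noise (σ default 0.002). The mild nonlinearity
  and dark term exist precisely so the third-order variable matrix has
  real work to do.
* **Virtual spectrometer**: truth plus seeded Gaussian noise, clipped at
  zero.
* **Lesion scenes** (`makeLesionScene`): Beer–Lambert attenuation of a
  smooth skin base by hemoglobin-like absorption (Gaussian bumps at 415 and
  540 nm) everywhere, plus melanin-like monotone-decreasing absorption
  inside a central disk, with optional log-normal texture. The chromophore
  curves are smooth parametric stand-ins, not literature extinction
  tables — sufficient to give the 415 nm band its diagnostic contrast, and
  clearly synthetic.

What passing tests show: the calibration machinery recovers models inside
its own class exactly, degrades monotonically with instrument noise, and at
realistic noise reaches the quality regime reported for physical rigs; the
synthesis stage provably increases lesion contrast over the white-light
rendering *for this absorption model*. What they do not show: performance
on real skin (no spatial chromophore heterogeneity, specular highlights,
shading or demosaicing), calibration transfer across cameras, or behaviour
beyond 700 nm where the reconstruction is unconstrained.

# Numerical and degenerate-input conventions

* Reflectance is validated to [0, 1.2] (fluorescent overshoot tolerated);
  reconstructed cubes to [−0.1, 1.3], clipped to [0, 1] only on export.
  Reconstructed spectra are clipped at zero before any colorimetry.
* sRGB decoding happens exactly once at image ingest; images carry a
  `linear` attribute so double decoding is detectable. Calibration and
  synthesis operate in linear light throughout.
* Saturated pixels (any channel ≥ 0.999) are flagged in a mask and still
  converted.
* Degenerate annealing targets (all patch colours identical) warn and
  proceed; a constant objective accepts every proposal and returns the
  initial value.
* ENVI cubes are float32 BSQ; the pipeline re-reads every artifact it
  writes so cached and fresh runs produce bit-identical metrics.

# Problem sizes and seeds

All experiments are desk-scale by design: 24 calibration patches on a
401-point grid, lesion scenes of 20–48 px square in the tests and demo
pipeline, 2000 annealing iterations. The full test suite runs in a few
seconds; the acceptance script in under two. Every stochastic operation
takes an explicit seed; the calibration bench records 20240714 as its
provenance default, and generators are bit-reproducible given (parameters,
seed).

# Known limitations

* Reconstruction beyond 700 nm is an extrapolation of the PCA basis, not a
  measurement; the 780 nm auxiliary band inherits this.
* The analytic CMFs limit absolute colorimetric accuracy to ~1–2 % of peak;
  swap in tabulated data if absolute XYZ against external instruments is
  required.
* Calibration assumes the scene shares the calibration illuminant and
  camera state; no chromatic adaptation or multi-illuminant support.
* No RAW/Bayer decoding, PSF simulation, or radiative-transfer skin model;
  the lesion generator is a contrast test bed, not a tissue model.
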