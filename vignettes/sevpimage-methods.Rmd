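---
title: "Single-sEVP high-content imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sEVP high-content imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevpimage)
```

## The measurement problem

Small extracellular vesicles and nanoparticles (sEVPs, 30–200 nm) are far
below the diffraction limit, so in total internal reflection fluorescence
(TIRF) microscopy each surface-anchored particle appears as a
diffraction-limited bright spot whose *integrated* intensity — not its
apparent size — carries the quantitative information. With three spectrally
separated labels targeting the lipid membrane plane (the conjugated
oligoelectrolyte COE), the luminal cargo (CFSE) and a surface tetraspanin
(CD63, via dye-labelled antibodies), every particle yields three positivity
calls and three intensities. `sevpimage` turns fields of such spots into:

* a seven-class subpopulation assignment — COE⁺ particles are vesicular
  sEVs, COE⁻ are non-vesicular NPs, and CFSE/CD63 positivity subdivides each
  branch (the all-negative class is invisible by construction);
* molecule counts for the antibody channel, calibrated against the
  single-fluorophore intensity distribution;
* heterogeneity statistics: subpopulation (Venn) fractions with
  between-ROI standard errors, pairwise marker correlations, a relative
  size proxy, the between-subpopulation normalized-intensity variance, and
  Welch tests between samples.

## Image model and preprocessing

A channel image is modelled as
`ADU = gain(x) × Poisson(signal + background) + N(0, σ_read²)`,
with a smooth multiplicative `gain(x)` from uneven illumination. Two
corrections run per channel, in this order:

1. **Flat-field** — the illumination profile is estimated as a wide
   Gaussian blur (radius 30 px = 7.5 µm at the 0.25 µm/px scale) of the
   image after a small grey-scale opening (3 px radius) that removes
   diffraction-limited spots from the estimate, and divided out after
   normalizing to its mean. Division, not subtraction: uneven excitation
   scales emitted intensity multiplicatively, and downstream molecule
   counting needs spot intensities comparable across the field. The small
   opening also makes the operation idempotent in practice — without it the
   spots themselves dent the gain estimate.
2. **Rolling ball** — diffuse background is the grey-scale opening of the
   intensity surface by a paraboloid with the apex curvature of a ball of
   radius 50 px (12.5 µm), computed exactly by separable sliding-parabola
   envelopes with replicated edges. Spots (a few pixels wide) are far above
   the ball's curvature limit and survive; smooth background is removed
   completely. Near the border (within one ball radius) a steeply rising
   background can be undercut — the classic limitation of the algorithm —
   and at the boundary period of exactly four ball radii a sinusoidal
   background retains roughly 16 % amplitude at the image edge while the
   interior is exact.

The order matters and is covered by a regression test: removing background
first and flattening afterwards leaves spot intensities scaled by the local
gain.

## Detection

Detection follows the ComDet-style band-pass convention: the image is
convolved with a Gaussian-smoothed Mexican-hat (equivalently one
Laplacian-of-Gaussian at σ = 1 px for the 2-px kernel), and connected
regions above `k_sd × SD` of the filtered image with area ≥ 3 px become
spots; `k_sd` defaults to 3.5, inside the conventional 3–4 band.

**What "SD" means is the one place this package deliberately departs from
the plain reading.** The plain standard deviation of a filtered image that
contains bright particles is dominated by the particles themselves — on
realistic scenes it sits 2–20× above the noise floor, so a 3.5 × SD
threshold silently discards the dim half of the population (dim here still
means tens of σ above pixel noise). Since single-antibody calibration and
low-copy particles must survive detection for the method to work at all,
the threshold scale defaults to the robust MAD-based SD, which tracks the
noise floor regardless of the particle load; `robust_sd = FALSE` restores
the plain estimator.

Photometry: centroids are intensity-weighted on the preprocessed image;
integrated intensity is summed over the footprint dilated by 2 px (the
threshold truncates PSF tails at roughly the 85–95 % level, so the plain
footprint sum would be biased low), minus the median of a 2-px background
ring starting 2 px outside the footprint, times the aperture area.
Overlapping apertures of nearby spots are partitioned by intensity-guided
propagation so no pixel is counted twice.

Two cleanup stages mirror what practitioners do by hand. *String
segmentation* splits above-threshold regions containing ≥ 2 local maxima
(each above threshold, ≥ 2 px apart) along watershed lines; total intensity
is conserved across the split because the partition is of the measurement
aperture itself. *Aggregate flagging* marks spots that are simultaneously
large (> 50 px), circular (4πA/P² > 0.8) and in the extreme intensity tail
(above the 0.999 quantile of the normally-sized spots); flagged spots are
excluded from every population statistic and the flagged fraction is
reported, since in real preparations such aggregates are a few percent of
particles in the affected samples.

## Colocalization and categorization

The default mode reproduces the composite-image procedure: channels are
each rescaled by their own filtered-image (robust) SD, merged by pixel-wise
maximum, and detected once. A channel is positive at a composite spot when
its band-filtered response summed over the footprint strictly exceeds
`k_sd × SD_c × sqrt(S(A))`, where `S(A)` is the variance multiplier of a
sum of band-filtered noise over an `A`-pixel footprint, computed exactly
from the kernel autocorrelation (band-pass filtering correlates
neighbouring pixels, so `S(A) ≠ A`). A channel exactly at threshold counts
negative — a conservative, deterministic tie-break. A secondary mode
detects per channel and greedily matches spots across channels within 2 px
(all candidate pairs in ascending distance order, each spot used once); it
exists as a cross-check and agrees with composite mode on ≥ 95 % of
particles on well-separated fields.

Chromatic offset is assumed ≤ 1 px and not corrected; a constant
per-channel shift can be configured.

## Molecule counting

The single-fluorophore ("single-CD63") intensity is the peak of a Gaussian
fitted to the intensity histogram (Freedman–Diaconis bins) of isolated
antibodies imaged without particles. The fit is restricted to bins within
0.5–1.5× the modal bin so dimer contamination at twice the unit intensity
cannot drag the peak; fits where μ₁ ≤ 2σ₁ are refused as indistinguishable
from zero. Copy numbers then come two ways:

* **Ratio** — `count = intensity / μ₁`, kept real-valued (the count
  histogram is the intensity histogram with a rescaled abscissa; rounding
  would discard information).
* **Deconvolution** — the intensity density is modelled as
  `Σ_n w_n N(n μ₁, n σ₁²)` (the closed-form n-fold convolution of the
  unit Gaussian, rather than numerical self-convolution), and the weights
  are estimated by non-negative least squares on the binned histogram with
  the sum-to-one constraint enforced and a 10⁻⁶ ridge for conditioning;
  `n_max` defaults to 100. The two estimators agree within 15 % on
  unimodal inputs; σ₁ > μ₁ is reported as ill-conditioned.

No background-count subtraction is applied: non-specifically adsorbed
antibodies on a well-passivated, well-washed surface are treated as
negligible relative to particle-bound ones.

## Heterogeneity statistics

Venn fractions pool particles over ROIs for the point estimate and report
the SD of per-ROI fractions over √(#ROIs) as the error bar. Pairwise
correlations are Pearson on the double-positive particles of a
subpopulation; with `log = TRUE` they are computed on log intensities,
which under the generator's log-normal model estimates the latent copula
correlation directly (the Pearson correlation of the intensities
themselves is attenuated by the log-normal transform — about 0.77 for a
latent 0.8 at geometric SD 1.8 — which is worth knowing when comparing
scatter plots across packages). The normalized-intensity variance of a
marker is the population variance of per-subpopulation means divided by
their grand mean (max-normalization is available); it is exactly invariant
to global rescaling. Group comparisons use Welch's two-sample t-test on
trial-level summaries with conventional stars — Welch is the robust
default for small numbers of trials with unequal variances, and the choice
is a package convention. The capture arithmetic
`f = density × area / (concentration × volume)` and the acquisition tiling
`ceil(chip / field)` are provided as checked unit conversions; `f > 1`
warns of a mass-balance violation.

## The synthetic scene generator

Every stage is validated against `generate_scene()`, which emulates: a
Poisson number of particles (density × area) at uniform sub-pixel
positions; categories from the seven-class mixture; log-normal COE/CFSE
intensities coupled through a latent Gaussian copula; CD63 intensities
built as sums of per-antibody truncated-normal draws over a zero-truncated
Poisson copy number, so counting stages have exact integer ground truth;
an isotropic Gaussian PSF whose per-pixel integrals are exact
(`pnorm` differences); a linear illumination ramp; Poisson shot noise on
signal plus background and additive Gaussian read noise. All randomness
flows from one integer seed, and identical parameters give bit-identical
images and truth tables.

Default study conditions, chosen once as representative values rather
than fits to any particular instrument: 0.25 µm/px; PSF σ = 1 px (a 2-px spot); background
100 ADU; read noise 3 ADU; COE/CFSE log-normal with medians 9000/8000 ADU
and geometric SD 1.8, so each channel spans roughly an order of magnitude,
as real per-particle intensity histograms do; CD63 copies zero-truncated
Poisson(10) at 1000 ± 150 ADU per antibody, putting all three channels on
a comparable 10³–10⁴ ADU scale; latent COE–CFSE correlation 0.8 (membrane
area and luminal cargo both track particle size); density 0.05/µm².
Real acquisitions sit at 0.12–0.36 particles/µm²; the generator's default
is kept below that so that ground-truth evaluation is not dominated by
unresolvable sub-PSF particle pairs, and validation suites state their
densities explicitly.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: EM-CCD excess noise (the gain register
roughly doubles shot-noise variance), spectral cross-talk and chromatic
offsets between channels, non-specific surface binding, photobleaching
within an exposure, and aggregate morphology beyond bright discs. The
detection and categorization accuracies measured here are therefore upper
bounds for matched real conditions.

## Validation suites and problem sizes

The bundled tests run the whole stack at sizes chosen to give stable
statistics: detection precision/recall on 100 fields of 25 × 25 µm at
0.05 spots/µm² with spot intensities 800 ± 150 ADU (peak SNR ≈ 12 ± 2);
7-way categorization on ~2000 imaged particles across nine 75 × 75 µm
fields; Venn recovery on 10 ROIs × ~2000 particles against binomial
sampling error; copy-number recovery at λ = 10 with 20 % unit CV;
two-component deconvolution on 10⁴ draws with a grid-search oracle for the
NNLS solver; correlation recovery at n ≥ 2000 pairs; 10⁴ null replicates
for the Welch type-I rate; and byte-identical re-runs for determinism.

## Numerical and design notes

* Pixel coordinates are 0-based, `(x, y) = (column, row)`, pixel centres at
  integers, footprints half-open; centroids are continuous.
* Spots within one PSF σ of the border are rendered and flagged in truth;
  the detector excludes a 4-px margin, and both sides of every
  truth-versus-detection comparison apply the same exclusion.
* The greedy matcher and the evaluation matcher resolve ties by ascending
  distance; at equal distance, earlier spot index wins — deterministic
  across platforms.
* `venn_fractions` of pooled ROIs equals the particle-weighted mean of
  per-ROI fractions exactly; the SE is between-ROI, which is what error
  bars across selected regions mean.
* The calibration fit falls back to windowed moments when fewer than four
  histogram bins cover the dominant mode (e.g. near-degenerate σ).
* Known limitations: no sub-PSF pair resolution (< 2 px separations merge);
  no spectral unmixing; no absolute sizing (the size proxy is relative);
  captured fractions depend on externally measured bulk concentrations.
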