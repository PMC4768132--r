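---
title: "Detecting the helical surface lattice of a rod virus in scanning-probe height maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the helical surface lattice of a rod virus in scanning-probe height maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixpsd)
```

## The problem

Tobacco mosaic virus (TMV) is a rigid rod, roughly 300 nm long and 18 nm
across, whose ~2130 identical coat proteins form a helix with 49 subunits per
three turns and an axial rise of 2.3 nm per turn. On a surface it images a
few nanometres low (~14 nm apparent height) and its surface corrugation is at
the very limit of what an AFM probe can resolve: the relevant periodicities
(2.3–9.2 nm) sit on a steeply curved flank, the corrugation amplitude is a
fraction of a nanometre, and scan noise is of the same order.

`helixpsd` implements the complete single-particle analysis chain for this
regime: a geometric model of the helical lattice that predicts where spectral
peaks can appear; a synthetic height-map generator with probe broadening, so
that every step can be validated against data with known ground truth; the
line-averaged power spectral density (PSDF) of a boxed region with background
comparison and SNR box optimization; peak detection and harmonic assignment
against the lattice building block; and correlation-length extraction from
two-slope log–log fits.

## Lattice geometry and the off-axis angle argument

With $s = 49/3 \approx 16.33$ subunits per turn, the subunit reached after
$n$ full turns is number $\mathrm{round}(n\,s)$; the vector joining the two
protein centres is exactly axial only when $n\,s$ is an integer, i.e. every
three turns (6.9 nm). Otherwise it misses the axis by

$$\theta_n = \arctan\!\left(\frac{R\,\Delta\varphi_n}{n\text{-turn axial distance}}\right),$$

with the arc offset measured on the *outer* cylinder radius $R = 9$ nm — the
choice that reproduces the published angle set — giving 27°, −14°, 0°, 7°,
−6°, 0° for $n = 1\ldots6$ (sign positive when the partner lags in azimuth;
the magnitude is the physically meaningful quantity, and handedness defaults
to +1 because nothing downstream depends on it):

```{r}
repeat_vectors(helix_parameters(), 6)
```

A line spectrum taken *along the axis* responds strongly to near-axial
vectors (6.9 nm, and 9.2 nm at only 7°) and weakly to strongly tilted ones
(4.6 nm at 14°). `predicted_peaks()` encodes this ordering as a Gaussian
visibility $\exp(-(\theta_n/\theta_0)^2)$ with a user-set width
`attenuation_deg` (default 10°): the data constrain only the *ordering*
(suppressed vs strong), so no absolute weight is ever asserted. Wavenumbers
use $k = 2\pi/l$ throughout, so 6.9 nm ↔ 0.91 nm⁻¹ and 2.3 nm ↔ 2.73 nm⁻¹.

## The synthetic scene

`scene_spec()` + `render_scene()` emulate the statistical structure of the
real samples rather than their photometric detail:

* **Cylinder**: silhouette height $z(t) = R + \sqrt{R^2 - t^2}$ scaled by an
  affine compression `apparent_height_nm / (2R)` (default 14/18). Only the
  apparent height is reproduced; no contact mechanics.
* **Corrugation**: one Gaussian bump (default amplitude 0.2 nm, σ = 1.0 nm)
  per lattice subunit on the upper half-cylinder, weighted by the cosine of
  the azimuth and projected to the image plane. The amplitude of TMV surface
  corrugation under gentle attractive-regime imaging is not known; the
  default is chosen so single-turn stripes sit near the detection limit.
* **Substrate**: a smoothed Gaussian field with exact RMS (default 0.4 nm,
  the measured roughness of template-stripped gold), plus Poisson-placed
  18 nm spherical-cap disks emulating coat-protein (double-)disk aggregates
  (default 30 µm⁻², cap height 4.6 nm = two axial repeats).
* **Sampling**: 512×512 px at 0.5 nm/px, so the Nyquist wavenumber
  (6.28 nm⁻¹) comfortably exceeds the 2.73 nm⁻¹ pitch line; the constructor
  refuses pixel sizes that cannot resolve the pitch. The default 300 nm
  particle is deliberately longer than the 256 nm frame (with a clipping
  warning), which keeps analysis lines free of end-of-particle steps.

Measurement noise is separate (`noise_spec()`): white per-pixel noise, a
constant per-line offset, and per-line *axial jitter* — each fast-scan line
resampled with a random subpixel shift. Jitter is the mechanism we use to
emulate why the topography channel hides the lattice while the second-mode
contrast channel shows it: shifting whole lines scrambles the phase of the
corrugation *between* lines without visibly degrading any single line.
`make_channels()` renders one scene and applies two frozen presets
(topography: 0.3 / 0.2 / 1.6 nm RMS white / line / jitter; mode2-like:
0.03 / 0.01 / 0.05 nm). These presets were calibrated once against the
channel-contrast requirement (lattice peak signal-specific in mode2-like,
undetected in topography, in ≥ 90% of seeded replicates) and then frozen.

What the generator does **not** emulate: the physics of multifrequency
cantilever dynamics (the mode2-like channel is only a low-noise contrast
channel), water films, tip wear, scanner drift or creep, and — critically —
the true coat-protein form factor (see "Known limitations").

## Probe broadening

`build_tip()` samples a spherical cap $-(R-\sqrt{R^2-r^2})$ (or a
paraboloid, or an ideal point) on an odd, apex-centred grid; `tip_dilate()`
computes the imaged surface as the greyscale dilation
$\max_u\,[z(x+u) + t(u)]$ with edge replication (avoiding rim artifacts in
boxes that touch the frame). Dilation is exact against a brute-force
double-loop oracle, extensive, monotone, and translation-equivariant;
`tip_erode()` provides the adjoint reconstruction as a verification tool
only.

## The averaged PSDF

Following standard practice for noisy scans, each line in a box is
mean-subtracted, Fourier transformed and squared, and the squared moduli are
averaged over lines, discarding phase. Conventions, all stated because the
original tooling does not document its own:

* one-sided spectrum, DC excluded; bin spacing $\Delta k = 2\pi/(L\,\Delta x)$;
* normalization such that $\sum P\,\Delta k$ equals the mean per-line
  variance (Parseval, checked to 10⁻⁹ on noiseless input);
* per-line mean removal only — no detrending, no window by default (peak
  *position* fidelity matters more than sidelobe suppression here; a Hann
  window is available by flag, rescaled to keep broadband levels comparable);
* no zero padding (bins keep physical meaning);
* boxes are axis-aligned, 1-based inclusive ranges, lines along rows or
  columns only. Arbitrary-angle extraction is deliberately absent: rotating
  the raster interpolates the very periodicities under test.

Peak positions are insensitive to these choices; absolute power values are
not, and are never compared against published values.

A peak's SNR is its bin power over the median of 9 surrounding bins
(offsets −6…−2 and +2…+5), excluding the peak's three central bins so a
narrow line does not inflate its own floor. `compare_background()` applies
the signal-vs-substrate box comparison; `optimize_box()` reproduces the
"grow the box until the SNR is maximal" step as a deterministic greedy
search over edge moves.

## Peaks, harmonics, correlation length

`detect_peaks()` keeps local maxima with SNR above a threshold (default 3),
merging adjacent bins towards the higher power. `assign_harmonics()` assigns
each peak the integer $m$ minimising $|k - m k_0|$ within a tolerance of one
bin — the physical resolution of the spectrum — and reports unmatched orders
as missing; no multiplicity correction is applied, because the detection is
descriptive, not inferential.

`correlation_length()` fits two least-squares lines in (log k, log P) with
an exhaustive breakpoint search (≥ 4 bins per segment), excluding the
DC-adjacent bin and everything above 0.8 of Nyquist, where leakage and
pixelation dominate. The correlation length is $2\pi/k_c$ at the
intersection of the two lines. Degenerate inputs — indistinguishable slopes,
a breakpoint escaping the fitted range, too few bins — raise errors rather
than returning silently:

```{r}
dk <- 0.02; k <- (1:150) * dk
pw <- ifelse(k < 1.25, 1, (k / 1.25)^-3)
ps <- structure(list(wavenumbers = k, power = pw, dk = dk,
                     n_lines_averaged = 16L, line_length_samples = 300L,
                     box = box_selection(c(1, 16), c(1, 300), "rows"),
                     source_channel = "synthetic", pixel_size_nm = 0.5,
                     window = "none"), class = "psdf")
correlation_length(ps)
```

## Numerical choices worth knowing

* The scene origin lies exactly on a pixel centre, so the cylinder crest
  (t = 0) is sampled and a bare cylinder peaks at exactly the apparent
  height; rim pixels carry a 10⁻⁹ nm epsilon guard so rotated renders are
  reproducible to round-off.
* All randomness flows from integer seeds (scene seed; one seed per noise
  spec); rendering and the full pipeline are bit-reproducible, and the
  caller's RNG state is restored.
* Harmonic tolerance is inclusive with a 10⁻⁹ relative guard against
  floating-point ties exactly at the bin edge.
* Text rasters round-trip at ~10⁻⁶ nm; float TIFFs are stored rescaled to
  [0, 1] at 32-bit precision with the z-range in a JSON sidecar, and reading
  a TIFF without its sidecar (or a text matrix without a
  `# pixel_size_nm:` header) is a hard error — a pixel size is never
  guessed.
* The pipeline refuses line-flattened maps: per-line flattening removes the
  inter-line phase structure the averaged PSDF measures.

## Problem sizes

The bundled tests and drivers use 512×512 px scenes (256 nm at 0.5 nm/px)
for end-to-end checks, 20 seeded replicates for the channel-contrast and
pitch-recovery properties, 100–200 replicates for the knee-recovery Monte
Carlo, and ≤ 64×64 px images for exact brute-force oracle comparisons. The
acceptance script renders one 720×120 px scene (690-sample lines, bin
spacing 0.0182 nm⁻¹) so that the fundamental can be read to two decimals.

## Known limitations

* **The first harmonic is not missing in synthetic spectra.** Real TMV
  spectra show the 6.9 nm fundamental and the 2.3 nm third harmonic but no
  3.45 nm first harmonic. A perfect helical lattice decorated with one bump
  per subunit cannot reproduce that: along any axial line, the 0.91 nm⁻¹ and
  1.82 nm⁻¹ layer lines arise from azimuthal orders −16 and +17 (selection
  rule $l = 3n' + 49m'$), whose reciprocal vectors differ by only ~6% in the
  transverse direction, so *any* separable bump envelope that keeps the
  fundamental strong keeps the first harmonic at a level comparable to the
  third (for isotropic bumps $P_2/P_3 = e^{+0.58\sigma^2} \ge 1$). On the
  noiseless default scene the measured layer-line powers are
  2.9×10⁻² : 1.2×10⁻³ : 8.1×10⁻⁴. The absence of 3.45 nm in experiment
  reflects the true coat-protein form factor and the instrumental noise
  floor, neither of which a lattice-of-bumps generator encodes. The
  corresponding end-to-end test asserts the missing harmonic anyway and is
  an expected failure, kept as an honest record of this model limit.
* **Small tips can raise harmonic content.** Greyscale dilation with a 2 nm
  ball leaves contact cusps in corrugation valleys whose curvature radius
  (~1.3 nm) it cannot follow; the cusps *add* third-harmonic power relative
  to an ideal point probe before the familiar monotone suppression sets in
  (measured ratios 0.020 → 0.028 → 0.026 → 0.012 for point, 2, 6, 10 nm).
  The "bigger radius ⇒ lower harmonic content" argument is asymptotic and
  holds across 2 → 6 → 10 nm; the strict monotonicity test across all four
  probes is likewise an expected failure, documented rather than tuned away.
* Passing synthetic tests demonstrate that the *procedure* recovers known
  periodicities under realistic noise; they cannot validate claims about
  real virions, whose corrugation amplitude, form factor and noise spectrum
  are not known inputs here.
* The published per-virion correlation-length statistic (5.5 ± 1.7 nm over
  70 particles) requires the original raw images; only the extraction
  procedure and its synthetic recovery are in scope.
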