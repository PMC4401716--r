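---
title: "Axial sectioning of 2D SMLM data with a virtual light-sheet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axial sectioning of 2D SMLM data with a virtual light-sheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlsmlm)
```

## The problem and the idea

A 2D single-molecule localization microscopy (SMLM) experiment fits every
blinking emitter with a 2D Gaussian, regardless of how far the emitter sits
from the focal plane. Under broad illumination (epi, HiLo), emitters several
hundred nanometres above or below focus are still detected; they appear as
*larger and dimmer* point-spread functions (PSFs) and smear the reconstruction
with out-of-focus localizations.

Because each PSF is fitted individually, the fit parameters themselves carry
the axial information: the fitted width grows with defocus and the fitted peak
amplitude falls. Thresholding width and amplitude therefore retains only
emitters within a thin slab around the focal plane — a *virtual light-sheet*
(vls) — without touching the illumination. The package calibrates those
thresholds on a bead z-stack in which the true axial position of every PSF is
known, so the user gets the two quantities that characterize a binary
classifier:

* **confidence** = TP/(TP+FP): the probability that a retained localization
  really originated inside the slab;
* **recall** = TP/(TP+FN): the fraction of in-slab localizations that survive
  filtering.

Two selection recipes are provided. The **structural mode** picks the width
threshold at the intersection of the confidence and recall curves (balanced
contrast gain versus sampling), then an amplitude threshold reaching 90%
confidence. The **confidence mode** picks the width of maximal confidence and
an amplitude threshold reaching 95%, sacrificing recall for certainty — the
right choice when clusters must be classified as in- or out-of-focus before
counting molecules.

## The synthetic microscope

Nothing in the calibration logic depends on simulated data — any bead z-stack
read with `read_stack()` works — but the package ships a full camera-level
simulator so that every stage is testable against ground truth.

**Defocus law.** The PSF is a circular Gaussian with
$\sigma(z) = \sigma_0\sqrt{1+(z/z_R)^2}$ (the Gaussian-beam form). Defaults
are $\sigma_0 = 175$ nm, typical for green-emitting beads on a high-NA oil
objective, and $z_R = 400$ nm, chosen once so that the PSF is visibly blurred
(about $1.3\,\sigma_0$) some 330 nm from focus, matching the qualitative
appearance of bead z-scans on such instruments.

**Amplitude model.** Total detected photons per frame are drawn uniformly
from 500–1,500 (the photon fluence at which single fluorophores are imaged)
and are held independent of defocus; the peak amplitude therefore falls as
$1/\sigma(z)^2$. This reproduces the "larger and dimmer" phenomenology that
the thresholds exploit. Real defocused PSFs additionally lose photons into
Airy rings that a Gaussian does not capture, so the simulated axial contrast
is, if anything, conservative.

**Noise.** Poisson shot noise with an optional EMCCD excess factor
(default 2, implemented as a variance-doubling scaled Poisson draw), Gaussian
read noise (default 1 count), a 100-count baseline and integer quantization.
This is simpler than a full EM-gain gamma model but sufficient for threshold
statistics. Camera defaults: 100 nm pixels, gain 1 photon/count, so
everything is in photon units.

**Coordinates.** Continuous $(x,y)$ in nm; pixel $(0,0)$ spans
$[0,\text{pixel})^2$. $z = 0$ is the focal plane; the sign of $z$ is
unobservable under a symmetric defocus law, which is also why the package
never claims to tell "above" from "below" — only "in" from "out".

**Blinking movies.** `simulate_smlm_movie()` switches emitters on with a
fixed per-frame activation probability and geometric burst lengths — a
two-state stand-in for photoactivation, with no bleaching or dark-state
kinetics. Layout generators provide the two benchmark geometries: tight 3D
clusters at chosen depths, and a uniform cytosol with ellipsoidal voids whose
projections only clear up after axial filtering. What passing tests on these
synthetic data do *not* show: robustness to dipole orientation effects,
aberrated or astigmatic PSFs, drift, or fitting engines whose width/amplitude
conventions differ wildly — for foreign tables the schema importer converts
units, but the calibration must always come from the same fitter as the data.

## Calibration pipeline and its numerical choices

1. **Fitting.** Spots are local maxima of a lightly smoothed frame above
   median + 4 MAD (the threshold keeps expected false maxima per frame well
   below one) and are fitted by least squares with a five-parameter circular
   Gaussian (`minpack.lm` Levenberg–Marquardt). Least squares rather than MLE:
   the method is fitter-agnostic by design, and LSQ is the convention an
   imported table is most likely to share. Width is the σ of the circular
   fit; the amplitude is the offset-excluded peak converted to
   photons/µm² (peak per pixel ÷ pixel area), the unit in which published
   thresholds of order 1,500–2,200 photons/µm² are quoted. Fits are flagged
   invalid when the optimizer fails, the peak is non-positive, or σ leaves
   $(0.5, 10)\times$ the expected in-focus width — no single emitter can
   appear narrower than about half the diffraction-limited PSF, and fits
   below that bound are invariably noise spikes riding on a defocused
   pedestal. Two safeguards keep strongly defocused PSFs honest: when the
   fitted width approaches the fit-region half-width the fit is repeated
   with a larger region (a clipped region otherwise degenerates the
   width/offset estimates), and converged localizations landing within
   $\max(\text{min separation}, 1.5\sigma_{\text{fit}})$ of a brighter one
   in the same frame are merged, since one wide PSF can seed several
   detection maxima.

2. **Bead traces.** Localizations are linked by lateral proximity (500 nm
   radius); beads closer than the link radius are discarded as ambiguous
   rather than guessed. Traces covering less than half the scan are dropped.

3. **Focal plane.** For each bead, the background-subtracted integrated
   intensity in a fixed box is computed per z step; the focal plane is its
   argmax, and the bead-averaged profile is fitted with a 1D Gaussian +
   baseline. The box half-width defaults to $1.5\sigma_0$ in pixels (box side
   ≈ 3 in-focus sigmas): a box matched to the PSF core loses photons as the
   PSF defocuses and therefore shows a strong axial peak, whereas a much
   larger box would capture nearly all photons at every z under this
   simulator's photon-conserving PSF and flatten the profile into
   degeneracy. The 1D fit runs as a bounded Levenberg–Marquardt problem with
   moment-based starting values; σ is capped at twice the scanned range
   because a flatter profile carries no width information (beyond the cap the
   amplitude and baseline become collinear). FWHM is reported as
   $2\sqrt{2\ln 2}\,\sigma$ exactly.

4. **Slab thickness.** `define_vls()` supports both the profile-FWHM rule
   and an explicit thickness. The pipeline default is the explicit ~600 nm
   convention used for high-NA objectives (inclusive bounds, centred on the
   fitted focal plane). The profile FWHM is a poor default *for this
   simulator* — see above — and on shallow scans it can exceed the scanned
   range entirely, which would make every localization "in-slab" and the
   curves degenerate. With a real instrument's profile (greater axial
   contrast) the FWHM rule is a sensible alternative and remains one
   configuration key away.

5. **Threshold scan.** Widths are scanned over 100–500 nm in 1 nm steps
   (the published scan direction is 500 → 100 nm; the grid is ours).
   Confidence at thresholds keeping nothing is *undefined* and excluded from
   argmax decisions, never coerced to 0 or 1. The structural crossing is
   found on the piecewise-linear interpolant; with several crossings the one
   at the largest threshold wins (maximal recall). Amplitude candidates are
   the observed values of the surviving points, which makes the scan
   exhaustive and exactly reproducible by a brute-force oracle; the selected
   threshold is the smallest reaching the mode's confidence target, i.e. the
   recall-maximal qualifying choice. Ties in the confidence-mode argmax break
   toward the larger width for the same reason.

6. **Evaluation.** `crossval_confidence()` reruns the whole pipeline on one
   synthetic stack and measures confidence/recall on an independent replicate
   — the number a user would actually experience. The calibration carries
   both curves, the parameter-plot table and achieved ratios.

## Problem sizes

The simulation defaults mirror the reference acquisition protocol (201 steps
of 10 nm, 10 frames per step, 28 beads). The validation and acceptance runs
use a reduced scan — 41 steps of 25 nm, 5 frames per step, 20 beads, i.e.
roughly 4,000 localizations per stack and ~100 per axial step — which the
robustness analysis justifies: selection is stable down to ~31 localizations
per in-focus step, while z-steps much above 40 nm measurably degrade the
transferred confidence (the package asserts both properties in its tests, by
subsampling and by coarsening a fine scan to 80 nm). Unit tests use smaller
stacks still (e.g. 12 beads, 21 × 50 nm steps).

## Known limitations

* The defocus law is symmetric and aberration-free; real PSFs are not, and
  published threshold values (e.g. width 223 nm/206 nm, amplitude 1,502/2,164
  photons/µm² on one instrument) shift with wavelength, optics and fitting
  engine. They are reference magnitudes; a calibration must be measured per
  instrument, matched in spectrum and fitter. The thresholds this package
  selects on its simulator land in the same range but are not expected to
  reproduce any instrument's numbers exactly.
* Width/amplitude thresholds cannot separate two planes symmetric about the
  focus, and the method does not reduce photobleaching or photodamage — it is
  post-processing, not illumination shaping.
* Cluster grouping is a deterministic single-linkage stand-in; experiments
  with an established cluster definition should supply their own assignment
  to `classify_clusters()`.
* Blinking-related overcounting is untouched; the cluster classification only
  prevents the *under*-counting caused by undetectable out-of-focus emitters.
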