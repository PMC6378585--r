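---
title: "parastorm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{parastorm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `parastorm`, the parameters
that matter, the design choices made where several reasonable options
existed, and what the simulation-based tests do and do not demonstrate
about real microscope data.

## The processing model

Single-molecule localization microscopy reconstructs a super-resolved
image in four stages: acquire a long camera time series of sparsely
blinking fluorophores; localize every emitter in every frame; filter and
drift-correct the localization table; render the table as an image.  The
localization stage is the expensive one and is embarrassingly parallel
across frames.  `parastorm` exploits this with an *interleaved* worker
plan: worker $w$ of $W$ processes frames $w, w+W, w+2W, \dots$  Emitter
activity decays over a dSTORM acquisition (photobleaching), so contiguous
frame blocks would hand early workers far more localizations than late
ones; interleaving samples the decay evenly and the per-worker workloads
match to within a few percent.  The merge stage stably re-sorts the
per-worker tables by frame, so for deterministic engines the merged raw
table is *byte-identical* to a single-worker run — this equivalence is the
pipeline's headline correctness property and is asserted in the tests for
all three engines at $W \in \{1, 2, 4, 8\}$.

Workers run as forked processes of a local pool (or serially); a manifest
export writes one YAML job description per worker (input, start frame,
stride, engine) so an external scheduler can execute the same plan.
Outputs land in a job-numbered directory: raw and postprocessed CSVs
(ThunderSTORM-compatible dialect), preview images tagged `2D`/`3D`, the
drift graph, and a timestamped human-readable log.

## Localization engines

Spot candidates come from a difference-of-Gaussians band-pass
($\sigma_1 = 1.0$, $\sigma_2 = 1.6$ px — approximating the à-trous
wavelet front ends common in SMLM software) followed by strict
8-neighbour local maxima above $k = 3$ robust standard deviations
($1.4826 \times$ MAD) of the filtered frame.  Ties keep the first
candidate in row-major order; candidates within one ROI radius of the
border are dropped.  The threshold has a numerical floor so noise-free
synthetic frames do not admit floating-point ripple as candidates.  ROIs
(radius 3 px in 2D, 4 px for elliptical 3D spots) are converted to
photons via the camera model
$\text{photons} = (\text{ADU} - \text{baseline}) \times
\text{photons/ADU}$.

All engines operate on the *integrated* Gaussian PSF — per-pixel
error-function integrals rather than a sampled Gaussian — which stays
accurate at $\sigma \approx 1.3$ px:

$$\mu_{ij} = N \, E_i(y_0, \sigma_y) \, E_j(x_0, \sigma_x) + b.$$

* **NWLS** minimizes $\sum_i w_i (y_i - \mu_i)^2$ with
  $w_i = 1/\max(y_i, 1)$ (the floor avoids division by dark pixels).
* **MLE** minimizes the Poisson deviance $\sum_i (\mu_i - y_i \ln \mu_i)$
  with $\mu_i$ floored at $10^{-6}$.

Both use a Levenberg–Marquardt-damped iteration (Gauss–Newton for NWLS,
Fisher scoring for MLE) with analytic Jacobians, a 50-iteration cap and
convergence when the largest relative parameter change drops below
$10^{-6}$.  Divergence — position leaving the patch, width outside
$[0.3, 10]$ px, or $N \le 0$ — flags the fit non-converged rather than
raising an error; non-converged fits are discarded by the frame driver.
On noiseless spots both engines recover the generating parameters to
better than $10^{-3}$ px and the two agree to the same tolerance.

* **Phasor** localization subtracts the patch minimum, takes the first
  Fourier coefficient along each axis, and reads the position from its
  phase; the width proxy $\hat\sigma = (W/\pi)\sqrt{\ln(\Sigma I/|P|)/2}$
  follows from the Fourier magnitude of a Gaussian.  It is non-iterative
  (always "converged", `n_iter = 0`), several-fold faster, and accurate
  to a few hundredths of a pixel on clean spots — the preview-quality
  trade-off.  A patch whose Fourier magnitude exceeds its summed
  intensity is degenerate; the single-bright-pixel limit ($|P| =
  \Sigma I$) is allowed and returns that pixel with a zero-width proxy.

Lateral precision uses the Thompson formula (see `thompsonUncertainty`)
with $\sigma$ the geometric-mean width, $b$ estimated as the standard
deviation of the one-pixel ROI border ring (the formula needs a
background-noise scale and the border ring is background-dominated).
Phasor fits carry no uncertainty, matching the convention that
uncertainty outputs exist only for Gaussian fitting; downstream filters
treat a missing uncertainty as "keep".

## Astigmatic 3D

A cylindrical lens makes the PSF elliptical with z-dependent widths.
Calibration fits the defocus model
$\sigma(z) = \sigma_0\sqrt{1 + ((z - c)/d)^2}$ per axis
(`minpack.lm::nlsLM`, with perturbed-start retries because a perfectly
centred start can present a numerically singular initial gradient).  A
calibration is rejected as degenerate when widths do not vary with z,
when the two focal offsets coincide within 5 nm (no astigmatism to
invert), or when $\sigma_x(z) - \sigma_y(z)$ is not monotonic on the data
range (ambiguous inversion).  z lookup minimizes
$(\sqrt{\sigma_x} - \sqrt{\sigma_{x,cal}(z)})^2 +
 (\sqrt{\sigma_y} - \sqrt{\sigma_{y,cal}(z)})^2$
on a dense 1 nm grid with local parabolic refinement — the $\sqrt\sigma$
metric de-weights the large-width wings; grid-then-parabola is robust to
noisy widths where root finding is not.  Round-trip accuracy on clean
widths is well under 1 nm; out-of-range widths clamp to the boundary with
a large residual.  The axial uncertainty propagates the lateral width
uncertainty through the calibration slope,
$\Delta z = \Delta\sqrt{\sigma}\, /\, |d(\sqrt{\sigma_x} -
\sqrt{\sigma_y})/dz|$, capped at 1000 nm; the 500 nm postprocessing
filter consumes it.  Phasor width proxies can drive the same machinery
via a calibration fitted against phasor widths (`engine_tag = "phasor"`).

## Postprocessing

Steps run in a configurable order (default `minphot, sigma, zunc, drift,
merge`; the order is a package choice — the intercentile window is
computed on the table *as it stands* when the step runs, i.e. after
`minphot` by default):

* `minphot` removes records with fewer than 1 photon (unphysical fits);
  the boundary survives ("less than one" is removed, 1.0 is kept).
* `sigma` keeps widths inside the 10th–75th intercentile range.
  Percentiles interpolate linearly between order statistics at rank
  $p(n-1)$ (`quantile` type 7), the most common convention; bounds are
  inclusive.
* `zunc` removes 3D records with axial uncertainty above 500 nm
  (boundary kept, missing uncertainties kept, 2D tables passed through).
* `drift`: frames are split into 5 equal temporal bins, each rendered as
  a 2D histogram at 1/5 camera-pixel super-resolution, and
  cross-correlated against the first bin by FFT with sub-pixel peak
  refinement by a paraboloid fit on the 3×3 neighbourhood of the
  correlation maximum.  The correlation surface is first smoothed with a
  circular Gaussian of 2 super-pixels: drift *within* a bin smears the
  correlation peak into a broad plateau (~450 nm at 2 nm/frame and
  200-frame bins) whose discrete argmax otherwise jitters by whole
  super-pixels under sampling noise — smoothing restores few-nanometre
  bin estimates without moving the (symmetric) peak.  Bin-centre
  displacements are interpolated
  linearly to per-frame values.  The end segments are *extrapolated
  linearly* (and the trajectory re-referenced so frame 1 is exactly
  zero): with constant end padding, a linear stage drift of
  2 nm/frame would leave ~200 nm of uncorrected motion in the first and
  last tenth of the movie, defeating the correction's purpose; linear
  extrapolation of the end segments removes it.  A drift summary graph
  is saved alongside the table.  Bins with fewer than 10 localizations
  abort with advice to use fewer bins.
* `merge` chains localizations of one emitter across consecutive frames
  (greedy, photon-weighted centroid, 50 nm capture radius, no gap by
  default).  Same-frame records never merge — two spots in one frame are
  two molecules.  Merged records keep the first frame, photon-weighted
  position and width, summed intensity, and a Thompson uncertainty
  recomputed from the merged photon count; the merged axial uncertainty
  is scaled by $\sqrt{N_{max}/N_{total}}$, the same $1/\sqrt{N}$
  precision gain the lateral formula exhibits.

Each step appends a provenance line (`kept a of b`) to the table and the
run log.

## Rendering

`histogram` counts localizations per super-pixel (20 nm default); `ash`
averages $s^2$ histograms whose origins shift by fractions of a
super-pixel (s = 2 default) — mass is conserved exactly in both;
`gaussian` splats each record as a normalized Gaussian (fixed width or
per-record uncertainty) on a grid padded by $4\sigma$ so edge records
keep their mass.  For 3D tables the z projection colours each occupied
super-pixel by the *mean z* of its records, mapped linearly over
−400…+400 nm (clamped), with ASH intensity as brightness; empty pixels
are black.  Scatter-plot rendering is omitted as redundant with these
modes.  Images are written as 32-bit float TIFF plus an 8-bit PNG
preview.

## The simulator and what tests do (and do not) show

`simulationConfig` defaults describe a typical dSTORM regime: 64×64 px
field, 100 nm pixels, $\sigma_{PSF}$ 130 nm, lognormal ~1000 photons per
ON event, 10 background photons/px/frame, baseline 100 ADU at 0.5
photons/ADU, 1.6 e⁻ read noise.  Blinking is a per-frame Bernoulli
($p_{on}$) with permanent bleaching after an ON event ($p_{bleach}$),
which yields the approximately exponential decay of localizations per
frame at rate $p_{on} p_{bleach}$ seen in long acquisitions.  Filament
structures are 3–8 random quadratic Bézier curves sampled every 15 nm
with 10 nm jitter, emulating microtubule images; `grid` placement serves
isolation-controlled validation (e.g. the 3D depth study); `uniform` is
the unstructured control.  Drift is linear at a configurable nm/frame.
Emitter densities in the study movies are kept in the sparse regime the
single-emitter fitting model assumes (roughly ≤ 2 spots per 1000 px² per
frame); at several-fold higher density overlapping PSFs inflate the
robust detection threshold and localization counts saturate, which is a
property of sparse-emitter fitting generally, not of the parallel
scheduling under test.

Study problem sizes: equivalence and precision use a 500-frame 64×64
movie (~1000 matched events); load balancing uses 2000 frames at decay
rate 0.002/frame with Gaussian NWLS (the engine whose workload motivates
interleaving — the phasor engine has no convergence rejection, so the
detector's constant false-positive floor would dilute the block
contrast); drift recovery uses 1000 frames at (2, −1) nm/frame; the 3D
study uses a 36-emitter grid over ±400 nm depth, 300 frames, with the
automated `minphot, sigma, zunc` chain before matching.

The simulator does **not** model triplet/dark-state kinetics or buffer
chemistry, sCMOS pixel-dependent gain/noise maps, axial drift,
time-varying activation power, or multi-emitter overlap fitting.
Passing tests therefore demonstrate the correctness of the scheduling,
merge, estimation and postprocessing machinery under a faithful but
simplified photophysical model — they do not certify performance on any
particular microscope's data, where background structure, aberrations
and density violations dominate.

## Numerical choices and degenerate inputs

* Deterministic arithmetic everywhere: no RNG in detection, fitting,
  merging or rendering; simulation randomness is fully seeded.  CSV
  floats are written as the shortest representation with ≤ 6 significant
  digits, making repeated writes byte-identical (the equivalence checks
  hash files).
* Constant ROIs raise a degenerate-input error at initial estimation;
  pure-background fits return non-converged; the frame driver skips
  both.
* `fitGaussian` treats an inadmissible LM step at exhausted damping
  ($\lambda > 10^8$) as convergence only if the attempted step was below
  tolerance.
* Worker plans reject $W > n_{frames}$ rather than idling workers;
  merges reject overlapping frame sets; trajectories must cover the
  table's frame range.

## Known limitations

High-density data (overlapping PSFs) is out of scope — counts saturate
rather than degrade gracefully.  The drift estimator assumes a rigid
lateral shift between temporal bins; non-rigid or axial drift is not
corrected.  The phasor z path requires a phasor-specific calibration and
is less accurate than Gaussian fitting near the edges of the depth
range.  Batch mode parallelizes across movies but not across nodes of a
real scheduler; the manifest export exists precisely so an external
queueing system can take over worker execution.
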