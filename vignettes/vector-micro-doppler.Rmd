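---
title: "Vector micro-Doppler processing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector micro-Doppler processing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hvmudi)
```

This vignette explains the science implemented by `hvmudi`: the signal
models, the adaptive rules, the tunable parameters and their defaults, what
the phantom simulator does and does not emulate, and the numerical choices
made where the design was genuinely open. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## 1. Signal model

A plane-wave acquisition transmits `NA` tilted wavefronts (tilt angles
θ₁…θ_NA, here −3°…+3° in 1° steps) at pulse repetition frequency
`prf_hz` (3500 Hz), so one compounded frame costs `NA` transmissions and
the effective frame rate is `FR = prf_hz / NA` = 500 Hz. The beamformed
complex IQ data form a 4-D lattice (lateral x, axial z, slow time t,
angle). A scatterer moving with speed `v` in direction θ_D (measured from
the +z axis toward +x; descending flow has a positive axial component)
advances the phase of the angle-θᵢ echo by

    φᵢ = 4π f_c v cos(θ_D + θᵢ) / (c · FR)

per compounded frame, so the per-angle axial velocity is
`v_axial = c · FR · φ / (4π f_c)` and the unambiguous (Nyquist) axial
velocity is `c · FR / (4 f_c)` — 4.8125 mm/s at 40 MHz and 500 Hz. These
two relations are the backbone of both the estimator and the simulator.

## 2. Block-wise adaptive SVD clutter filtering

Tissue echo ("clutter") is typically 20–40 dB stronger than blood but
varies slowly and coherently over space, so in the Casorati matrix
`A` (pixels × frames) of a spatial block it concentrates in the first few
singular components, while noise fills a plateau of small, slowly decaying
singular values. The filter retains orders `T_L…T_H` of `A = U Δ V^H`.

**Selection rules** (the concrete form is a package design decision):

* *Turning point*: the order at which the curvature (discrete second
  difference) of `log10 Δ` first changes sign — the end of the steep
  clutter descent.
* *Noise plateau* `T_H`: the first order where a 5-point moving slope of
  `log10 Δ` exceeds −0.01 per order.
* *Frequency rule* `T_L`: the smallest order at/after the turning point
  whose temporal singular vector has a characteristic Doppler frequency
  above the clutter-band parameter `f_clutter_hz`.
* *Fallbacks*: if no order passes the frequency rule, `(T_L, T_H) =
  (2, N_t)`; if the selected order lies inside the noise plateau and the
  plateau starts at the first order (a pure-noise block), likewise
  `(2, N_t)`; if the plateau starts later (a clutter-only block), the
  selected `T_L` is kept and `T_H` extends to `N_t`, so all clutter
  components stay rejected.

**Why an FFT-based frequency estimator.** The frequency rule must
recognize *blood* components. For flow perpendicular to the beam — the
canonical phantom geometry — the compounded blood signature is spectrally
symmetric (tones at ±f), so the lag-1 autocorrelation *argument* (the
classic mean-Doppler estimator) reads ≈ 0 and would misclassify broadside
blood as clutter. Lag-1 *magnitude*-based spectral-width estimators have
the opposite flaw: on a finite record their readings for slowly varying
components are inflated by edge effects (a deficit of 1 % in `|R₁|/R₀`
already reads as ~11 Hz at FR = 500 Hz). The component criterion therefore
uses the second spectral moment about zero of a Hann-windowed periodogram,
which reads a symmetric pair ±f as f and keeps ~1/T resolution for slow
components. The *cutoff* frequency itself (below) keeps the lag-1 argument
form.

**Recombination.** Blocks of 64 px slide with 90 % overlap; each filtered
block is weighted by a separable Hann taper (strictly positive, so the
pixel-wise weights always normalize to 1) and averaged. This removes the
grid-pattern artifacts of independent block processing. Border blocks are
shifted inward to keep full size. Internally the per-block SVD is computed
from the `N_t × N_t` Gram matrix (`A^H A`), which is exact and avoids
forming `U`; the reconstruction uses `A V_δ V_δ^H`.

**Adaptive cutoff.** The high-pass cutoff for the vector stage is
`FR · |arg Σ_t v[t+1] v*[t]| / 2π` evaluated on the `T_L`-th temporal
singular vector, i.e. the mean Doppler frequency of the slowest retained
component. One global scalar is used (the median over blocks, preferring
blocks where the frequency rule found a flow component), floored at
`f_clutter_hz`: the high-pass never dips inside the declared clutter band.
At broadside the blood component's mean frequency is ≈ 0, so the floor is
what keeps the cutoff meaningful there.

`f_clutter_hz` defaults to 10 Hz for general use. The phantom protocol
passes 2 Hz: a water-tank tube phantom has quasi-static wall echo rather
than physiological tissue motion, and the slowest preset's Doppler content
starts at ~3 Hz.

## 3. Vessel enhancement

The power image `Σ_t |s|²` of the filtered series maps vascular presence.
Two stages suppress the remaining background:

* **Bowler-hat transform**: grayscale openings by disks of radius
  `r = 1…r_max` versus line segments of half-length `r` over `phi_count`
  orientations in [0°, 180°); the output is `max_r (max_φ IL − ID)`,
  clipped at zero. Lines fit inside elongated structures where disks do
  not, so vessels respond and blobs/flat background vanish. Defaults
  `r_max = 30` px, `phi_count` = 12 (15° steps). The line openings are
  computed by shifted minima/maxima rather than 2-D kernel morphology
  (degenerate one-column kernels are handled incorrectly by the kernel
  route; out-of-image pixels are ignored so flat fields stay flat).
* **Hessian vesselness**: Gaussian-derivative Hessians at scales
  σ ∈ {1, 1.5, 2} px (σ²-normalized, kernel half-width 4σ), eigenvalues
  ordered `|λ₂| ≥ |λ₁|`, response
  `exp(−(λ₁/λ₂)²/2β²)(1 − exp(−(λ₁²+λ₂²)/2α²))` when λ₂ < 0, zero
  otherwise (including the λ₂ = 0 flat-field limit), maximized over σ.
  α = 2, β = 1. The input is normalized to unit maximum so the fixed
  sensitivities act on a consistent scale.

**Binarization** keeps pixels within 3 dB of the image maximum
(`I > I_max · 10^(−3/10)`), the reading of a "dynamic range > 3 dB"
threshold that yields a rule from a single number; it is applied to the
final vesselness-weighted image and is configurable. The mask is thinned
(Zhang–Suen) to a one-pixel skeleton; each skeleton pixel's orientation is
the principal axis of its 7×7 skeleton neighborhood.

## 4. Vector Doppler stage

Per angle and per pixel, the raw (not SVD-filtered) slow-time series is
high-passed with a fifth-order Butterworth at the adaptive cutoff,
zero-phase (forward–backward), so no group delay biases the subsequent
lag-1 phase.

**Finite-record transients.** At cutoffs of a few hertz, the filter's
settling time rivals the 0.4 s record (a 2 Hz fifth-order high-pass
settles over ~130 of 200 frames), and padding cannot absorb the edge
transients — note that any reflection-type extension maps a complex tone
e^{jωt} to its negative frequency, so the junction discontinuity is of
order of the signal itself. The transients are linear combinations of the
filter's homogeneous modes, which are known a priori from its poles; after
filtering (with maximal odd-extension padding and exact steady-state
initial conditions), the package projects out the modes of every pole
whose settling exceeds a third of the record, anchored at either record
end. Closed-form tone checks in the test suite verify per-frame phase
increments within 1 % down to a few hertz.

**Phase and solve.** The inter-frame phase is
`arg Σ_t s[t+1] s*[t]` over a temporal window — 10 frames (20 ms) sliding
with unit stride for time-resolved output, or one full-record window for
steady flow (the phantom protocol). Converting each angle's phase by the
Doppler equation gives `v_axial(θᵢ) = a cos θᵢ − b sin θᵢ` with
`a = v cos θ_D`, `b = v sin θ_D`; `(a, b)` are solved per voxel by least
squares, `v = √(a²+b²)`, `θ_D = atan2(b, a)`.

With a ±3° angular span the design matrix is strongly anisotropic
(`Σ sin² θᵢ ≈ 0.0085`), so equation noise on the sine column is amplified
~11×. Two measures keep the solve stable:

* columns are normalized before the unweighted solve, and voxels failing a
  condition bound (10⁶) are flagged invalid;
* the pipeline weights each angle's equation by its lag-1 autocorrelation
  magnitude (coherent-power weighting, standard in ensemble
  autocorrelation velocimetry). At broadside the center angle's Doppler
  line is always ≈ DC and is removed by the high-pass, leaving a
  noise-only phase whose variance would otherwise fold into a positive
  speed bias through `v = √(a²+b²)`.

`solve_vector()` defaults to the plain unweighted least squares (the form
the oracle-equivalence tests exercise); weighting is an option that
`hvmudi_vector_flow()` enables.

Velocities whose per-angle projections would alias are flagged rather than
unwrapped; the phase domain is (−π, π].

## 5. Hemodynamic metrics

* **Density**: `100 · N_vessel / N_ROI` on the binary mask.
* **Diameter**: at each skeleton pixel the enhanced intensity is sampled
  along the centerline normal (initial half-length one wavelength
  `c/f_c`); the diameter is the distance between the two half-maximum
  crossings (linear interpolation). If fewer than two crossings are found
  the segment grows by 10 µm, at most 10 times (a bounded version of the
  stated increment), after which the pixel is excluded from the mean.
  Because fully developed speckle has 100 % intensity contrast, meaningful
  FWHM values require an envelope-smooth image (the enhanced image, or an
  averaged/smoothed power image, as the tests do).
* **Trajectories**: the time-averaged vector field, Gaussian-smoothed with
  σ = 2 px per component, is integrated forward from every vessel pixel
  with the explicit first-order update `P_{k+1} = P_k + v(P_k)/FR`
  (bilinear velocity lookup), terminating at mask exit, a speed floor, or
  a length cap.
* **SOAM tortuosity**: the sum of in-plane angles between consecutive step
  vectors at every interior trajectory point, divided by the full path
  length. (The printed index ranges of the source formulas are
  inconsistent for short paths; summing over all interior points matches
  the metric's standard definition and the large-n limit.) ROI summaries
  weight trajectories by pixel count.
* **Pulsatility index**: `(max − min)/mean` of the signed per-frame
  velocity trace, so reversals deepen the minimum.
* **Reversal ratio**: a vessel pixel reverses when either Cartesian
  velocity component changes sign more than twice (≥ 3 changes) over the
  window, after the same σ = 2 px smoothing; exact zeros do not count as
  changes. The ratio is reversal pixels over vessel pixels.
* **Classification**: per connected component, mean axial velocity
  > +ε → penetrating arteriole (descending), < −ε → ascending venule,
  within ±ε → unclassified, with ε = 5 % of the component's mean speed.

## 6. The phantom simulator

`simulate_iq()` bypasses acoustic propagation: blood speckle is a fixed
complex circular-Gaussian field (spatially smoothed to a ~1 px correlation
length, shared across angles since the same scatterers are insonified),
advanced inside the tube by the analytic per-angle phase increment φᵢ.
This is exactly the signal model the estimators invert, which makes the
simulator oracle-friendly: the preset speed and direction are the ground
truth for end-to-end recovery tests.

* **Clutter** is a sum of four spatially smooth complex fields riding slow
  temporal tones — low-rank and band-limited by construction. The band
  parameter defaults to 10 Hz, with mode frequencies at fractions
  {0, 0.02, 0.05, 0.08} of the band edge and power split
  {0.70, 0.17, 0.09, 0.04}: tissue/wall echo in a fixed preparation is
  dominated by a quasi-static component with sub-hertz drift. (A clutter
  spectrum filling the whole band at +30 dB would overlap the slowest
  preset's Doppler lines at ~1.6 Hz, a regime in which no temporal filter
  of any kind could separate the two — no meaningful validation could be
  defined there.) Clutter is identical across angles.
* **Noise** is circular white complex at the stated SNR relative to blood.
* **Not modeled by default**: speckle decorrelation from scatterer
  translation (an optional lateral-drift mode exists), depth-dependent
  attenuation and focusing, nonlinear propagation, hemodynamic pulsation.
  Passing phantom tests therefore demonstrates correctness of the phase
  chain and of the adaptive rules under realistic amplitude relations, not
  robustness to decorrelation or beamforming artifacts in vivo.

The default phantom mirrors the validation protocol: a 280 µm tube
perpendicular to the beam through the image center, plug flow, 200 frames
(0.4 s at FR = 500 Hz, the value implied by the stated acquisition time,
kept configurable), half-wavelength pixel pitch (19.25 µm at 40 MHz),
clutter 30 dB above blood, 20 dB SNR, presets 1.8–14.4 mm/s, four seeded
repetitions.

`synth_vector_field()` provides mask/field scenarios with analytically
known metrics (straight vessel, L-bend, pulsatile trace with PI exactly 1,
two-vessel reversal scene with ratio exactly 0.40, Y-junction) for
metric-level tests decoupled from the imaging chain.

## 7. Problem sizes and numerical choices

The in-silico validation runs at 128×128 px, 200 frames, 7 angles, eight
presets × four seeds; the adaptive cutoff for this steady scene is
estimated on a non-overlapping 2×2 tiling of 64 px blocks (the global
cutoff is a median across blocks, and the homogeneous scene makes a sparse
tiling equivalent to the dense one), while the full 90 %-overlap
recombination path is exercised on smaller scenes in the unit tests. The
full-record lag-1 window is used for the steady phantom; the sliding
10-frame window is the default for time-resolved output.

Other numerics: complex SVD throughout (no real/imaginary splitting);
eigenvalues below 10⁻⁶ of the largest singular value are treated as exact
zeros when the Gram route is used; the binarization of an all-zero image
is an empty mask, not an error; `λ₂ = 0` gives zero vesselness; Hann
tapers are built strictly positive so recombination weights normalize
everywhere; trajectory integration uses bilinear interpolation with
replicate clamping at the image border.

## 8. Known limitations

* The adaptive `T_L` rule can mis-rank clutter residuals and blood when
  their singular values interleave (short records coarsen the frequency
  resolution of the criterion); the cutoff's clutter-band floor makes the
  velocity path robust to this, but power images of marginal scenes can
  retain clutter residues.
* Vesselness with σ ≤ 2 px responds at the walls, not the interior, of
  vessels much wider than ~5 px; wide-tube masks should come from the
  power image or ground truth rather than the vesselness output.
* FWHM diameters on single-realization speckle are biased low; use
  envelope-smooth images.
* No aliasing correction: presets are expected to stay below the
  per-angle unambiguous limit.
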