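# hvmudi

High-spatiotemporal-resolution vector micro-Doppler imaging of
microvascular flow from ultrafast plane-wave ultrasound, without contrast
agents.

## The problem

Imaging microvascular hemodynamics in small animals requires resolving
vessels a few tens of micrometers wide while following flow dynamics at
hundreds of frames per second. Ultrafast high-frequency plane-wave imaging
acquires the raw material — per-angle complex IQ ensembles at a pulse
repetition frequency of several kilohertz — but the blood signal is buried
under tissue clutter tens of decibels stronger, and a single transmit
angle measures only the axial velocity component. `hvmudi` implements the
full processing chain from raw per-angle IQ to enhanced vascular maps,
per-voxel vector velocity fields, and hemodynamic statistics:

1. **Coherent compounding** of the tilted plane-wave transmissions
   (`compound()`); PRF 3500 Hz over seven angles gives an effective frame
   rate FR = 500 Hz (`effective_frame_rate()`).
2. **Block-wise SVD clutter filtering** (`blockwise_filter()`). Each
   64-pixel Casorati block `A = U Δ V^H` is truncated to an adaptively
   chosen singular-order range `[T_L, T_H]`: `T_L` from the joint
   magnitude-curve / Doppler-frequency rule, `T_H` from the noise plateau.
   Overlapping blocks (90 %) are recombined with Hann weights. A cutoff
   frequency for the later high-pass is read from the lag-1
   autocorrelation of the `T_L`-th temporal singular vector
   (`adaptive_cutoff()`, `estimate_cutoff()`).
3. **Vessel enhancement**: bowler-hat transform (difference of line- and
   disk-shaped grayscale opening banks, `bowler_hat()`) followed by
   Hessian vesselness with eigenvalues `|λ₂| ≥ |λ₁|`,

   Δσ = 0 if λ₂ > 0, else exp(−(λ₁/λ₂)²/2β²) · (1 − exp(−(λ₁²+λ₂²)/2α²)),

   maximized over scales σ ∈ [1, 2] px (`hessian_vesselness()`, α = 2,
   β = 1). Binarization keeps the top 3 dB of dynamic range; the mask is
   thinned to a centerline skeleton (`binarize_and_skeletonize()`).
4. **Multibeam vector Doppler** (`hvmudi_vector_flow()`): per angle, a
   fifth-order zero-phase Butterworth high-pass at the adaptive cutoff,
   lag-1 phase estimation, the Doppler equation
   `v_axial = c · FR · φ / (4π f_c)`, and a per-voxel least-squares solve
   of `v_axial(θᵢ) = v cos(θ_D + θᵢ)` over all angles for speed `v` and
   direction `θ_D`.
5. **Hemodynamic quantification**: vascular density (% of ROI), vessel
   diameter by full width at half maximum along centerline normals,
   tortuosity by the sum-of-angles metric (SOAM), pulsatility index
   `(max − min)/mean`, flow-reversal ratio (fraction of vessel pixels
   whose velocity component sign flips more than twice), and
   arteriole/venule classification by mean axial flow direction.
6. **Flow rendering** (`render_flow()`): direction→hue / speed→saturation
   maps, advected particle animations, arrow fields.

A phantom simulator (`simulate_iq()`) generates per-angle IQ for a
straight micro-tube scene — blood speckle advanced by the analytic Doppler
phase, low-rank band-limited tissue clutter, white noise — with exported
ground truth, and `synth_vector_field()` emits mask/vector-field scenarios
with analytically known metric values.

## Worked example

Simulate the 280 µm micro-tube phantom (plug flow 7.2 mm/s, perpendicular
to the beam, clutter 30 dB above blood, 20 dB SNR) and recover the flow:

```r
library(hvmudi)
r <- phantom_measure(7.2e-3, seed = 1)
r[, c("cutoff_hz", "mean_speed_m_s", "rel_err", "dir_deg")]
#>   cutoff_hz mean_speed_m_s     rel_err  dir_deg
#> 1         2     0.00717005 0.004159791 89.99298
```

The adaptive cutoff settled at 2 Hz (the clutter band edge); the in-tube
mean speed is 7.17 mm/s — 0.4 % from the preset — and the circular-mean
flow direction 89.99° against a true 90° (lateral flow). At the slowest
preset (1.8 mm/s) the error grows to a few percent because the inner
angles' Doppler lines approach the cutoff.

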