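---
title: "Methods: simulating and characterising a multimode-fibre photoacoustic endomicroscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterising a multimode-fibre photoacoustic endomicroscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamendo)
```

This vignette documents the models behind the package, the choices made
where the design was genuinely open, and what the built-in simulator does
and does not establish about a physical instrument.

## The fibre model and what it stands in for

Light transmission through a multimode fibre is linear in the input field:
a complex transmission matrix `T` maps the `N` DMD micromirrors (binary
amplitude modulators, row-major order over the square sub-region) to the
field at each output-plane pixel. `generate_tm()` draws `T` with i.i.d.
circular complex Gaussian entries of variance `1/N` inside the fibre-core
disc (default ϕ100 µm at 1 µm camera pitch) and exactly zero outside.

Two deliberate simplifications:

* **No mode correlations.** A graded-index fibre has structured,
  correlated modes; an i.i.d. matrix is the standard fully-developed
  speckle model. It is sufficient to validate the calibration algebra and
  the *statistics* of binary-amplitude focusing, which depend only on the
  field being circular Gaussian at each pixel. Anything that relies on the
  real modal structure (bending robustness, memory effects, realistic
  point-spread aberrations away from the core centre) is out of scope.
* **Variance `1/N`.** This keeps the all-ON reference intensity O(1) per
  pixel for every mirror count, so images across `N` are directly
  comparable. (The flip side is that the all-ON intensity does *not* grow
  with `N`; the focusing gain does.)

## Intensity-only characterisation

The calibration displays the `2N` columns of `[H1, H2]`,
`H1 = (H + 1)/2`, `H2 = (−H + 1)/2`, with `H` the Sylvester Hadamard
matrix (`N` a power of two; the instrument this emulates used
`128 × 128 = 2^14` mirrors). The display order is fixed as all `H1`
columns then all `H2` columns; any consistent order is algebraically
equivalent, one is pinned for reproducibility.

`rvitm()` computes `(2 I − I_·1) · [H, −H]ᵀ`. Writing the field under
pattern `k` as `(E_R ± S_k)/2` with `E_R` the all-ON field and
`S_k = Σ_n H_kn t_n`, the quadratic terms cancel between the `H1` and `H2`
blocks and Hadamard orthogonality leaves exactly
`2N · Re(t_n Ē_R) = 2N · A_R A_n cos(θ_n − φ_R)` per mirror. Two
consequences, both tested: the subtracted all-ON column is not load-bearing
(any constant offset on the measurements cancels), and the estimate equals
the analytic oracle `analytic_rvitm_oracle()` to machine precision on
noiseless data. The matrix is kept on this raw `2N`-multiplied scale:
focusing uses only ranks, so scale never matters.

`select_focus_pattern()` switches ON the `⌈0.30 N⌉` mirrors with the
largest entries for the target pixel. The 30 % fraction is the instrument's
operating point; `⌈·⌉` is our rounding choice (no rule was stated), and
ties break towards the lowest mirror index so selections are deterministic.

The classed `rvitm` fit carries `coef`, `predict` (the linear
interference-term intensity model), `residuals`, `summary` and `plot`
methods. The intensity model is approximate by construction — intensity is
quadratic in the field — so residuals on calibration data are structured,
not noise; they are exposed for diagnostics, not inference.

## Photoacoustic synthesis

`simulate_a_line()` is a delay-only acoustic model: per-depth source
strength is the absorber map weighted by a separable 3-D Gaussian focus
(lateral FWHM 1.2 µm, axial FWHM 22 µm — the instrument's focus diameter
and depth of field — times pulse energy, 20 nJ), each depth contributing
the sensor impulse response delayed by the one-way time of flight at
`c = 1485 m/s`. No attenuation, diffraction or 1/r spreading: over the
≤ 0.5 mm depths simulated here, and with a near-omnidirectional sensor,
these are second-order effects for validating the pipeline.

The sensor is a Gaussian-envelope cosine burst parameterised by its two
published spectral numbers: 8 MHz centre frequency and 6.5 MHz −6 dB
amplitude full width (so σ_f = 6.5/2.355 MHz and σ_t = 1/(2π σ_f) ≈ 58 ns).
Default sampling is 250 MHz (4 ns) over a configurable window.

Signal conditioning is a 20 MHz zero-phase 4th-order Butterworth low-pass.
It is applied exactly in the frequency domain as the squared magnitude
response `1/(1 + (f/f_c)^8)` after odd-reflection end padding — the
textbook forward–backward cascade has this response and zero phase, and the
spectral implementation avoids end transients on short traces entirely.

**Envelope vs signed amplitude.** Images and MIPs use the analytic-signal
envelope (a bipolar pulse would otherwise make the projection
sign-sensitive). Axial-resolution metrology in acoustic mode instead uses
the *positive lobe of the signed profile*: with this sensor's fractional
bandwidth, the envelope is ~200 µm long on the depth axis while the
positive peak of the carrier is ~60 µm — and the positive-peak width is
what the time-of-flight mapping resolves and what the instrument convention
reports. `assemble_volume_acoustic()` therefore offers both
(`signal = "envelope"` for display, `"signed"` for metrology), and
`axial_resolution()` takes the positive part before fitting. In optical
sectioning, the z-profile across the 5 µm-spaced focal planes is governed
by the 22 µm depth of field, so optical sectioning resolves depth ~2×
better than this sensor's acoustic sectioning — the comparison the package
reproduces.

## Metrology conventions

* **Enhancement factor** = peak intensity inside the focal disc ÷ mean
  intensity of in-core pixels farther than 3 × FWHM from the focus. The
  background region had to be pinned down (it was not defined); excluding a
  3-FWHM guard ring keeps focus tails out of the background estimate.
* **Power ratio** uses a disc of diameter one FWHM, consistent with
  quoting fluence as energy over the ϕ1.2 µm focal area
  (20 nJ → 1.77 J/cm²).
* **FWHM** is linearly interpolated at half peak; ESF → LSF resolution
  averages 10 adjacent edge profiles, differentiates, and reports the FWHM
  of an unweighted least-squares Gaussian fit (moment-initialised,
  Levenberg–Marquardt). Gaussian fits are also used for axial profiles;
  multi-lobed profiles are rejected rather than silently fitted.
* **Scan grid**: square lattice with one point pinned to the FOV centre,
  keeping points whose centre lies in the closed disc. At ϕ100 µm this
  gives 7845 (1 µm step) and 31417 (0.5 µm) positions — the instrument's
  rounded 7850 / 31500 pixel counts. Frame time is positions ÷ DMD rate.

## Mosaicing

Consecutive frames are registered with the single-step upsampled-DFT
cross-correlation method: coarse FFT correlation, then local evaluation of
the inverse DFT on a 1/κ lattice (κ = 10) around the peak, rather than
literally upsampling the images 10× by bicubic interpolation — the same
precision contract at a fraction of the cost. Two refinements proved
necessary for *sequences* and are part of the method here:

* the correlation surface is **normalised by the overlap** of the two
  frames' valid-pixel masks. Plain periodic cross-correlation weights each
  lag by the shrinking overlap area, which biases every pairwise estimate
  a few hundredths of a pixel towards zero; over a 40-frame
  constant-velocity sequence that compounds to a visible drift.
* the fine peak is **parabolically interpolated**, removing the 1/κ
  quantisation of the refinement lattice (which would otherwise also
  accumulate whenever the true step has a constant fractional part).

Stitching quantises each cumulative offset to 1/κ pixel, realises the
subpixel residual by bilinear resampling of the frame (and of its mask,
which serves as the stitching weight), and accumulates values and visit
counts; the rendered mosaic is the running average, so overlapping regions
are averaged exactly as frames arrive. The canvas is pre-allocated and
overflow is an explicit error, never silent growth. Frames are not
intensity-normalised before stitching.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed, and multi-stage
pipelines fan a master seed out deterministically, so identical
(configuration, seed) reproduce outputs checksum-identically
(`run_experiment()` records MD5s in its manifest). Desk-scale defaults —
1024 mirrors (32 × 32) rather than the instrument's 16384, 64 × 64 output
grids in examples, ϕ100 µm FOV — keep a full characterisation in seconds
and the complete test suite under a minute while leaving the paper-scale
configuration available through `default_config()` overrides.

## What passing tests do and do not show

The simulator validates algebra, statistics and geometry: estimator
exactness, focusing gain and its scaling with mirror count, arrival-time
arithmetic, resolution recovery from known blurs, sectioning spans,
registration accuracy and mosaic fidelity. It does not model real modal
structure, fibre bending, camera nonlinearity, acoustic attenuation or
tissue heterogeneity, so quantities that are hardware-specific —
enhancement factors in the hundreds at 16384 mirrors, measured lateral
resolutions, absolute pressure — are represented only by their simulated
counterparts under the stated models, not reproduced as experimental
values.
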