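---
title: "Spatiotemporal encoding in MRI: models, simulation and reconstruction with spenr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal encoding in MRI: models, simulation and reconstruction with spenr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(spenr)
```

## The encoding model

Spatiotemporal encoding (SPEN) replaces the Fourier phase ramps of
conventional MRI along one axis with a quadratic phase
$\phi(y) = \beta y^2$. Under a decoding gradient the total phase
$\beta y^2 + k(t)\,y$ has a stationary point at
$y_\mathrm{stat}(t) = -k(t)/(2\beta)$: at each instant only spins near the
vertex of the parabola add coherently, so acquisition time maps directly
to position. Sweeping $k$ over $\Delta k = 2\beta\,\mathrm{FOV}$ scans the
vertex across one field of view, which requires the acquisition gradient
area to equal the excitation gradient area (`check_spen_condition()`).

The quadratic phase can be generated two ways, and the package treats
them as exactly equivalent parameterizations of the same forward model:

* **Chirped RF + constant gradient.** A pulse swept over bandwidth $BW$
  in time $T$ under a gradient $G$ (stored as $\gamma G/2\pi$ in Hz/m)
  excites position $y$ at the moment the sweep crosses its resonance,
  imprinting $\beta = \pi G^2 T / BW$ (`beta_from_chirp()`). The
  excited field of view is $BW/G$.
* **Quadratic encoding field.** A field $B(y) = C y^2$ applied for
  $\tau_g$ imprints $\beta = 2\pi \bar\gamma C \tau_g$
  (`beta_from_quadratic_gradient()`), decoupling the encoding from the
  RF pulse entirely.

Discretized on a uniform grid, the acquisition is the linear operator
$A_{ij} = \exp\!\left[i(\beta y_j^2 + k_i y_j)\right]\Delta y$
(`build_forward_operator()`); $\beta = 0$ reduces it entrywise to the DFT
matrix. In k-space the same model is a convolution: the measured samples
are the true k-space convolved with the chirp kernel
$H(k) \propto \exp[-ik^2/(4\beta)]$. `kspace_psf()` returns the analytic
unit-magnitude kernel; `kspace_psf_discrete()` returns the exact
FOV-windowed discrete transfer function, for which the convolution
identity holds to machine precision (`spen_convolve()`). The analytic
form is a stationary-phase approximation of the discrete one; the two
phases agree to better than 0.05 rad over the central half band once
$\beta\,\mathrm{FOV}^2 \gg 1$ (about 628 for the reference protocol).

## RF pulse design and the power comparison

`design_wurst_chirp()` builds the swept pulse with the standard WURST
envelope $A(t) = A_0\,(1 - |\cos(\pi t/T)|^n)$ and phase equal to the
time integral of the instantaneous frequency. All amplitudes are nutation
frequencies in Hz, so pulse energy ($\sum |b_1|^2 \Delta t$, Hz²·s), peak
power (Hz²) and RMS amplitude (Hz) are hardware-independent and are the
quantities through which the specific absorption rate scales
(`rf_metrics()`).

Two amplitude calibrations are offered. The default, `"analytic"`, is the
low-adiabaticity 90° rule $A_0 = \sqrt{R/4\pi}$ with $R = BW/T$ the sweep
rate — the convention under which swept-pulse power figures are usually
quoted, and the one that reproduces the reference chirp's published
energy/peak/RMS triple (about 3335 Hz²·s, 0.99×10⁶ Hz², 913 Hz for
50 kHz / 4 ms / WURST-40). The `"bloch"` option instead bisects $A_0$
until the simulated flip at sweep center is exactly 90°; this lands about
6% lower in amplitude because the exact on-resonance flip of an
analytically calibrated chirp overshoots to ≈95°. Both are tested; the
choice matters only for absolute power figures, not for the encoding.

Amplitude modulation narrows the excitation profile relative to the swept
band, so `bandwidth_corrected_chirp()` widens the sweep iteratively
(secant updates against the Bloch-simulated profile FWHM) until the
profile width matches the nominal bandwidth; the widening factor
(≈1.14 for WURST-40) decreases toward the block-pulse limit as the order
grows.

The comparison pulse for the quadratic-gradient route is a Hamming
windowed sinc (`design_sinc()`), amplitude-set by the small-tip condition
$2\pi\!\int b_1\,dt = \pi/2$. Its roughly sixfold lower RMS amplitude
relative to the chirp is the SAR argument for generating the quadratic
phase with gradient hardware instead of RF.

## Bloch verification

`simulate_pulse()` integrates the Bloch equation as one hard-pulse
rotation per RF raster sample (1 µs default) about the effective field,
with no relaxation — appropriate for millisecond pulses and the
validation role the simulator plays here. The compiled core preserves the
magnetization norm to $10^{-8}$ and matches a plain-R Rodrigues-rotation
oracle to $10^{-10}$ in the tests.

Simulating the chirp under its excitation gradient and fitting the
unwrapped transverse phase over the central 80% of the FOV (the edges are
excluded because the sweep cannot pass fully through spins there, leaving
their flip and phase ill-defined) recovers the analytic $\beta$ to better
than 0.3%, and places the parabola vertex at one FOV edge — the natural
prephasing of the swept excitation. Sign conventions: with the package's
left-handed rotation convention an up-swept chirp imprints
$-(\beta y^2 + \beta\,\mathrm{FOV}\,y)$; an ideal refocusing pulse
conjugates this to the $+\beta y^2$ convention in which the forward
operator and all reconstructions are written.

## Digital phantoms and signal synthesis

`make_bottle_1d()` (smoothed top-hat) and `make_rod_phantom()` (uniform
disk with zero-density rods) provide the 1D and 2D test objects;
`with_shim_offresonance()` adds a linear-plus-quadratic off-resonance map
whose peak (Hz) emulates deliberately degraded shimming. The default 2D
study uses a 50 Hz peak — a realistic poorly shimmed phantom at 3 T; the
published experiments do not state their shim offsets, so the map is a
parameterized emulation, not a replica.

One modeling rule matters more than any other here: **the phantom grid
must oversample the spatial chirp**. The synthesis grid step must stay
below $\pi/(\beta\,\mathrm{FOV})$, otherwise the discrete sum cannot
represent the quadratic phase and the synthesized samples lose the
continuum localization that makes SPEN work (every reconstruction then
aliases, which is a numerical artifact of the coarse quadrature, not
physics). The 2D generator therefore synthesizes on a fine grid (256
points along the SPEN axis for the reference $\beta$) while acquiring a
64×64 matrix, and `phantom_downsample()` produces the matched ground
truth. `synthesize_epi_hybrid()` models the alternating-polarity EPI
readout with true per-sample acquisition times (echo spacing × line +
dwell × sample, echo-centered), optional complex Gaussian noise, and a
readout gradient-timing error that offsets even lines — the saw-tooth
delay artifact of EPI.

What the generator deliberately does not emulate: relaxation and
diffusion, coil sensitivities, the chirp's own edge-attenuated excitation
profile inside the operator (the operator assumes uniform excitation),
and scanner hardware imperfections beyond the single gradient-delay
parameter. Passing tests therefore demonstrate the encoding/decoding
mathematics and its distortion behavior, not full scanner realism.

## Reconstruction

Four reconstructions are provided, in increasing order of model use:

* `reorder_magnitude()` — the direct time-to-position map; blurred by the
  intrinsic PSF (packet width $\approx\sqrt{\pi/\beta}$, about 14 mm ≈ 4
  pixels for the reference protocol).
* `fresnel_recon()` — the convolution/conjugate-phase method:
  $\hat\rho(y) = \sum_i w_i\, s_i\, e^{-i(\beta y^2 + k_i y)}$ with
  trapezoid quadrature weights (or grid-spacing weights, which make it
  exactly $A^H s$). Its `aperture` argument applies a Gaussian window of
  SD $\sigma_k$ around each position's stationary sample $-2\beta y$.
* `tikhonov_recon()` — dense regularized inversion
  $(A^H A + \lambda I)x = A^H s$, the deterministic solver used for
  operator-consistent data.
* `fourier_epi_recon()` / `spen_epi_recon()` — the 2D pipelines: even
  line reversal and integer-shift alignment (`align_epi_lines()`,
  magnitude cross-correlation, integer shifts only — sub-sample delays
  cannot be corrected this way and leave residual ghosting), inverse DFT
  along the readout, then per-column decoding along the SPEN axis.

The aperture deserves its own paragraph, because it is the one genuinely
open design choice. The reference single-shot protocol encodes with
time-bandwidth 200 but acquires only 64 lines, i.e. the k-step is ~3.1×
the FOV Nyquist step. The acquired data are still local — each sample's
signal comes from its stationary packet — but a *full-aperture* linear
decoder re-introduces the sampling periodicity: a point object and its
replica at $2\pi/\delta k$ (64 mm) produce sampled data differing only by
a constant phase, so full-aperture conjugate-phase or exact-inverse
reconstructions fold content between the two whenever the data deviate
from the discrete model (sub-pixel shifts, off-resonance). Windowing the
kernel to the Fresnel zone of each position excludes the distant samples
where aliased content lives and restores the local, robust behavior of
the physical method. The default SD is $4\sqrt{|\beta|}$ rad/m — a fixed
number of Fresnel zones, so the aperture scales correctly with the
encoding strength; for the reference protocol this resolves ~1.5 pixels
while keeping ghost levels around 1%. With fully sampled 1D acquisitions
(k-step at or below $2\pi/\mathrm{FOV}$, e.g. 256 samples) no window is
needed and the plain adjoint is used.

`spen_epi_recon(method = "tikhonov")` remains available and is the
sharper choice for exactly grid-consistent data; `image_metrics()`
reports RMS error after a global intensity match, centroid displacement
(m and pixels) and the ghost ratio over truth-empty rows.

Distortion robustness follows directly from the k-step: a constant
off-resonance $\Delta f$ shifts either encoding by
$2\pi\,\Delta f\,\mathrm{esp}/\delta k$, and the SPEN k-step is
$\beta\,\mathrm{FOV}^2/(\pi N)$ times larger than the EPI phase-encode
step — 3.1× for the reference protocol, which is what the paired
simulations show (e.g. 0.63 px vs 3.48 px at 100 Hz).

## Sequence assembly and Pulseq export

Three SE-EPI timelines share one readout train (64 lines, 0.5 ms echo
spacing, 4 µs dwell, 80 µs ramps): the chirp-SPEN variant (chirp under
the encoding gradient, linear-term refocusing lobe, hard 180°,
stationary-point prephaser, N−1 SPEN blips whose areas satisfy the area
condition to 10⁻⁶ by construction), the quadratic-gradient variant (3 ms
sinc excitation, non-selective 180°, the quadratic event in the TE
delay — or before the 180° with `placement = "pre"`, which inverts the
parabola and flags the inverted reconstruction kernel), and the Fourier
reference (conventional phase-encode blips). All hit TE = 60 ms exactly
at the default configuration; the chirp variant is the longest, owing to
its 4 ms excitation and extra encoding lobes. Echo spacing and dwell are
not published for the reference experiments, so the defaults were chosen
once as typical clinical values; only the duration *ordering* across
variants is asserted, not absolute durations.

The quadratic event is exported with its nominal hardware setting
(313 mT/m² for 5 ms) verbatim. Because the $\beta$ implied by that
nominal setting exceeds the chirp's by ~27× while the published phase
maps show comparable steepness (the effective calibrated coefficient of a
matrix coil is not the nominal driver setting), the encoding $\beta$ used
for blips, prephaser and reconstruction defaults to the chirp-matched
value (`beta_mode = "matched"`); `"native"` mode is supported and simply
needs longer blips and prephasers under the amplitude limit.

`export_pulseq()` writes a deterministic, version-stamped text subset of
the Pulseq format ([VERSION], [DEFINITIONS], [BLOCKS], [RF], [TRAP],
[ADC], [SHAPES], plus a [QUAD] extension section for the quadratic
event); `import_pulseq()` reads it back, erroring loudly on unsupported
sections rather than skipping them. Round-tripping reproduces the
timeline within raster quantization, and two exports of the same
timeline are byte-identical.

## Numerical choices and limitations

* Unit conventions: gradients as $\gamma G/2\pi$ (Hz/m), $k$ in rad/m
  with $k = 2\pi \times$ gradient area, $\beta$ in rad/m², phases in rad.
  The published phase expressions mix $2\pi$ factors; one radian
  consistent convention is fixed here and validated against the Bloch
  simulator, which is unambiguous.
* Grids are uniform, centered, half-open $[-\mathrm{FOV}/2,
  \mathrm{FOV}/2)$; the centered transforms used in reconstruction invert
  the operator's $e^{+iky}$ convention explicitly.
* Phase unwrapping runs outward from the grid center and excludes
  positions with flip below 1°, where transverse phase is undefined.
* Rasters: RF 1 µs, gradients 10 µs; every event start/duration is
  raster-aligned and the Pulseq writer refuses misaligned timelines.
* Problem sizes: the shipped studies use 64-sample 1D inversions,
  256-point 1D convolution checks, 721-point Bloch phase grids and
  256×64-synthesis / 64×64-acquisition 2D studies — small enough to run
  the whole suite in well under a minute, large enough that every
  phenomenon (localization, aliasing, delay ghosts, distortion ordering)
  is resolved.
* Known limitations: no relaxation or multi-slice; no coil or B1 maps; no
  aliasing-suppression post-processing beyond the Fresnel aperture; the
  excitation-profile weighting is not folded into the forward operator;
  absolute sequence durations depend on unpublished readout timing.

## A worked 1D example

```{r example}
chirp <- design_wurst_chirp(chirp_design(50e3, 4e-3, wurst_order = 40))
rf_metrics(chirp)

beta <- beta_from_chirp(250e3, 50e3, 4e-3)
pars <- encoding_params(beta, fov_from_chirp(50e3, 250e3))
pars

tr <- spen_trajectory(pars, 256)
ph <- make_bottle_1d(256, pars$fov, 0.5)
op <- build_forward_operator(pars, tr, ph$y)
s <- synthesize_spen_signal(ph, op, tr)
rec <- fresnel_recon(s, pars, tr)
plot(rec, main = "SPEN bottle profile, conjugate-phase reconstruction")
```
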