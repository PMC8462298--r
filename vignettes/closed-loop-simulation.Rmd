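---
title: "Closed-loop phase-shifted stimulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop phase-shifted stimulation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasestim)
```

`phasestim` emulates a closed-loop optogenetic neuromodulation loop in
discrete time: an FIR phase-shift controller converts a recorded local
field potential (LFP) into a light command at a fixed 1 ms tick, the light
excites a synthetic neural oscillator, and the resulting LFP is recorded
through a model of the analog front end. This vignette explains each model,
the parameters that matter, and the choices made where the design was
genuinely open.

## The control loop

Every tick the engine performs, in order: (1) advance the plant one step
using the stimulation value computed `loop_delay_ticks` earlier (default
one full tick — the emulator's quantization of the sub-millisecond hardware
latency); (2) clock the analog chain with the new LFP sample and let the
channel scheduled for this tick read it; (3) if that is the control channel,
update the FIR and compute the stimulation command; (4) gate the command to
zero during control epochs; (5) log one packet. With `n_channels = 2` read
in an alternating manner, the controller runs at
`effective_channel_rate(0.001, 2)` = 500 Hz on channel 0, and the command
is held (zero-order hold) at the 1 kHz plant rate between updates. Whether
the hardware's stimulation update precedes or follows the record step
within one interrupt is not observable from outside; the fixed order above
is this emulator's documented convention.

## FIR kernel design

The controller kernel is a windowed cosine atom

$$h[k] = w[k]\cos\!\big(2\pi f_0 (k - c)/f_s + \varphi\big),
\qquad c = (n_\text{taps}-1)/2,$$

with a Hann taper `w` (Hamming and rectangular are available). Rather than
relying on the atom being approximately normalized, the design solves a
2×2 linear system over the two quadrature atoms so that the frequency
response at $f_0$ has *exactly* unit magnitude and *exactly* the commanded
phase once the linear-phase term of the centre tap is removed. Because the
correction is linear, the identity $h_{\varphi+180^\circ} = -h_\varphi$
holds to machine precision.

Two parameters matter:

- `bandwidth_hz` (default 6 Hz): the approximate −3 dB width of the pass
  band. The default tap count is derived from it as
  $n \approx 1.45 f_s / \mathrm{bw}$, giving 121 taps at $f_s = 500$ Hz.
  We chose 121 over a shorter kernel because one tap-count requirement we
  consider non-negotiable is strong off-band rejection (|H| < 0.1 at
  $f_0/4$ and $4 f_0$); at 101 taps the low-side skirt of a 10 Hz kernel
  still passes 15% at 2.5 Hz, while 121 taps brings it under 5%.
- the group delay $c/f_s$ (0.12 s at the defaults): the causal kernel
  delays the signal by half its length, and the commanded phase is defined
  *relative to the delayed signal* — no delay compensation is attempted.
  Physically this matters: the loop phase rotates by
  $360^\circ \cdot f \cdot 2c/f_s \approx 43^\circ$ per Hz across the pass
  band, which tilts the enhancement/suppression stripes of the modulation
  map across frequency, exactly the oblique pattern seen in phase-resolved
  modulation maps.

Negative algorithm outputs are hard-rectified to zero light (an LED cannot
emit negative light) rather than offset into a bipolar range; the
saturation ceiling defaults to 1 in normalized light units. Physical
calibration (mW, mA) is out of scope. The FIR history buffer is zeroed at
every epoch boundary so conditions are statistically independent of one
another.

## Analog front-end model

The recording path is, in physical order: amplifier band-pass
(2nd-order 1 Hz high-pass, 1st-order 200 Hz low-pass, unity gain) →
level shifter (affine ±10 V → 0–3.3 V, saturating at the rails) →
2nd-order 250 Hz anti-aliasing low-pass → 12-bit mid-rise ADC. All
recursive stages are digital Butterworth designs with the stated corner at
the −3 dB point; "cutoff" is taken in the −3 dB sense throughout. The
amplifier corner frequencies, gains and the ADC resolution are not fixed
by the hardware description we model; the defaults above are LFP-band
conventions and every one is configurable, with stage enable flags for
tests.

Two details are deliberate:

- **DC operating point.** Each recursive stage is initialised in its
  steady state for a settled 0 V tissue input, as a physical analog chain
  would sit, so the level-shifter offset causes no start-up transient.
- **Firmware offset removal.** The controller subtracts the recorded DC
  operating point (the mid-scale ADC code, 1.6504 V at the defaults)
  before the FIR, so a silent input produces exactly zero drive.

## The synthetic plant

Living tissue is replaced by the minimal model that produces the
phenomenon of interest: a linear stochastic resonator

$$x'' = -\omega_0^2 x - 2\zeta\omega_0 x' + k\,\mathrm{light} + \sigma\xi(t),$$

integrated by semi-implicit (symplectic) Euler–Maruyama at the loop tick.
The explicit Euler step is unusable here: its numerical anti-damping
($\approx \omega_0 \mathrm{d}t/2$, i.e. an effective $\zeta$ error of 0.03
at 1 kHz) would swamp the physical damping; the symplectic step has no such
secular error and reproduces the analytic stationary SD
$\sigma/\sqrt{4\zeta\omega_0^3}$ and the per-period decay
$e^{-2\pi\zeta/\sqrt{1-\zeta^2}}$ to within the test tolerances.

Defaults, chosen once and frozen: $f_0$ = 10 Hz, $\zeta$ = 0.03 (a
narrow-band oscillation), $\sigma$ = 86 V·s^−3/2 (stationary SD ≈ 0.5 V,
comfortably inside the ±10 V rails), light coupling k = 1200 V/s² per
light-unit, measurement noise 0.01 V, and a condition gain of 8
light-units/V. The coupling and gain were calibrated in a pilot sweep so
that the default 8-condition session reproduces the qualitative closed-loop
phenomenon — phase-dependent enhancement *and* suppression around 10 Hz
with roughly opposite extremal phases — robustly across seeds, and were
not revisited afterwards. Because light is non-negative, phase dependence
arises from the timing of rectified half-waves: the linear half of
$\max(y,0) = y/2 + |y|/2$ carries the commanded phase and acts as positive
or negative damping, while the $|y|$ half contributes only DC and harmonics.
Feedback strength is a compromise: far weaker and suppression drowns in
estimator variance; far stronger and the loop destabilises at neighbouring
frequencies inside the analysis band (the group-delay tilt above), which
masquerades as enhancement at the "suppressing" phase.

What the plant does **not** emulate: opsin kinetics, light propagation,
nonlinear neural-mass dynamics, non-stationarity, artefacts. Passing tests
therefore show that the algorithmic loop behaves as designed on a
narrow-band stochastic oscillation, not that any particular tissue will
respond identically.

## Scheduler

Stimulation epochs are laid out as ON followed immediately by its control
epoch (interspersed controls), with sequential or pseudorandom condition
order; pseudorandomisation permutes conditions independently within each
repetition block. Whether randomisation should instead span the whole
session is unclear from the protocols we mirror; block-wise permutation is
the default because it bounds the spacing between repeats of a condition.
The permutation is drawn from R's Mersenne–Twister with the generator kind
pinned explicitly, so plans are bit-identical across platforms for a fixed
seed. All randomness in a session derives from one seed via named
per-module substreams; no module reads ambient RNG state.

## Spectral analysis

Power spectra are Welch averages of Hann-windowed periodograms, 2 s
segments with 50% overlap at the 500 Hz channel rate — 0.5 Hz resolution,
enough to resolve the structure around 10 Hz, and satisfying a discrete
Parseval identity within 1%. Epoch heads are trimmed by 1 s to discard
filter and loop transients; PSDs are estimated per epoch and averaged
within condition, never across epoch discontinuities. The modulation map is
the dB ratio to the *pooled* control spectrum (a ratio for scale
invariance; pooling because a single no-stimulation reference is the
natural control), tiled over two phase cycles (0–720°) for display. The
dominant-frequency detector takes the band argmax with ties broken toward
the lower frequency.

`modulation_extrema()` reports either the deepest single cells of the map
(`"pointwise"`, the default — the deepest red and blue) or per-phase band
means (`"band_mean"`); the pointwise statistic is the right one for
locating the enhancement/suppression extremes because the group-delay tilt
moves the extreme cell across frequency between phase conditions.

## Numerical and degenerate-input conventions

- Config errors (invalid specs, Nyquist violations, unknown YAML keys) and
  data errors (rate mismatches, missing headers, out-of-range ticks) are
  distinct condition classes, mapped to CLI exit codes 2 and 3.
- Out-of-range analog inputs saturate (level shifter, ADC) rather than
  error, mirroring physical rails; a negative light command is a contract
  violation and errors.
- Columnar text files round-trip numbers at 15 significant digits; session
  logs embed a YAML header sufficient to re-run the session bit-identically.
- Problem sizes used in the shipped tests — 60 s stability runs, one
  160 s closed-loop session, twenty 960 s zero-gain null sessions — were
  chosen as the smallest sizes at which the statistical assertions are
  stable across seeds.

## Known limitations

Single-input single-output control only (one control channel; the second
channel is logged but unused); no phase-tracking of drifting oscillations
(the FIR centre frequency is fixed); no artefact rejection beyond the
epoch head-trim; hardware timing (interrupt jitter, bus throughput) is not
simulated; and the plant caveats above.
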