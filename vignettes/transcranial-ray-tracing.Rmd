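---
title: "Modeling transcranial photoacoustic signals by deterministic ray tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transcranial photoacoustic signals by deterministic ray tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullray)
```

## The problem

A photoacoustic (PA) source inside the brain emits a broadband pressure
pulse that must cross the skull before reaching an external ultrasound
detector. The skull distorts the signal four ways: amplitude attenuation
(impedance mismatch, absorption), pulse broadening (frequency-dependent
attenuation and dispersion), an arrival-time advance (bone is roughly twice
as fast as soft tissue), and ringing artifacts (reverberation between the
skull faces). `skullray` is a deterministic forward simulator for these
effects in a flat layered geometry: brain tissue of thickness `T` with a
spherical absorber at depth `d` below the inner-skull surface, a skull
layer of thickness `h`, a coupling layer of thickness `k`, and a flat
circular detector of radius `rd`.

Rather than solving the lossy elastic wave equation on a grid, the
simulator traces rays per frequency, builds a per-frequency impulse
response at the detector, and convolves it with the short-time Fourier
transform (STFT) of the source pulse. Cost scales with the number of rays
and modeled frequencies, not with the acoustic volume.

## Media: power-law absorption and Kramers-Kronig dispersion

Each medium carries a density, a longitudinal sound speed at a reference
frequency, optional shear parameters (solids only), and power-law
absorption per mode,

$$\alpha(f) = \alpha_0 \left(\frac{f}{1\ \mathrm{MHz}}\right)^{y},$$

with $\alpha_0$ in Np/cm at 1 MHz — the standard tissue-acoustics
convention. `absorption()` returns Np/m. The bundled `table1_media()` set
uses soft tissue ($\rho$ = 1000 kg/m³, $c_L$ = 1500 m/s, $\alpha_{0L}$ =
0.05 Np/cm, $y$ = 1.18), cranial bone ($\rho$ = 1800, $c_L$ = 2900, $c_S$
= 1444, $\alpha_{0L}$ = 1.70, $\alpha_{0S}$ = 3.41, $y$ = 0.93) and
lossless water ($\rho$ = 1000, $c_L$ = 1486).

Causality ties absorption to dispersion. For $0 < y < 3$, $y \neq 1$ the
Kramers-Kronig relation gives

$$\frac{1}{c(\omega_2)} - \frac{1}{c(\omega_1)} =
  \alpha_0' \tan\!\left(\frac{\pi y}{2}\right)
  \left(\omega_2^{\,y-1} - \omega_1^{\,y-1}\right),$$

where $\alpha_0'$ is the prefactor converted to Np/m per (rad/s)$^y$
($\alpha_0' = 100\,\alpha_0 / (2\pi\cdot 10^6)^y$), so that the absorption
and dispersion formulas are mutually consistent in SI units. Two
conventions had to be fixed here because tabulated constants rarely state
them:

* **Frequency units of $\alpha_0$.** We read Np/cm *at 1 MHz with the
  exponent applied to frequency in MHz* — the ubiquitous tissue
  convention. The conversion above follows from it.
* **Reference frequency of the tabulated speeds.** Not universally
  stated; `scenario()` exposes it as `f_ref` with default 1 MHz,
  consistent with the 1-MHz absorption convention.
* **Sign of the dispersion relation.** As written, media with $y < 1$ are
  faster at higher frequencies (for skull: 2900 m/s at 1 MHz, ≈3138 m/s
  at 5 MHz, ≈2730 m/s at 0.3 MHz). Some formulations carry the opposite
  sign; the implemented behavior is pinned by a regression test so it
  cannot silently flip. This choice has a measurable consequence
  discussed under *Limitations*.

$y = 1$ is rejected ($\tan(\pi y/2)$ singular), and lossless media
($\alpha_0 = 0$) are non-dispersive by construction. The loss-operator
coefficients $\tau = -2\alpha_0' c_0^{y-1}$ and
$\eta = 2\alpha_0' c_0^{y}\tan(\pi y/2)$ of the equivalent
fractional-Laplacian wave equation are provided by
`loss_operator_coeffs()` for diagnostics; the engine itself applies
absorption and dispersion directly along ray segments.

At exactly zero frequency the relation above is singular for $y < 1$
($\omega^{y-1} \to \infty$), so the DC bin of the engine is traced in the
lossless non-dispersive limit (reference speeds, zero absorption). The DC
bin of a bipolar PA pulse carries essentially no energy, so this choice is
inconsequential in practice.

## Interface physics

At the fluid–solid interface an incident longitudinal wave splits into a
reflected wave and transmitted longitudinal and shear waves. With
$Z_L = \rho_s c_L/\cos\theta_L$, $Z_S = \rho_s c_S/\cos\theta_S$,
$Z_f = \rho_f c_f/\cos\theta_i$ and Snell angles
$\sin\theta_{L,S} = (c_{L,S}/c_f)\sin\theta_i$, the pressure transmission
coefficients are

$$T_L = \frac{\rho_f}{\rho_s}
        \frac{2 Z_L \cos 2\theta_S}{D}, \qquad
  T_S = -\frac{\rho_f}{\rho_s}
        \frac{2 Z_S \sin 2\theta_S}{D}, \qquad
  D = Z_L\cos^2 2\theta_S + Z_S \sin^2 2\theta_S + Z_f,$$

and the intensity coefficients follow as
$I_L = \frac{\rho_f\tan\theta_i}{\rho_s\tan\theta_L}|T_L|^2$,
$I_S = \frac{\rho_f\tan\theta_i}{\rho_s\tan\theta_S}|T_S|^2$,
$I_r = 1 - (I_L + I_S)$.

Numerical conventions worth stating:

* **Normal incidence.** The tangent ratio in $I_L$ is 0/0 at
  $\theta_i = 0$; we define it as exactly 1 there, which yields
  $I_L(0) = (\rho_f/\rho_s) T_L^2 = 0.414$ for the tissue/skull pair. The
  small-angle *limit* of the ratio is $c_f/c_L \approx 0.52$, so
  $I_L(\theta_i)$ is deliberately discontinuous at 0; a test asserts the
  discontinuity so the convention cannot regress.
* **Evanescence.** Beyond a mode's critical angle its transmitted
  coefficient is set to zero and flagged; no complex evanescent fields are
  carried across interfaces. Transmission paths found by the ray engine
  are always subcritical by construction, so this only matters for direct
  coefficient queries.
* **Amplitude convention and reflection.** $T_L$, $T_S$ carry a
  $\rho_f/\rho_s$ factor (White's convention; the true
  transmitted/incident pressure ratio is $(\rho_s/\rho_f) T$). The
  fluid-side reflection coefficient from the same boundary problem,
  $R = (Z_L\cos^2 2\theta_S + Z_S\sin^2 2\theta_S - Z_f)/D$, closes the
  energy flux as $R^2 + (\rho_s/\rho_f)^2(I_L + I_S) = 1$ at every
  oblique angle (verified to $10^{-10}$ in the tests); the definitional
  $I_r = 1 - I_L - I_S$ is the intensity table's bookkeeping quantity,
  not the reflected flux fraction. The ray engine follows the convention
  consistently: amplitudes entering the skull are multiplied by $T_L$ or
  $T_S$ exactly as defined above.

For the solid-to-fluid crossing (skull into coupling gel) no closed form
is tabulated as commonly; `solid_fluid_transmission()` solves the
three-unknown boundary-value problem directly — continuity of normal
displacement and normal stress, vanishing shear traction — for an incident
longitudinal *or* shear wave, using displacement potentials and Cramer's
rule on the $3\times 3$ system. Only a longitudinal wave exists in the
fluid. The amplitude convention matches the transmission formulas above
(at normal incidence, L-in reduces to $2Z_f/(Z_L+Z_f)$; shear at normal
incidence transmits nothing by symmetry). The solver returns the same-mode
and mode-converted reflection coefficients as well, which the ray engine
uses for reverberation bookkeeping; an energy-flux closure test
($\sum \rho\,\mathrm{Re}(k_z)\,|A|^2$ conserved) holds to $10^{-10}$ at
all angles, including past the critical angles where reflected branches
turn evanescent.

## The source pulse

A uniformly illuminated spherical absorber of radius $r_0$ under a
Gaussian laser pulse of duration $\tau_l$ emits the bipolar N-shaped
far-field pulse

$$p(r, t) = -\frac{\beta E_a}{2\pi^{3/2} C_p \tau_e^2\, r}
  \,\frac{t - \tau}{\tau_e}\, e^{-\frac{1}{2}\left(\frac{t-\tau}{\tau_e}\right)^2},$$

with $\tau = r/c_0$, $\tau_a = r_0/c_0$ (half the acoustic transit time
across the sphere) and $\tau_e = \sqrt{\tau_a^2 + \tau_l^2}$. The pulse is
antisymmetric about $t=\tau$ with extrema at $\tau \pm \tau_e$; its
spectrum peaks at $1/(2\pi\tau_e)$ — about 0.24 MHz for $r_0$ = 1 mm in
soft tissue — and larger absorbers emit narrower-band waves. Because every
distortion metric is a ratio, a time, or a bandwidth, the thermodynamic
prefactors $\beta$, $C_p$, $E_a$ default to 1. The default laser duration
is 7 ns (a typical Q-switched Nd:YAG pulse), negligible against
$\tau_a \approx 0.67\ \mu s$.

The engine defines the source *at the absorber surface* ($r = r_0$);
spherical spreading beyond the surface is the ray engine's job (factor
$r_0/\mathrm{path\ length}$). One subtlety: at $r = r_0$ the arrival time
$\tau$ equals $\tau_e$, so a record starting at $t = 0$ would truncate the
leading lobe; `pa_waveform()` therefore starts its default record at
$\tau - 8\tau_e$ (negative times are fine).

## Ray engine

**Mesh.** A `mesh_n` × `mesh_n` grid (default 100, i.e. up to $10^4$ rays)
circumscribes the detector aperture; cells outside the disk are dropped
(≈ π/4 of the square survives).

**Path finding.** For each cell and each skull mode (longitudinal, shear)
the three-segment Snell-consistent path from the target is found by a
Fermat construction: all segments share the ray parameter
$p = \sin\theta_i / c_i$, and the accumulated lateral offset
$\sum_i d_i \tan\theta_i$ is a strictly increasing function of $p$, so
bisection (90 iterations, vectorized over all cells) pins $p$ to machine
precision. Paths are solved once at `f_ref` and reused across
frequencies: dispersion perturbs speeds by a few percent and path
perturbations enter arrival time only at second order (Fermat
stationarity). Geometry guarantees subcritical incidence everywhere a
path exists.

**Per-frequency propagation.** Along its fixed geometry each ray, per
frequency $f$, accumulates travel time $\sum_i L_i / c_i(f)$ with
dispersive speeds, amplitude decay $\exp(-\sum_i \alpha_i(f) L_i)$,
interface factors ($T_L$ or $T_S$ entering the skull, the
boundary-condition solid-to-fluid coefficient leaving it, both evaluated
at the dispersive speeds for that frequency), and spherical spreading
$r_0/\sum_i L_i$. For the skull-free reference stack the same machinery
runs with fluid–fluid coefficients (which degenerate to $T=1$, $R=0$ for
identical media).

**Reverberation.** Rays reflect between the skull faces: each double
bounce multiplies the amplitude by
$R_\mathrm{outer} R_\mathrm{inner}$ (solid-side reflection coefficients
from the boundary solver), adds two skull chords of delay and absorption,
lengthens the spreading path, and costs two reflections against the
budget (`max_reflections`, default 20). Reverberation branches keep their
mode: cross-mode bounce conversion is dropped because shear absorption
(3.41 Np/cm) kills multiply-reflected shear energy, so multiple-reflection
artifacts are carried by longitudinal waves. Rays die on three
conditions: the reflection budget, an amplitude floor (`amp_floor`,
default $10^{-10}$ of a unit launch), or lateral drift beyond the
simulation half-width (`extent_halfwidth`, default $4 r_d$ — the lateral
extent of the simulated region is otherwise unconstrained by the
geometry, so it is an explicit engine setting). Rays reflected from the
(rigid, $R = +1$) transducer face can optionally make extra round trips
in the coupling layer (`transducer_reflections`, default off).

**Impulse response.** Arrivals are binned at $1/f_s$ resolution;
coincident complex amplitudes add coherently. The result — per modeled
frequency, a sparse map from arrival-time bin to accumulated complex
amplitude — is the scenario's impulse response, computed once and reusable
against any source.

## STFT convolution engine

The source signal is analyzed with a periodic Hann window of length
`2 * n_freqs` (so the 64 default bins span DC to Nyquist at
$f_s/(2 n_\mathrm{freqs})$ = 0.39 MHz spacing at 50 MHz). The periodic
Hann window satisfies constant overlap-add *exactly* for any hop dividing
the window (the constant is $W/2H$), and the signal is padded so every
sample receives full analysis weight, making `istft(stft(x))` exact to
machine precision.

`apply_response()` convolves each frequency row with that bin's impulse
response resampled onto the frame grid. An arrival at time $t$ is split
linearly between the two bracketing frame slots, each slot carrying the
exact carrier phase $e^{-i 2\pi f (t - k H/f_s)}$. The phase factor
preserves sub-hop delays in the carrier; the linear split preserves them
in the envelope. With the 50%-overlap hop the frame grid (1.28 µs) is
coarse against the ~0.24 MHz carrier, which measurably biases the
received spectrum, so the high-level pipeline (`simulate_scenario()`)
defaults to a hop of `n_freqs/4` (0.32 µs at standard settings), at which
the received bandwidths are converged (halving the hop again changes them
by < 0.5%). `stft()` itself defaults to the conventional 50% overlap.

The Nyquist row (stored for exact reconstruction) reuses the nearest
modeled frequency's arrivals re-phased at its own frequency. An optional
per-frequency detector responsivity is applied after the response;
`transducer_gaussian(center, frac_bandwidth)` models a commercial probe as
a Gaussian with a −6 dB full width of `frac_bandwidth * center`.

## Distortion metrics

* `attenuation_pct`: $100\,(\max|p_\mathrm{ref}| -
  \max|p_\mathrm{skull}|)/\max|p_\mathrm{ref}|$.
* `broadening_pct`: signal duration is the span between the first and
  last crossings of the analytic-signal envelope above 10% of its peak
  (threshold configurable); broadening is the relative duration increase.
* `time_shift_measured`: lag of the cross-correlation maximum of the two
  envelopes with parabolic sub-sample refinement, positive when the
  transcranial signal arrives *earlier* (bone is faster).
  `time_shift_analytic` gives the non-dispersive prediction
  $\Delta t = h/c_0 - h/c_\mathrm{skull}$.
* `bandwidth_3db`: width of the contiguous region around the spectral
  peak above $\mathrm{peak}/\sqrt 2$, with zero-padding and linear
  interpolation of the crossings.
* `nsd`: $100\,\sigma(|x| - |x_\mathrm{ref}|)/\sigma(|x_\mathrm{ref}|)$
  with the *population* standard deviation (divide by $N$; configurable).

The matched reference for all with/without comparisons is the same
geometry with the skull medium replaced by brain tissue
(`without_skull()`), so both signals traverse identical thicknesses and
the skull layer alone differs.

## Study conditions and what the tests show

The shipped scenario presets are the package's reference conditions: the
standard media set above; geometry $h$ = 7 mm, $k$ = 10 mm, $r_0$ = 1 mm,
$T$ = 5 cm with $d$ = 1.7 cm (`"fig2-min"`, 0.025-inch detector) or $d$ =
2.7 cm (`"fig6"`, 0.25-inch detector); $f_s$ = 50 MHz, 64 frequencies,
100 × 100 mesh, 20-reflection budget. Thickness sweeps cover 0.5–9.61 mm
(mouse through thick human frontal bone) and depth sweeps 1–3 cm. The
acceptance suite runs these full-size conditions (8.5 scenario pairs,
about a minute in total); the unit/property tests use scaled-down meshes
(5–15 cells per side) and 4–32 frequency bins, which exercise every code
path at identical physics.

What passing tests do *not* show: the simulator models flat, smooth,
homogeneous layers. Real skulls are curved, rough at sub-wavelength
scales, porous (diploë), and laterally heterogeneous; none of that is
represented, so agreement at these conditions does not validate the model
against real transcranial data — only against the layered-medium physics
it implements.

## Known limitations

* **Geometric spreading ignores refraction divergence.** Amplitudes decay
  as $r_0/\mathrm{path\ length}$. Refraction at the fast skull actually
  spreads ray tubes further (an effect growing as the target approaches
  the skull); a dynamic-ray-tracing spreading factor would capture it.
  This is the main reason simulated attenuation is nearly independent of
  target depth at fixed skull thickness: with matched geometry the
  spreading ratio cancels, interface and absorption losses dominate, and
  both are depth-insensitive at these apertures. Reported
  depth-dependent attenuation variations of tens of percentage points
  cannot be reproduced by *any* energy-conserving flat-layer model whose
  impedance chain already caps two-interface transmitted pressure at
  ≈0.38 of the incident amplitude: the corresponding ≈62% floor is what
  this engine shows (and it is consistent with ex vivo skull
  measurements, which sit at ≈60–85% attenuation for 0.5–9 mm of bone).
* **Dispersion direction vs. measured time shifts.** With the printed
  Kramers-Kronig sign, low frequencies travel *slower* than the 1-MHz
  reference speed, so the measured envelope advance of a transcranial
  pulse (band ≈0.2 MHz, group speed ≈2820 m/s) lands ~4% *below* the
  non-dispersive $\Delta t$ formula. In the $\alpha_0 \to 0$ limit the
  engine converges to the analytic value, confirming the gap is pure
  dispersion, not an engine artifact.
* **Reverberation is same-corridor.** Echoes re-traverse their own skull
  chord rather than walking laterally to neighboring detector cells;
  with a 100 × 100 mesh the aggregate over cells approximates the true
  lateral redistribution well, but individual-cell echo timing is
  approximate.
* **Frequency sampling.** 64 bins at 50 MHz put only two bins inside the
  source's main lobe. The per-bin response varies smoothly, so the
  convolution interpolates acceptably, but narrowband spectral features
  of the response below the 0.39 MHz bin spacing are not resolved.
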