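# skullray

Deterministic ray-tracing simulation of transcranial photoacoustic (PA)
signals in R.

PA brain imaging records laser-induced ultrasound through the skull, and
the skull corrupts the signal: impedance mismatch and power-law absorption
attenuate it, frequency-dependent attenuation and dispersion broaden it,
the ~2× faster bone sound speed shifts its arrival earlier, and
reverberation between the skull faces appends ringing. Full-wave
(pseudo-spectral / FDTD) solvers capture this but scale with the acoustic
volume and frequency; `skullray` instead traces rays per frequency through
a flat layered head model, assembles a per-frequency impulse response at
the detector, and convolves it with the short-time Fourier transform of
the source pulse. Runtime scales with rays × frequencies — a full
10⁴-ray, 64-frequency scenario runs in seconds — making systematic
thickness/depth sweeps and aberration studies cheap.

The physics core:

* **Media** — power-law absorption α(f) = α₀ (f/1 MHz)^y (Np/cm
  convention) with the causally linked Kramers-Kronig dispersive phase
  speed, per mode (longitudinal/shear).
* **Interfaces** — plane-wave pressure transmission with
  longitudinal↔shear mode conversion at the fluid–solid interface
  (`TL = (ρf/ρs)·2ZL cos2θS / (ZL cos²2θS + ZS sin²2θS + Zf)`, etc.),
  intensity coefficients with energy closure IL + IS + Ir = 1, Snell
  critical angles, and a boundary-condition solver for the solid→fluid
  crossing (no standard closed form), validated by energy-flux closure.
* **Source** — the N-shaped pulse of a spherical absorber under Gaussian
  laser excitation: p ∝ −((t−τ)/τe)·exp(−½((t−τ)/τe)²)/r with
  τe = √(τa² + τl²), τa = r₀/c₀.
* **Engine** — Fermat/Snell path finding by vectorized bisection,
  per-segment absorption/dispersion, interface factors, 1/r spreading,
  same-mode reverberation with a 20-reflection budget, arrival binning at
  1/fs; then STFT → per-bin convolution → inverse STFT.
* **Metrics** — peak attenuation %, envelope-duration broadening %,
  envelope cross-correlation time shift, 3-dB bandwidth, normalized
  standard deviation (NSD).

## Worked example

Simulate the deep-target scenario (7 mm skull, absorber 2.7 cm below the
inner-skull surface, 0.25-inch detector) and its matched skull-free
reference, and quantify the distortions:

```r
library(skullray)

sc <- scenario_preset("fig6")
sc
#> <pa_scenario> h=7 mm, d=2.7 cm, k=10 mm, T=5 cm, r0=1 mm, rd=6.35 mm
#>   fs=50 MHz, 64 freqs, mesh 100x100, max 20 reflections

res <- compare_with_without(sc)   # ~3 s
res$report
#>   attenuation_pct broadening_pct time_shift_us bw_with_MHz bw_without_MHz
#>              71.3             89          2.11       0.117          0.271
```

Reading the numbers: the skull removes 71% of the peak pressure, nearly
doubles the envelope duration, advances the arrival by 2.1 µs (the
non-dispersive prediction `time_shift_analytic(7e-3, 1500, 2900)` is
2.25 µs; the dispersive band travels slightly slower than the 1-MHz
reference speed), and narrows the received 3-dB bandwidth from 0.271 MHz
to 0.117 MHz — the skull acting as a low-pass filter.

Plane-wave coefficients at the tissue/skull interface:

```r
m <- table1_media()
intensity_coefficients(m$tissue, m$skull, c(0, 15, 30) * pi / 180)
#>   theta_i     TL      TS     IL     IS     Ir
#>    0.0000 0.8631  0.0000 0.4139 0.0000 0.5861
#>    0.2618 0.8625 -0.2115 0.1916 0.0259 0.7825
#>    0.5236 1.2513 -0.2862 0.1330 0.0478 0.8191
```

At normal incidence no shear is generated; by 30° almost 5% of the
incident energy converts to shear, and beyond the 31.2° longitudinal
critical angle only shear enters the bone.

Scenarios can also come from YAML configs with explicit units (see
`inst/extdata/fig6.yaml`), and a thin CLI wraps the same functions:

```sh
Rscript inst/cli/skullray simulate --config inst/extdata/fig6.yaml --out received.csv
Rscript inst/cli/skullray coeffs --angles 0:85:1 --out coeffs.csv
Rscript inst/cli/skullray metrics with.csv without.csv
```

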