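---
title: "Models and methods behind the fccs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fccs package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccs)
```

This vignette explains the physical models the package implements, the
numerical choices made where the method leaves them open, what the synthetic
data emulate (and what they do not), and the known limitations. It states no
empirical result beyond what the package's own tests and acceptance script
compute.

## The measurement

Fluorescence cross-correlation spectroscopy monitors photon count
fluctuations from two spectrally separated detection channels observing a
confocal volume. The normalized correlation of channels $a$ and $b$,

$$G_{ab}(\tau) = \frac{\langle F_a(t)\,F_b(t+\tau)\rangle}
                      {\langle F_a\rangle\langle F_b\rangle},$$

has a fluctuation amplitude $G(0^+)-1$ inversely proportional to the number
of independently diffusing fluorescent particles in the observation volume.
For the cross channel, only double-labeled complexes contribute, which is
what makes the method a live-cell dimerization assay.

## Correlation models

### Autocorrelation

Each autocorrelation channel is fitted with two freely diffusing components
and one triplet (reversible dark) state:

$$G(\tau) = 1 + \left[1 + \frac{F_t\,e^{-\tau/\tau_t}}{1-F_t}\right]
\frac{1}{N}\left[
F_1\Big(1+\tfrac{\tau}{\tau_{D1}}\Big)^{-1}
     \Big(1+\tfrac{\tau}{S^2\tau_{D1}}\Big)^{-1/2}
+ (1-F_1)\Big(1+\tfrac{\tau}{\tau_{D2}}\Big)^{-1}
     \Big(1+\tfrac{\tau}{S^2\tau_{D2}}\Big)^{-1/2}\right]$$

with $N$ the mean molecule number in the effective volume, $F_t$ and
$\tau_t$ the triplet fraction and relaxation time, $F_1$ the fast-component
fraction, $\tau_{D1} \le \tau_{D2}$ the diffusion times and $S = z_0/\omega$
the structure parameter of the 3D Gaussian volume. Two transcription choices
deserve note: the triplet exponential is implemented in its decaying form
$e^{-\tau/\tau_t}$ (a growing exponential cannot describe a relaxing dark
state), and the axial de-correlation term carries $S^2$, the standard 3D
Gaussian form consistent with the volume calibration below.

### Cross-correlation

The cross channel uses the same two-component diffusion kernel without a
triplet term, and its amplitude is tied to the channel molecule numbers:

$$G_c(\tau) - 1 = \frac{N_c}{N_g N_r}\,[\,\ldots\,],$$

so with $N_g$, $N_r$ fixed from the two autocorrelation fits, the fitted
amplitude directly yields the number of double-labeled complexes $N_c$.

### Derived statistics

* **RCA** $= N_c / N_g$: fraction of green-labeled molecules in complexes.
  The green channel is the denominator by the assay's convention (the
  protein of interest carries the green tag); `computeRCA(..., denominator =
  "min")` offers the conservative alternative. Values marginally above 1 are
  clipped with a warning — they arise from fit noise, not biology.
* **CPM** $= FI / N$: mean count rate over fitted molecule number, the
  molecular brightness. A homodimer with two identical fluorophores doubles
  it.
* **Volume calibration**: a reference dye of known $D$ (ATTO488,
  400&nbsp;µm²/s, green; Rhodamine B, 427&nbsp;µm²/s, red) fitted with a
  single component gives $\omega = \sqrt{4 D \tau_D}$, $z_0 = S\omega$,
  $V_{\mathrm{eff}} = \pi^{3/2}\omega^2 z_0$. The DNA-bound diffusion
  coefficient is the exact inverse, $D = \omega^2/(4\tau_{D2})$; the package
  treats the two as a round-trip identity and tests it to machine precision.
* **Bound fraction** $= 100(1 - F_1)$ from a two-component fit.
* **Group comparison**: classic pooled-variance two-sided Student's t-test,
  the convention for comparing per-cell RCA/CPM/D values between treatment
  groups.

## Fitting: numerical choices

The fits are weighted least squares (weights $1/\mathrm{sd}^2$ when per-lag
standard deviations from repeat measurements are available, unity otherwise)
by Levenberg–Marquardt (`minpack.lm`). Design choices:

* **Constraints by reparameterization.** $N, \tau_{D1} > 0$ on the log
  scale; $F_t, F_1 \in (0,1)$ by logit; $S > 1$ via $\log(S-1)$; and the
  ordering $\tau_{D2} \ge \tau_{D1}$ enforced by
  $\tau_{D2} = \tau_{D1}(1 + e^u)$, so the optimizer cannot leave the
  physical region or cross the components.
* **Triplet time bounds.** $\tau_t$ is constrained to 0.1–100&nbsp;µs
  (log-logistic). Unbounded, the triplet term can trade off against the
  millisecond diffusion decay (a dark state relaxing at $\sim\tau_D$ is
  indistinguishable from diffusion), which sends $N$ and $F_t$ to
  boundaries. The bound encodes the photophysical time scale of real
  fluorophore dark states.
* **Multi-start.** The two-component model has a classic degeneracy: a very
  slow second component mimics a baseline offset. Each fit is therefore
  restarted from a small set of perturbed starting points (shifted
  $\tau_{D1}$, $\tau_{D2}$, $F_1$) and the lowest weighted residual norm
  wins.
* **Initialization.** Amplitude-based: $N_0 = 1/(G(\tau_{\min})-1)$,
  diffusion times from the half-amplitude decay lag. No manual seeding is
  needed.
* **Fixing parameters.** Any subset may be fixed. The analysis convention
  for live-cell data fixes $\tau_{D1}$ at the globally determined
  free-protein value (700&nbsp;µs) to sharpen the slow-component estimates —
  the package's tests verify that this reduces the across-seed variance of
  $\tau_{D2}$ — and fixes $S$ from the dye calibration.
* **Convergence reporting.** Solver termination on the function/parameter
  tolerances, or at the point where machine arithmetic permits no further
  reduction, is reported as converged; anything else (iteration limit) is
  flagged, with parameters still returned. Fits where the two diffusion
  times collapse within 10% are flagged `degenerate-components`.
* **Lag-zero exclusion.** The smallest usable lag is one bin: in photon
  counting the zero-lag point is dominated by shot noise (and, on real
  hardware, afterpulsing), so it is never fitted.

## Correlators

`correlateDirect()` evaluates the definition at every multiple of the bin
width (cost $O(n\,\mathrm{lags})$) and serves as the reference
implementation. `correlateMultitau()` implements the Schätzel-style
multi-tau scheme: 16 linear lag channels per block, rebinning by 2 after
each block, yielding the quasi-logarithmic grid hardware correlators
produce. Both use *symmetric normalization* — channel means computed over
the overlapping segments at each lag — which reduces bias from slow drifts;
the first block is arithmetically identical to the direct estimator, and
each later block is identical to the direct estimator applied to the
correspondingly rebinned trace (both tested exactly). At rebinned lags the
multi-tau estimate differs from the un-rebinned direct estimate by the
triangular binning kernel; for signals varying slowly relative to the
rebinned width the difference is below $10^{-3}$ (tested on a smooth trace).
`splitAndAverage()` emulates the repeat-measurement protocol (ten 20-s
acquisitions per cell is typical): the trace is split into equal segments,
each correlated, and the per-lag mean and SD returned — the SDs feed the
weighted fits.

## The synthetic-data generator

`simulatePhotonTrace()` is a Brownian-dynamics forward model: point emitters
in a periodic box receive independent Gaussian displacements of standard
deviation $\sqrt{2D\Delta t}$ per coordinate per step; the detection
efficiency at position $(x,y,z)$ is
$\exp(-2(x^2+y^2)/\omega^2 - 2z^2/z_0^2)$; triplet blinking is a two-state
telegraph process whose stationary dark fraction and relaxation time equal
the species' $F_t$, $\tau_t$; per-bin photon counts are Poisson draws on the
integrated detected intensity plus background. Identical seeds give
bit-identical traces.

Deliberate generator choices:

* **Defaults are the study conditions.** $\omega = 0.2$&nbsp;µm,
  $z_0 = 1.0$&nbsp;µm ($S = 5$), consistent with the ATTO488 calibration
  constants ($\omega = \sqrt{4 \cdot 400 \cdot 25\,\mu s}$); fast species at
  $\tau_{D1} = 700$&nbsp;µs ($D \approx 14.3$&nbsp;µm²/s in this volume);
  DNA-bound species at $\tau_{D2} = 50$&nbsp;ms ($D = 0.2$&nbsp;µm²/s),
  i.e. $\tau_{D2} \gg \tau_{D1}$.
* **Closed box, fixed molecule number.** `round(countMean)` molecules are
  conserved under periodic boundaries (constant mean concentration); the box
  must be at least 5× the volume radii so periodic images do not correlate.
* **Brightness convention.** The species brightness is the *apparent*
  counts-per-molecule — detected photons/s per molecule averaged over the
  effective volume — so a perfect measurement's $FI/N$ recovers it directly;
  the peak emission rate at the volume center is $2\sqrt{2}$ times larger
  (the 3D Gaussian $\gamma$-factor). This makes the generator's mean
  intensity exactly `countMean * Veff/Vbox * brightness`, the identity the
  tests check.
* **Noise model for synthetic curves.** `generateModelCurves()` adds
  Gaussian perturbations of SD `noiseSd * (G - 1)` — multiplicative on the
  fluctuation part. No noise model is standard in the literature for fitted
  curves; this one matches the empirical scaling of FCS residuals and keeps
  the $G \to 1$ tail well-behaved.
* **Dose-response plateaus.** The published dose-response is anchored by
  $IC_{50} = 1250$&nbsp;nM and slope $-0.66$; the RCA plateaus are not
  printed, so the generator defaults to top = 0.45 (untreated dimerization
  level typical of this assay) and bottom = 0.10 (near the negative-control
  level), chosen once as realistic values. The "2% noise" condition is an
  absolute response SD of 0.02.

What the generator does **not** emulate: detector afterpulsing and dead
time, spectral cross-talk between channels, photobleaching, cell-boundary
confinement, anomalous diffusion. Passing tests therefore demonstrate the
correctness of the estimators and fits under ideal photophysics, not
robustness to instrument artifacts in real data.

## Problem sizes and reproducibility

Simulation-based checks use 1–5&nbsp;s traces at 20&nbsp;µs bins with
60–100 molecules in a $1.2 \times 1.2 \times 5$&nbsp;µm box and medians over
3–10 seeds; curve-based checks use quasi-logarithmic grids spanning
1&nbsp;µs–1&nbsp;s and medians over 10–50 seeds. These sizes give relative
errors comfortably inside the tolerances asserted (a few percent for
amplitudes and diffusion times) while keeping the whole suite fast. All
randomness is seeded; `runPipeline()` reruns are byte-identical.

## Known limitations and open choices

* **IC50 sampling distribution.** At the generator's conditions (8 doses
  spanning 10&nbsp;nM–30&nbsp;µM, triplicate, shallow slope), a few percent
  of noisy realizations are best fitted — in the strict least-squares sense —
  by a shallower, right-shifted curve, so the IC50 estimator has a heavy
  right tail. Central tendency across seeds is therefore summarized by the
  median throughout (the pharmacological pIC50 convention would be the
  natural alternative).
* **Volume mismatch.** The green and red observation volumes are treated as
  one shared volume; the analysis equations carry no channel-specific volume
  correction, so chromatic aberration biases RCA in real instruments but not
  in the simulations.
* **Cheng–Prusoff.** The kinase assay convention is
  $[\mathrm{ATP}] = K_m$, giving $K_i = IC_{50}/2$; predictions at cellular
  ATP require the kinase's ATP $K_m$, which must be supplied by the user.
* **Model scope.** No three-component fits, no anomalous-diffusion
  exponents, no maximum-entropy diffusion-time distributions, no photon
  counting histogram analysis.
* **Interfaces.** This is an analysis package: the end-to-end entry point is
  the exported `runPipeline()` (manifest in, tidy CSV + JSON out) rather
  than a shell command; all IO is plain CSV/JSON with units in the column
  names, and instrument exports with microsecond lag grids are accepted via
  a units flag.
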