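---
title: "Methods: from tracked filaments to motor response coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tracked filaments to motor response coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliabeat)
```

This vignette is the package's own account of its science: the waveform
model, the shape-space reduction, the mechanochemical boundary-value
problem, and the numerical and design choices behind each stage. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The waveform model and its gauges

A tracked recording is a series of 25 (by default) points along a beating
filament. The shape at each instant is fully described by the tangent angle
ψ(s, t) on normalized arc length s ∈ [0, 1], and the periodic beat is
parameterized as a travelling wave

$$\psi(s,t) = a(s)\cos(2\pi f t + \varphi(s)),$$

after two gauge corrections that remove everything that is not dynamic
shape:

* **Co-swimming frame.** The per-frame arc-length mean of ψ is subtracted.
  This removes the rigid-rotation mode (a freely swimming filament rotates
  as it beats) and is our operational definition of the co-swimming frame.
  The same subtraction is applied to model waveforms, so data and theory
  are always compared in the same gauge. Other constructions of the
  co-swimming frame exist (e.g. via hydrodynamic torque balance); ours is
  chosen because it is exactly invariant under rigid rotation of the
  coordinates and identically applicable to theory — the package never
  mixes gauges.
* **Static mode.** The per-position time mean (the time-averaged curvature,
  biologically the mean bend of the axoneme) is subtracted before spectral
  analysis.

An important and easily missed consequence, verified numerically during
development: the co-swimming gauge *changes the amplitude profile*. If one
builds $a(s)e^{i\varphi(s)}$ with a symmetric $a(s)$ and then subtracts the
complex arc mean, the modulus of the result can have markedly different
Legendre coefficients (in a typical wild-type-like construction the
parabolicity moves from 0.35 to 0.15). All shape features in this package —
experimental and theoretical alike — are therefore defined on the gauged
mode, and the synthetic generator prescribes its target features in the
same convention (Section 5).

## 2. Discretization: the chord-midpoint grid

Tangent angles are computed from chords of consecutive tracked points and
naturally live at the chord midpoints. For 25 equally spaced points these
are the 24 positions $s_i = (2i-1)/48$, a uniform grid that is symmetric
under $s \to 1-s$ and whose plain average is a midpoint-rule integral over
the *full* interval [0, 1]. We keep the profiles on this grid end to end:
24 amplitude and 24 phase samples (48 numbers) enter the model fit.

This choice is deliberate. An interior grid that drops the basal point
(s = 1/24, …, 1) truncates [0, 1/24] asymmetrically, and with 24-point
trapezoidal quadrature that truncation biases the measured amplitude
asymmetry by about +0.15 — large enough to make a perfectly symmetric
waveform appear asymmetric and to swamp the wild-type identity ā₁ ≈ 0. On
the midpoint grid a symmetric profile has exactly zero asymmetry.

Arc-length integrals on any grid use *cell weights* (each sample owns the
cell between neighbouring midpoints, extended to 0 and 1): midpoint rule on
the native grid, trapezoid on inclusive grids. Legendre coefficients are
computed from these weighted products with the small discrete
non-orthogonality removed through the Gram matrix, which makes the
decomposition exact on polynomials through the requested order on any
grid; residual quadrature error on generic smooth profiles is of order
10⁻³–10⁻² at 24 points, and the test suite asserts exactly that level.

## 3. Spectral estimation

* **Periodogram.** Per-position Hann-windowed periodogram; the local beat
  frequency f(s) is the parabolic-interpolated peak (zero-frequency bin
  excluded) and f = ⟨f(s)⟩.
* **Q-factor.** Beat regularity needs a scalar measure; we define
  Q = (peak frequency)/(FWHM of the arc-length-averaged PSD peak), with
  the FWHM floored at one bin. For noiseless finite records Q is
  window-limited; its value is only meaningful comparatively, and the
  tests assert monotonicity against injected phase noise rather than an
  absolute number.
* **Harmonic fraction.** Power within ±1 bin of mf for m ≥ 2, relative to
  all harmonic neighbourhoods m ≥ 1, on the arc-averaged PSD. With a Hann
  window a bin-centred tone puts all its energy within ±1 bin, so the
  bookkeeping is exact in the calibrated test and accurate to ~1%
  off-centre.
* **Fundamental mode.** The complex amplitude at each position is the
  Hann-windowed discrete Fourier transform evaluated at the *interpolated*
  peak frequency (window gain compensated), not at the nearest integer
  bin: at a half-bin offset Hann scalloping would attenuate amplitudes by
  ~15%, which is far larger than the 0.02 rad round-trip accuracy we
  require. Phase is unwrapped along s and the arbitrary global phase is
  fixed by φ(first point) = 0.

## 4. The boundary-value problem and its closure

With time dependence $e^{2\pi i f t}$, the linearized force balance is

$$i\,\bar{Ma}\,\psi = -\partial_s^4\psi + \partial_s^2 f_{sl},
\qquad f_{sl} = k\,\Delta + \beta\,\partial_s\psi,$$

with $\Delta(s) = \Delta_b + \psi(s) - \psi(0)$,
$\bar{Ma} = 2\pi f \xi_n L^4/\kappa$, and boundary conditions
$\partial_s\psi(0) = F_b$, $\partial_s\psi(1) = 0$,
$\partial_s^2\psi(0) = f_{sl}(0)$, $\partial_s^2\psi(1) = f_{sl}(1)$,
plus the global sliding balance $\int_0^1 f_{sl}\,ds = F_b = \chi_b\Delta_b$.
Defaults κ = 580 pN·μm² and ξₙ = 0.0049 pN·s·μm⁻² are standard values for
reactivated axonemes; Ficoll media multiply ξₙ by 1.1 / 1.6 / 3.2 for
1% / 5% / 10%. Because the regime of interest has $\bar{Ma}/(2\pi)^4 \ll 1$,
results are insensitive to moderate changes in these constants.

The general solution is a combination of four exponentials $e^{x_j s}$
with $x_j$ the roots of $x^4 - \beta x^3 - k x^2 + i\bar{Ma} = 0$
(confluent basis $s\,e^{xs}$ when roots coincide within 10⁻⁶; the
characteristic-roots helper flags these). The five homogeneous conditions
in the four coefficients plus $\Delta_b$ admit a non-trivial solution only
when the 5×5 determinant vanishes. With (k, β′, β″, Mā) fixed, the system
is over-determined unless one more unknown closes it; we close through the
basal response: χ_b enters the determinant affinely (it appears only in the
Δ_b column), so det = 0 has the closed-form root χ_b = d₀/(d₀ − d₁) with
d₀, d₁ the determinants at χ_b = 0 and 1. This is consistent with the
observation that fitted basal responses are small, and it makes the
solution for given (k, β′, β″) generically unique — the discrete solution
family reappears only through the wavenumber of the resulting waveform,
which is why the fit enforces the lowest-wavenumber rule (Section 6). The
nullspace is extracted by SVD (condition number guarded at 10¹²); boundary
and balance residuals are checked to 10⁻⁸ on every solve, and the returned
waveform is gauged with its *exact* arc mean (the basis functions have
closed-form integrals) and normalized to unit RMS.

In the dry-friction limit Mā → 0, χ_b → 0, the curvature takes the closed
form $\partial_s\psi = e^{\beta' s/2}\sin(n\pi(s-1))\,e^{i\beta'' s/2}$ on
branches $cd = i\pi n$ with $c = \beta/2$, $d = \sqrt{1 + 4k/\beta^2}$
(the square root is forced by consistency of the exponents $c(1\pm d)$
with the characteristic roots), giving $k = ((\beta'')^2 - 4\pi^2n^2)/4$
for real stiffness (which forces β′ = 0) and λ/L = −4π/β″. The test suite
verifies that the full solver collapses onto this closed form to <1%
relative L² as Mā → 0 and that the solved χ_b vanishes.

## 5. The synthetic generator

The generator emulates what the analysis assumes about real recordings:

* travelling-wave dynamics with a weak second harmonic (a travelling wave
  at 2f with doubled phase slope; its amplitude is set from the prescribed
  dynamic-power fraction, <10% by default);
* a static mode, modelled as a constant-curvature arc (zero for the
  *mbo2*-like condition, which beats without a static bend);
* hierarchical variability: per-axoneme parameters are normal around
  condition means, truncated at physical bounds (f > 5 Hz, L > 2 μm,
  a₀ > 0). The default eight conditions span slow/fast/viscous/mutant-like
  phenomenologies with frequencies inside 15–160 Hz and lengths inside
  7.2–15.4 μm; the within-condition frequency sd (12 Hz) is chosen so the
  between/within variance ratio of the default panel is of order the ~7
  observed across real condition panels, while amplitude means vary little
  between conditions relative to their within-condition spread. All
  numbers are generator choices, documented in the returned specs;
* coordinates produced by integrating the tangent angle from a fixed base
  with segment length L/(n−1), plus i.i.d. 10 nm isotropic localization
  noise per point (tracking-noise magnitude is not a measured quantity;
  10 nm stands in for nanometre-precision tracking);
* acquisition defaults 1000 fps, up to 3000 frames, 25 points, with a
  Nyquist guard on the highest synthesized tone.

Because all downstream features live in the co-swimming gauge and the
pipeline's quadrature convention (Sections 1–2), the generator adjusts its
construction parameters by a damped fixed-point iteration until the
*pipeline-convention* features of the synthesized mode equal the sampled
targets; without this, gauge and quadrature shifts of order 0.03–0.15 in
ā₂/ā₁ would make ground truth and measurement incommensurable. Phase
defaults are φ₁ = −π (λ = L, the typically observed ratio) and φ₂ = −ā₁
(emulating the observed anti-correlation between amplitude asymmetry and
phase parabolicity).

What the generator does **not** emulate: pixel-level imaging and tracking
artifacts (correlated localization errors, segment-length jitter),
swimming translation/rotation (the analysis is invariant to it),
three-dimensional torsion, frequency drift within a recording, and —
importantly — in `empirical` mode the waveforms are Legendre-parameterized
shapes, *not* exact solutions of the mechanical model. Fits to empirical-
mode waveforms therefore plateau at R² well below 1 and say nothing about
real-data fit quality; parameter-recovery claims are always tested on
`mechanical`-mode data, where the ground truth lies in the model family.

## 6. Fitting

The score is
$R^2 = 1 - \sum|\psi_{exp} - z\,\psi_{the}|^2 / \sum|\psi_{exp}|^2$ with
the complex least-squares scale
$z = \sum \bar{\psi}_{the}\psi_{exp} / \sum|\psi_{the}|^2$, both profiles
arc-length-mean-subtracted. This weighs real and imaginary parts equally
and is invariant to overall complex rescaling of either profile; whether
the original score weighted amplitude and phase differently is not
determinable from the available description, so ours is declared rather
than inferred.

Optimization is Powell's derivative-free direction-set method (implemented
in-package over `stats::optimize` line searches; no installed package
provides a principal-axis optimizer), with k = eᵘ enforcing positivity,
relative tolerance 10⁻⁶ and ≤2000 model evaluations per start, from the
three standard starts (3π², 0, −4π), (1.7, −2.1, −5.8), (3π², 0.15, −9.6).
Three robustness measures matter in practice:

* each start is first seeded by a coarse scan over β″ ∈ [−16, −3] (the r2
  landscape is multimodal in β″, with valleys between wavenumber basins);
* the search is restarted from its own optimum with a fresh direction set
  and shrinking steps until no further improvement, which rescues the
  long flat valleys where (k, β′, β″) trade off almost exactly;
* candidates are rejected if their curvature winds more than 2.5 turns
  (the lowest-wavenumber rule) or leave the physiological box k ∈ [0.05,
  100], β′ ∈ [−6, 6], β″ ∈ [−18, 5] — outside it the model family contains
  high-stiffness, short-wavelength solutions that can shadow noisy data.

β″ is not constrained negative during the search; non-propagating optima
(β″ ≥ 0) are rejected afterwards. Solutions are accepted per start and the
best of the three is returned with its solved χ_b and wavenumber. On a
3×3×3 grid spanning k ∈ {10, 20, 30}, β′ ∈ {−2, 0, 2}, β″ ∈ {−14, −10, −7}
at Mā = 50, all parameters are recovered from noiseless model waveforms to
within 1% with R² > 0.999 (asserted in the test suite).

## 7. Shape-space statistics

* `variance_explained()` uses pooled residuals after least-squares
  projection on orders ≤ n, with the order-0 (mean-amplitude) content
  excluded from the denominator — only shape variation is of interest.
  Whether to pool per-axoneme or across profiles is a genuine choice; we
  state the pooled definition and use it consistently.
* `pca_correlations()` runs PCA on mean-centred normalized amplitude
  profiles a(s)/a₀ (centering/normalization is again our stated choice)
  and fixes component signs so corr(ā₁, pc1) ≥ 0 and corr(ā₂, pc2) ≥ 0.
* `variance_components()` is the unbalanced one-way method-of-moments
  estimator (effective replicate number n₀), floored at zero, with
  singleton conditions excluded; it matches the informal between/within
  variance comparison the domain uses, rather than a likelihood fit.
* `energetics_envelope()` returns the tightest a₀ ∝ f^(−1/2) (elastic
  dissipation) and a₀ ∝ f^(−1) (viscous dissipation) bounds over a
  feature table.

## 8. Problem sizes and known limitations

The test suite synthesizes short recordings (64–2048 frames at 25 points)
and fits at most a few dozen axonemes; these sizes were chosen so the
full suite documents every claim in well under an hour on one core while
keeping every spectral estimate far above its resolution limit (≥30 beat
cycles per record where frequencies are asserted to one bin). The
acceptance script solves three deterministic model configurations and runs
in seconds.

Limitations worth keeping in mind: the model is linear (a solution of the
beating instability near onset — amplitudes are predicted up to scale, and
amplitude selection is outside its scope); the beat frequency is an input,
not predicted; three-dimensional components (twist) are not modelled; the
co-swimming gauge and R² definitions are internally consistent operational
choices that may differ from other groups' conventions by a frame or
weighting; and fits to waveforms far outside the model family (or with
several wavelengths on the filament) will ride the declared search bounds
and should be judged by their reported R² and flags, not their parameter
values alone.
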