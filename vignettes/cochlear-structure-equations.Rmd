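---
title: "Coherent-state filterbanks and the structure equations of cochlear signal processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherent-state filterbanks and the structure equations of cochlear signal processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleate)
```

## The model and its assumptions

The cochlea maps a pressure signal $f(t)$ to a basilar-membrane
displacement $u(x, t)$, $x$ the place along the duct.  Three empirical
facts anchor the model:

* **Quasilinearity.**  At a fixed sound level the map $f \mapsto u$ is
  close to linear; the compressive nonlinearity across levels is handled by
  a family of linear models indexed by a level parameter $c$
  ($c \approx 1$: high level; $c \gg 1$: low level).
* **Tonotopy and scaling.**  Each place has a characteristic frequency
  $\xi(x) = K e^{-x/l} - S$ ($S = 0$: the classical exponential law;
  $S > 0$: the physiological, shifted form).  Under the exponential law the
  transfer function is a function of the scaling variable $\omega/\xi(x)$
  alone, so the response is a wavelet transform.
* **Phase invariance.**  The Hilbert transform commutes with time shifts
  and dilations; the full invariance group of hearing is taken to be the
  affine group times the circle group.

The package's central modelling assumption is that the cochlear filter at
each level $c$ is the *extremal function* of the uncertainty inequality for
that group — the analogue of the Gaussian coherent states of the
Heisenberg group.  On $\omega > 0$,

$$h_c(\omega) = k\,e^{i\varepsilon}\,\omega^{\kappa - 1/2}
  e^{-i(\alpha\log\omega + \beta\omega)}\, e^{-(\kappa/c)\,\omega^c},$$

conjugate-symmetrically extended, and the transfer function at place $x$
is $\hat g_c(x,\omega) = \sqrt a\, h_c(a\omega)$ with $a = 1/\xi(x)$.
`uncertainty_gap()` verifies extremality numerically: the inequality gap
vanishes for $h_c$ (and all its dilates and phase rotations) and is
strictly positive for perturbed functions.

### Parameters

| parameter | meaning | default (preset `fig1`) |
|---|---|---|
| $c$ | linearisation level (dimensionless) | 1 |
| $\kappa$ | sharpness; $Q$ grows with $\kappa$ | 4 |
| $\alpha$ | logarithmic phase coefficient (rad) | $-\pi$ |
| $\beta$ | pure delay in CF cycles/$2\pi$ (scale-invariant time) | $2\pi$ |
| $\varepsilon$ | constant phase offset (rad) | $2\pi$ |
| $K, l, S$ | tonotopy: base frequency (Hz), length constant (mm), shift (Hz) | 20000, 6.6, 0 (200 shifted) |

The parameterisation is self-normalising: the generalised frequency
localisation $\nu_c(h_c) = (\int \omega^c |h|^2 / \int |h|^2)^{1/c}$ equals
1 exactly, so $\hat g_c(x,\cdot)$ is localised at $\xi(x)$.  The modulus
peaks *below* the localisation, at $\xi(x)(1 - 1/2\kappa)^{1/c}$, moving up
toward $\xi(x)$ with increasing $c$ — the level dependence seen in
basilar-membrane data.  Presets `fig2` (phase example), `fig5` (impulse,
$\kappa = 12$) and `fig6` (glide, $\gamma = 32\pi$) carry the worked
parameter sets; `fig5`'s $\alpha = -\pi$, $\beta = 4\pi$ are this package's
choice (the source figure fixes only $\kappa$ and the 200 Hz place; the
chosen delay is two CF cycles, and the acausality diagnostic below is
evaluated with it).

## The structure equations

The analytic response
$Zf(a,t) = 2\sqrt a\int_0^\infty \hat f(\omega) h_c(a\omega)
e^{i\omega t} d\omega$ satisfies, exactly at $c = 1$ and in the linearised
sense otherwise,

$$a\,\partial_a \log Zf = (A + iB) + (C + iD)\,\partial_t \log Zf,$$

with dilation-group coefficients $A = \gamma$, $B = -\alpha$,
$C = -a\beta$, $D = a\gamma$, $\gamma = c\kappa$.  Splitting into real and
imaginary parts couples $\log r$ and $\varphi$: complete knowledge of the
phase derivatives determines the amplitude derivatives and conversely
(`exchange_phase_amplitude()`).  For $c \neq 1$ the multiplier
$\omega^c$ is linearised at the localisation point $\omega = 1$
($\omega^c \approx 1 + c(\omega - 1)$); for a pure tone the second equation
still holds exactly at every $c$, while the first carries precisely the
linearisation error of $(a\nu)^c$ at $a\nu = 1$ — both are asserted in the
test suite quantitatively.

**A sign convention, made explicit.**  The phase of $h_c$ carries
$e^{-i\alpha\log\omega}$, which makes the phase-equation constant $-\alpha$
and the coefficient $D = +a\gamma$ in the form above.  This orientation is
forced by two facts about the click response: the instantaneous-frequency
glide rises at $s = \alpha + \beta$ and falls at $s = \beta$, and the
logarithmic phase term breaks phase monotonicity at low frequencies
(irrelevantly, since the amplitude is negligible there).  With the opposite
sign both come out backwards.

### Numerical realisation of the residuals

Derivatives are centred second-order differences on the uniform
$(\log a, t)$ grid; edge rows/columns are excluded, and points below an
amplitude floor ($10^{-6}\times\max|Z|$ by default) are masked, never
interpolated.  Phase differences use $\mathrm{Arg}(Z_{+}/Z_{-})$, which
equals the centred difference of any continuous unwrapping without global
unwrapping.

The complex residual is evaluated by default in the **multiplied-through
form** $a\partial_a Zf - (A{+}iB)Zf - (C{+}iD)\partial_t Zf$ rather than on
$\log Zf$.  The two are equivalent pointwise, but broadband signals have
amplitude nulls where $\log Zf$ has branch singularities; differencing the
log form there leaves an $O(1)$ error on a vanishing fraction of points and
destroys the convergence order, while the linear form converges cleanly at
order 2 (measured ratios 3.99–4.03 under simultaneous grid halving).
`structure_residuals(form = "log")` remains available and is the right
tool for tones and other null-free signals; the two real equations are
always reported in log-polar form under the floor mask.

At $c = 1$, band-limited noise (150–600 Hz) on 256 scale rows spanning the
signal band and $2^{16}$ samples/s gives a relative complex residual of
$9.4\times10^{-5}$ — pure discretisation error.  The scale window matches
the signal band deliberately: the equations are pointwise identities, so
the residual grid need not cover the filter support, and a narrow window
minimises the $\Delta\log a$ step at fixed row count.

## Holomorphic solutions

The equation is an inhomogeneous $\bar\partial$-equation: solutions factor
as $Zf = e^{P(a)} G(z)$ with the time-independent particular part
$P(a) = (\gamma - i\alpha)\log a$ and $G$ holomorphic in
$z = t - a\beta + ia\gamma$ (upper half-plane).  `dbar_residual()` measures
the discrete $\bar\partial$ of $Zf e^{-P}$; it vanishes at $c = 1$ to
second order (per-row normalisation, since $e^{-P}$ rescales rows by
$a^{-\gamma}$).  $G$ is additive over superpositions, and:

* **Pure tone** $A\cos(\nu t + \vartheta)$:
  $G = c_0\, A e^{i\vartheta} \nu^{\gamma - 1/2 - i\alpha} e^{i\nu z}$.
  The free constant $c_0$ is fixed by tangency at the linearisation point
  ($c_0 = k e^{i\varepsilon} e^{\gamma - \kappa/c}$), which makes
  $e^P G = Zf$ exact at $c = 1$.  For $c > 1$ the linearised exponent
  over-estimates the true one everywhere (convexity of $u^c$); the full
  $e^P G$ over-estimates $|Zf|$ on the above-CF side and under-estimates
  far below CF where the response is negligible — no constant makes the
  error one-sided everywhere, because the $(\gamma - \kappa)\log u$ term in
  the log-difference diverges as $u \to 0$.
* **AM tone** $(1 + A\cos\mu t)\cos\nu t$: `am_local_model()` returns the
  $\log(1+x)\approx x$ expansion of $F = \log G$, valid on the scale
  interval where the carrier dominates both sidebands; $F'$ is the carrier
  constant $i\nu$ plus a slow oscillation at $\mu$, matching the measured
  phase-derivative oscillation within 10%.
* **Harmonic complex** (violin-like, $|c_m|$ on a $-2$ dB/index line):
  per-place weights $d_m(a) \propto c_m (m\nu)^{\gamma-1/2-i\alpha}
  e^{-m\nu a\gamma}$ make the $n$-th harmonic dominant at $a = 1/(n\nu)$;
  the local expansion splits a carrier from a $2\pi/\nu$-periodic
  remainder.  Weights are computed in log space ($\nu^{\gamma}$ overflows
  doubles at $\gamma = 32\pi$).  The two-neighbour form of the remainder is
  accurate to 10% for low-to-mid harmonic indices; by $n \gtrsim 5$ at
  $\gamma = 32\pi$ the neighbour terms themselves reach $O(1)$ and the
  expansion premise fails.
* **Click**: $F(z) = K_0 - (\gamma + 1/2 - i\alpha)\log z$ with the
  principal branch ($\arg z \in (0,\pi)$); $K_0$ follows from the Gamma
  integral of $h_1$ and is exact at $c = 1$ (verified to $2\times10^{-12}$
  against the computed response); for $c \neq 1$ it is a one-point
  calibration, not a model claim.  The glide
  $f'(s) = [\gamma(\gamma + 1/2) + \alpha(s - \beta)]/[(s-\beta)^2 +
  \gamma^2]$ rises below $\alpha + \beta$, peaks slightly above 1
  ($1 + 1/2\gamma$ at $s = \beta$), and falls near $\beta$; the envelope
  peak travels as $t^* = a s^*$, $s^* = \beta + \alpha\gamma/(\gamma+1/2)$.

Because the extremal family is invariant under time translation, no member
can be supported on the positive time axis; the impulse response leaks a
small amount of energy into $t < 0$.  `impulse_response()` computes on a
time grid symmetric about 0 so this leakage is measurable: 0.13% for the
`fig5` preset at the 200 Hz place.

## General invariance groups

`group_model()` generalises dilations to the flow $\lambda_a$ of any
vector field $v(\omega)$ (odd extension, $v < 0$ on the working interval).
The conjugation map — $s'/s = -1/v$, anchored $s(\nu_0) = 1$ — turns the
flow into pure dilations, $s(\lambda_a\omega) = s(\omega)/a$, and the
extremal theory pulls back through the isometry
$h \mapsto \sqrt{s'}\,h\circ s$.  Structure-equation coefficients become
scale-dependent: with $\omega_a = s^{-1}(1/a)$ and $q_a = a s'(\omega_a)$,

$$A = \gamma q_a\omega_a,\quad B = -\alpha - \beta(1 - q_a\omega_a),\quad
  C = -\beta q_a,\quad D = \gamma q_a,$$

reducing exactly to the dilation constants for $v = -\omega$
(`model_dilation()`, asserted to $10^{-12}$).  Two concrete models:

* `model_example_1()` — $v(\omega) = -\omega\log(R/\omega)/\log(R/K)$,
  zeros at 0 and at an absolute frequency bound $R$: the conjugate of an
  affine vector field along the place axis.  Signals beyond $R$ are
  invisible to the model (out-of-band response below $10^{-6}$ in energy).
  Closed-form flow and conjugation map are provided and double-checked
  against the quadrature/Runge–Kutta construction.  As $R \to \infty$ the
  dilation group is recovered at rate $1/\log(R/K)$.
* `model_example_2()` — the shift map $s(\omega) = (\omega+S)/(\nu_0+S)$ of
  the physiological tonotopy, blended near $\omega = 0$ by a monotone C¹
  cubic Hermite arc on $(0, \varepsilon)$ (default $\varepsilon = 1$ rad/s;
  the blend location is arbitrary small and irrelevant in the audio range).
  Its scaling variable is the shift-generalised
  $(\omega + S)/(\xi(x) + S)$, and the filter family sharpens from wide
  apical to narrow basal tuning ($Q_{10}$ monotone in CF).

A point the linearisation makes precise: the general structure equations
acquire a model error from linearising $s(\omega)$ around $\omega_a$ even
at $c = 1$ — *unless* $s$ is affine.  Example 2's $s$ is affine, so its
$c = 1$ residuals converge at second order exactly like the dilation case;
example 1's do not (they stall at the model error, a few times $10^{-3}$
on audio-band grids), which is the quantitative form of the qualifier that
the framework's equations remain *approximately* satisfied.

Reconstruction uses the $L^2$-duality formula with the invariant measure
$d\omega/|v|$ and the admissibility constant
$C_h = \int_0^\infty |h_c|^2\, du/u$ evaluated in closed Gamma form, not
fitted to the grid; a band-limited signal is recovered to $8\times10^{-4}$
relative error, and a broadband signal through the banded model returns its
band-limited projection.  Scale grids for warped models are built in
$s$-units (`group_scale_grid()`); near a band edge $s$ diverges, so edge
coverage requires generous low-$a$ margins.

## Synthetic data

The generators (`generator_spec()`/`generate_signal()`) produce the
model's worked inputs: tones, AM tones with $\mu \ll \nu$ enforced,
harmonic complexes with a $-2$ dB-per-index amplitude line plus a seeded
uniform $\pm3$ dB ripple and seeded phases (the source describes "some
oscillation" without a magnitude; $\pm3$ dB matches the spread visible in
violin spectrograms), unit clicks, and flat-spectrum band-limited Gaussian
noise (unit RMS).  Everything is deterministic given the spec's seed.
What these signals do *not* emulate: level-dependent cochlear
compression within a single signal (the model is linear at fixed $c$),
middle-ear filtering, and real instruments' inharmonicity — so a green
test establishes the mathematical identities of the model, not
physiological fidelity.

## Numerical choices

* **Fourier/Hilbert conventions**: $f(t) = \int \hat f e^{i\omega t}
  d\omega$; Hilbert multiplier $-i\,\mathrm{sgn}\,\omega$ (so
  $H\cos = \sin$ and $Zf$ keeps positive frequencies).  The pair is pinned
  by the requirement that the $c = 1$ identities close numerically, which
  the pure-tone tests confirm to $10^{-9}$.
* **FFT analysis**: zero-padding to the next power of two with a 10%
  cosine taper by default; periodic on-bin test signals are analysed with
  `pad = FALSE, taper = 0`, where the discrete transform is exact.
  Rows with CF beyond $0.9\times$ Nyquist/2 are masked with a warning.
* **Quadrature and flows**: adaptive `stats::integrate` everywhere a
  functional is defined by an integral (tolerances $10^{-9}$–$10^{-11}$);
  group flows solved by an embedded Cash–Karp RK45 with relative tolerance
  $10^{-10}$ when no closed form exists; monotone inverses by safeguarded
  root finding.
* **Degenerate inputs**: zero signals reconstruct to zero; fixed points of
  flows are returned exactly; the exchange of phase and amplitude refuses
  $|D| < 10^{-12}$; coefficients refuse localisations at zeros of $v$.

## Known limitations

* The extremal filters are not causal; the model treats the small acausal
  leakage as an approximation error rather than redesigning the filters
  (minimum-phase variants are out of scope).
* The extremal phase is physiologically wrong below roughly half the CF;
  no substitute phase is provided, the region is simply where the
  amplitude mask silences the output.
* Example 1's structure-equation residuals contain an irreducible
  linearisation error; only example 2 (and the dilation model) admit exact
  $c = 1$ factorisation.
* WAV I/O covers mono PCM16/float32 only; multi-channel files are reduced
  to the first channel.
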