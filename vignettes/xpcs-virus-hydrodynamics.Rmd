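---
title: "Methods: small-angle XPCS of dilute Brownian suspensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-angle XPCS of dilute Brownian suspensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxpcs)
```

This note records the models, the tunable parameters, the numerical
choices, and the known limitations behind `saxpcs`. It is the place to
look when a default seems arbitrary: every one of them is argued here.

## The measurement and its two radii

A dilute suspension of monodisperse nanoparticles — the motivating case
is an icosahedral plant virus of roughly 13 nm geometric radius — is
illuminated with a partially coherent X-ray beam, and a photon-counting
area detector several metres downstream records speckle frames at tens
of kilohertz. Two complementary quantities come out of one data set:

* **Statics (SAXS).** Averaging the frames over time and azimuthally
  averaging over detector pixels gives the 1D scattered intensity
  $I(Q)$. For spheres with a Gaussian number distribution of radii
  $N(R; R_0, \sigma_R)$ and intensity weighting $V(R)^2$,

  $$P(Q) = \frac{\int N(R)\, V(R)^2 A(QR)^2\, dR}
                {\int N(R)\, V(R)^2\, dR},
    \qquad A(x) = \frac{3(\sin x - x\cos x)}{x^3},$$

  and fitting $I(Q) = s\,P(Q) + b$ yields the geometric radius $R_0$.

* **Dynamics (XPCS).** The normalised intensity autocorrelation of a
  pixel ensemble at momentum transfer $Q$ is, for free diffusion,
  $g_2(\tau, Q) = 1 + \beta\, e^{-2 D Q^2 \tau}$, with $\beta$ the
  coherence (contrast) factor of the instrument. The decay times
  $\tau_0(Q) = 1/(D Q^2)$ give the diffusion coefficient, and the
  Stokes–Einstein relation $D = k_B T / (6\pi\eta R_H)$ gives the
  hydrodynamic radius.

$R_H > R_0$ is the scientifically interesting outcome: the difference
measures hydration shells, surface charge effects and incipient
aggregation, and it grows with ionic strength and with strongly
salting-out ions.

## The correlator

`correlate_multitau()` computes, per pixel and delay,

$$G2(\tau) = \langle I(t)\, I(t+\tau)\rangle_{t},\qquad
  IF(\tau) = \langle I(t)\rangle_{t \in [0, T-\tau]},\qquad
  IP(\tau) = \langle I(t+\tau)\rangle_{t+\tau \in [\tau, T]},$$

the *symmetric normalisation*: the past and future windows are averaged
separately, which cancels slow drifts of the mean intensity to first
order (a property the test suite verifies numerically: a 10 % linear
ramp perturbs $g_2$ by less than $10^{-2}$, i.e. below $(bT/a)^2$).

Two ordering decisions matter and both follow the photon-starved regime
this analysis is designed for:

1. **Pixels are binned before the division.** Within each fine `Q`
   partition, $g_2 = \langle G2\rangle_{ij} / (\langle IF\rangle_{ij}
   \langle IP\rangle_{ij})$. Dividing per pixel first and averaging
   after self-normalises every pixel to $\approx 1$ and destroys the
   contrast — at a few times $10^{-5}$ photons per pixel per frame a
   per-pixel $g_2$ is essentially shot noise. Binning first is also the
   only way to measure $\beta$ on a static reference.
2. **Repeats are merged on the sums, not on $g_2$.** When a single
   acquisition is too sparse to normalise on its own,
   `average_accumulators()` merges the `G2`/`IF`/`IP` of repeats with
   pair-count weights; normalisation happens once, at the end.

Fine partitions are narrow (default width $10^{-3}\,$nm$^{-1}$, about
two detector pixels at an 8 m geometry) so that the radial variation of
$I(Q)$ inside a partition cannot inflate the $g_2$ baseline; the
normalised fine results are then rebinned by a factor of 10 for signal
to noise.

**Delay ladder.** The multi-tau scheme uses 8 channels per level;
level 0 holds lags $1..8$ at native resolution, every further level
doubles the frame-binning width (non-overlapping block means, which
preserve a constant stream exactly) and holds channels $(4, 8]$. The
classic DLS choice of 8 channels is a compromise between delay
resolution and cost and is configurable. Lags beyond $T/4$ are dropped:
beyond a quarter of the sequence length the number of independent pairs
is small enough that the estimate is dominated by a handful of
low-frequency modes. The $1/4$ rule is conservative and configurable.

**Error bars.** The default error is the *population* standard
deviation of $g_2$-per-pixel over the coarse partition — the
spread-across-speckles convention; `error = "sem"` divides by
$\sqrt{n}$ for comparisons between subset means (the stability check
uses it). Because all downstream fits use weights only relatively and
rescale parameter errors by the residual variance, the choice does not
bias the fitted $\tau_0$ or $D$.

**Bad pixels.** Photon-counting detectors can have pixels with
spuriously high self-correlation (e.g. gating overlap between a pixel's
double counters) that look normal in mean intensity. The flagger
computes per pixel the median of $G2/(IF \cdot IP)$ over the five
smallest lags and flags pixels above `median + 5 * 1.4826 * MAD` of
their fine partition. The rule is robust, parameter-light, skips
partitions with fewer than 10 pixels, and an epsilon guard keeps a
degenerate spread (MAD = 0) from flagging everything. The threshold is
this package's choice; its null false-positive rate ($\le 1\%$) is
pinned by a test.

## The fits

* `fit_single_exponential()` fits $\Delta g_2 = \beta e^{-2\tau/\tau_0}$
  by weighted Levenberg–Marquardt. $\beta$ is *fixed* by default (to the
  static-reference value, the standard procedure; the generator's
  realised contrast is $1/n_\text{modes}$), with a free-$\beta$
  diagnostic mode. $\tau_0$ is bounded to $[10^{-7}, 10^3]$ s; a fit at
  a bound, or a $\tau_0$ below half the smallest sampled delay (a decay
  the frame rate cannot resolve — this is also what a flat
  $\Delta g_2 \equiv 0$ converges to), is flagged unconverged and
  excluded downstream. Starting values come from a log-linear fit of
  the early decay.
* `fit_tau_vs_q()` regresses $\Gamma = 1/\tau_0$ on $Q^2$ through the
  origin by weighted linear least squares, with
  $\sigma_\Gamma = \sigma_{\tau_0}/\tau_0^2$. A linear fit in $\Gamma$
  was preferred over a log–log fit of $\tau_0(Q)$ because it weights
  precise points properly and makes $D$ the slope with a closed-form
  error. The default cutoff `q_max = 0.1` nm$^{-1}$ reflects where the
  single-exponential Brownian description starts to degrade for
  virus-scale particles.
* `fit_form_factor()` fits on **log**-intensity residuals, since SAXS
  spans decades and linear residuals would let the first decade
  dominate; weights come from propagated relative errors, with zero or
  missing errors replaced by the median positive one (unit weights for
  a noise-free curve). Raw Levenberg–Marquardt (`minpack.lm::nls.lm`)
  is used with a covariance computed from the Jacobian, because on an
  exactly model-generated curve the residuals vanish and the `nls`
  model-object machinery can reject the (perfectly good) solution.

## Numerical choices

* $Q = (4\pi/\lambda)\sin(\theta/2)$ exactly, not the small-angle
  approximation — at 8 m they differ by $\sim 10^{-6}$ relative, so
  this is correctness at no cost. Wavelength from
  $\lambda[\text{Å}] = 12.3984/E[\text{keV}]$.
* The sphere amplitude switches to the series $1 - x^2/10$ below
  $x = 10^{-3}$; branch continuity at the switch point is tested to
  $10^{-10}$.
* The polydispersity integral uses Simpson quadrature on 129 points
  over $R_0 \pm 4\sigma_R$ (truncated at $R > 0$); refinement by 10x
  changes the result by less than $10^{-6}$ relative over the fitted
  `q` range. A warning fires when $\sigma_R > R_0/2$, where the
  truncation becomes visible.
* Partition representative `Q` is the plain mean over member pixels,
  matching how the intensities themselves are averaged, so
  $\langle I(Q)\rangle$ stays self-consistent.
* Fine partitions start at the minimum unmasked `Q` and keep partial
  trailing bins: discarding measured pixels is worse than a ragged last
  bin.

## The synthetic generator

`brownian_speckle_sequence()` draws, per pixel, $n_\text{modes}$
independent complex Gaussian field modes advanced by the exact discrete
Ornstein–Uhlenbeck step

$$E_k(t + \Delta t) = E_k(t)\,e^{-\Gamma\Delta t} +
  \xi\,\bigl(1 - e^{-2\Gamma\Delta t}\bigr)^{1/2},
  \qquad \Gamma = D Q^2,$$

with stationary initial conditions, sums $|E_k|^2$ incoherently, and
emits Poisson counts. This reproduces exactly the statistics the
analysis assumes: $g_2 = 1 + (1/n_\text{modes})\,e^{-2\Gamma\tau}$ at
the frame ticks, gamma-distributed instantaneous intensities
(variance/mean $= 1 + \bar{n}/n_\text{modes}$ after Poisson mixing),
and contrast $\beta = 1/n_\text{modes}$. With a target $\beta = 0.14$
the generator uses $n_\text{modes} = 7$, i.e. a realised contrast of
$0.143$ — a 2 % quantisation that the config validates and reports.

What it deliberately does **not** emulate:

* **Inter-pixel speckle correlation.** Pixels are statistically
  independent. The analysis uses only per-pixel time correlations and
  pixel-ensemble averages, whose expectations are unchanged by
  cross-pixel correlation; only the error bars of real data would be
  somewhat larger (fewer effective speckles than pixels). Passing tests
  therefore validate estimator correctness, not real-beamline error
  magnitudes.
* **Frame integration.** Intensities are sampled at frame ticks rather
  than integrated over the frame. For $\Gamma\Delta t \lesssim 1$ the
  difference is a percent-level triangular smearing confined to the
  first lag of deep multi-tau levels; a warning fires when
  $\Gamma\Delta t > 50$.
* **Detector artifacts.** No gating overlap, dead time or afterglow;
  only the *symptom* handled downstream (high-correlation pixels) can
  be injected artificially to exercise the flagger.
* The `Q` dependence of the count rate is either flat or
  form-factor-weighted relative to the first ring; the real-beam
  `Q` dependence of flux and efficiency is not modelled.

All randomness flows from the config seed; the same seed reproduces the
event stream byte for byte (chunking of the simulation is fixed
internally so the draw order is stable).

## Validation scale

The study conditions behind the acceptance protocol — 279 K, solvent
viscosities 1.520/1.536/1.672 mPa s, contrast 1/7, 52 kHz frames,
count rates down to $7\times10^{-5}$ photons/pixel/frame — are kept as
stated. A real beamtime integrates on the order of $10^9$ frames per
condition; this package validates on desk-scale runs of 8 rings
$\times$ 200 pixels $\times$ 50 000 frames at an elevated rate of 0.05
photons/pixel/frame, which the test suite shows recovers the
ground-truth hydrodynamic radii within a few tenths of a nanometre.
The contrast calibration runs a static reference of 2000 pixels
$\times$ 20 000 frames. Unit tests use smaller fixtures still, chosen
so each statistical assertion has a comfortable margin (3–5 standard
errors) at fixed seeds.

## Stability diagnostic

`check_stability()` compares SAXS and $g_2$ results from subsets of one
acquisition by pairwise reduced $\chi^2$ with combined errors (subset
means, so SEM errors). The verdict uses one pooled statistic per pair —
$g_2$ pooled over `Q` and delay — because per-`Q` statistics average
only a dozen strongly correlated lag points each and would fail a
stationary null run far too often; the per-`Q` values are still
reported for localisation once a pair fails. The default threshold of
2.0 in reduced $\chi^2$ is a lenient screen for gross drift (radiation
damage, beam instability), not a calibrated hypothesis test.

## Known limitations

* Single-exponential dynamics only: no stretched exponentials,
  two-time correlations, or structure-factor corrections — the dilute
  Brownian limit is assumed throughout.
* No absolute-intensity calibration, flat-field, solid-angle or
  polarisation corrections in the SAXS branch.
* The plain-text event container is convenient and lossless but not
  suited to terabyte-scale streams; it mirrors the layout (event table
  plus attributes) of the chunked binary containers used at beamlines
  so the two are interchangeable at the interface level.
* The length-scale bounds quoted for such measurements depend on a
  $2\pi/Q$ convention; the package reports `Q` ranges and leaves the
  conversion to the user.
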