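---
title: "Adaptive VMD denoising of magnetocardiography signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive VMD denoising of magnetocardiography signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unshielded magnetocardiography records the heart's 20–100 pT magnetic field
amid interference that is often larger than the signal itself: power-line
pickup near 50 Hz, baseline drift below 0.5 Hz from motion, respiration and
ambient field changes, and broadband sensor noise. Classical fixed filters
must commit to cutoffs in advance; decomposition-based denoising instead
separates the recording into narrowband components and treats each
according to what it contains. The catch is that variational mode
decomposition (VMD) needs two parameters — the mode count $K$ and the
bandwidth penalty $\alpha$ — and poor choices cause mode mixing or mode
splitting. This package closes the loop: a metaheuristic selects
$(K, \alpha)$ per recording by minimizing a sparsity criterion, and the
resulting modes are dispatched by centre frequency.

## Variational mode decomposition

VMD models the signal as $K$ AM–FM components $u_k(t)$ with centre
frequencies $\omega_k$ and minimizes the summed bandwidths subject to exact
reconstruction. The ADMM solution alternates three updates in the frequency
domain:

* mode spectra through a Wiener filter,
  $\hat u_k \leftarrow \dfrac{\hat s - \sum_{i \ne k}\hat u_i + \hat\tau/2}
  {1 + 2\alpha(\omega - \omega_k)^2}$;
* centre frequencies to the centre of gravity of each mode's power
  spectrum, $\omega_k \leftarrow \int_0^\infty \omega\,|\hat u_k|^2
  \mathrm d\omega \big/ \int_0^\infty |\hat u_k|^2 \mathrm d\omega$;
* the Lagrange multiplier $\hat\tau \leftarrow \hat\tau + \beta(\hat s -
  \sum_k \hat u_k)$, with rate $\beta$.

The loop stops when $\sum_k \lVert\hat u_k^{n+1}-\hat u_k^n\rVert^2 /
\lVert\hat u_k^n\rVert^2 < \varepsilon$.

Numerical choices, all configurable through `vmd_params()`:

* **Boundary handling.** The signal is mirror-extended to twice its length
  before the FFT and cropped after inversion — the standard guard against
  wrap-around artifacts.
* **Multiplier off by default** ($\beta = 0$): with strong noise an exact
  reconstruction constraint would force noise back into the modes. The
  decomposition residual `input − Σ modes` is kept explicitly, so the exact
  bookkeeping identity holds for every input by construction.
* **Initialization.** `"uniform"` spreads $\omega_k$ linearly over
  $(0, f_s/4]$ and is the deterministic default; `"random"` draws from the
  seeded generator. With $K = 1$ the uniform start sits at $f_s/4$: a
  narrow Wiener filter (large $\alpha$) then locks onto content near the
  start frequency, which is the expected behaviour of this local scheme,
  not a defect — single-tone recovery tests place the tone accordingly.
* **Stopping.** $\varepsilon = 10^{-7}$, at most 500 sweeps — typical VMD
  settings; all test fixtures converge well before the cap.
* **Degenerate guard.** Centre frequencies closer than $10^{-6}$
  (normalized) are nudged apart by one grid step; duplicated Wiener peaks
  otherwise stall ADMM.
* The inner loop is compiled (Rcpp): the optimizer evaluates hundreds to
  thousands of decompositions per search.

## Choosing (K, α): mean envelope entropy

Each mode's Hilbert envelope $a_j = |u + \mathrm i\,H(u)|$, normalized to a
probability vector $p_j = a_j / \sum_j a_j$, yields the envelope entropy
$E = -\sum_j p_j \lg p_j$; the fitness is the mean over modes. Pulse-like
modes concentrate their envelope at the cardiac complexes and score low;
modes contaminated by noise approach the uniform bound $\lg N$. The `lg`
is read as log base 10 (the conventional meaning; the base only rescales
the objective and cannot move its argmin, and is configurable). The
$0 \cdot \log 0 := 0$ convention applies, and envelopes are used untrimmed:
edge bias is identical across candidates and cancels in the comparison.

## The improved arithmetic optimization algorithm

AOA moves a population around the incumbent best $X_b$ with
multiplication/division steps (exploration) or addition/subtraction steps
(exploitation), scaled by the math optimizer probability
$\mathrm{MOP}(t) = 1 - (t/T)^{1/\alpha_{mop}}$. The phase is gated by
comparing a uniform draw $R_1$ against the accelerated function; following
the published procedure, $R_1 < \mathrm{MOA}(t)$ selects exploration. Three
modifications, each independently switchable for ablation:

* **Tent-chaos initialization** (`tent_init`): one chaotic stream per
  dimension, knee parameter 0.7, 100-iterate burn-in, mapped affinely into
  the bounds. The skew tent map's invariant density is uniform, which the
  test suite checks with a Kolmogorov–Smirnov test.
* **Nonlinear accelerated function** $(t/T)^2 e^{1-t/T}$: rises more
  slowly than the linear schedule early on and meets it at the endpoints.
* **Population mutation** $r_1(X_b - X) + (1-r_1)(X_{rand} - X)$, proposed
  with probability 0.2 per candidate per iteration and accepted only on
  improvement. The published move gives no acceptance rule; greedy
  acceptance preserves the non-increasing best-fitness history.

Where the literature leaves granularity unstated, $R_1$ is drawn once per
candidate per iteration and the operator draws $R_2, R_3$ per dimension —
per-dimension draws preserve search diversity. Defaults
$\mu = 0.5$, $\alpha_{mop} = 5$, linear-schedule endpoints
$\mathrm{Min} = 0.2$, $\mathrm{Max} = 1$ are the common AOA settings. The
$K$ dimension is flagged integer-valued: searched continuously, rounded at
evaluation and reporting time. Fitness values are cached on quantized
positions ($K$ exact, $\alpha$ to 4 decimals) since the moves frequently
revisit near-identical candidates.

A structural note: every move is expressed relative to $X_b$ alone, as
printed in the source formulation. With bounds symmetric about zero the
scaled span $(U_b - L_b)\mu + L_b$ vanishes and the additive moves
degenerate onto $X_b$; test objectives therefore use asymmetric bounds
where a genuine search is required.

## Modal disposal

With the optimal $(K^*, \alpha^*)$ decomposition in hand, each mode is
classified by centre frequency $f_c$:

| condition | action |
|---|---|
| $f_c \ge f_{high}$ (default 50 Hz) | remove |
| $f_{base} \le f_c < f_{high}$ | wavelet threshold |
| $f_c < f_{base}$ (default 0.5 Hz) | wavelet threshold, then baseline correction |

$f_{high} = 50$ Hz is the local power-line frequency; sources differ on
whether 50 or 60 Hz is appropriate and both cutoffs are plain config
fields. When no mode falls below $f_{base}$, the lowest-frequency retained
mode receives the baseline treatment (`baseline_lowest_fallback`), matching
the practice of drift-correcting the lowest mode; whether the sub-drift
mode is wavelet-thresholded before correction is likewise a flag
(`baseline_wavelet_first`, default on).

**Wavelet thresholding** uses a periodic orthogonal DWT written in the
package (no wavelet transform is available in the installed R stack), db4
by default — the conventional cardiac choice — with depth
$\max(3, \lfloor\log_2 N\rfloor - 6)$, the universal threshold
$\lambda = \hat\sigma\sqrt{2\ln N}$, $\hat\sigma = \mathrm{median}(|d_1|)/0.6745$
from the finest detail level, and soft shrinkage by default. Perfect
reconstruction of the transform is itself under test.

**Baseline correction** subtracts a sliding-median baseline. The window is
one cutoff period, $\mathrm{round}(f_s/f_{base})$ samples: long enough that
cardiac content medians out, short enough to track drift well below
$f_{base}$ — a two-period window was measured to leave most of a 0.2 Hz
drift in place, failing the intended ≥ 10 dB low-band reduction, and was
rejected. Zero-phase Butterworth high-pass and cubic-polynomial detrending
are alternatives; the cubic suits monotone or single-swing trends only.
Records shorter than the window fall back to mean subtraction with a
warning.

## Metrics

HFNSA and LFNSA integrate a Welch PSD (Hann window, 2 s segments, 50 %
overlap — chosen to stabilize the estimates across realizations; a plain
periodogram mode is kept for oracle tests) over the > 40 Hz and < 0.5 Hz
bands. QRS amplitude is the mean peak-to-trough excursion within ±60 ms of
each R peak; peaks are detected on the raw signal (5–25 Hz zero-phase
bandpass, squaring, 150 ms integration, adaptive threshold with 200 ms
refractory) and reused on the denoised signal so the metric measures
amplitude change rather than detectability change. Spectral entropy keeps
the stabilizing $\varepsilon = 10^{-12}$ inside the logarithm exactly as
defined.

Two behaviours of these definitions matter when reading results on heavily
corrupted inputs:

* **QRSA is noise-inflated.** The reference amplitude is measured on the
  *raw* windows, where the max/min excursion includes the interference.
  Under the default study noise (power line 0.3, drift 0.5, broadband 0.1,
  relative to an R amplitude of 1) even substituting the noise-free clean
  signal as "denoised" scores about −39 %. Large negative QRSA values on
  such inputs therefore reflect the metric's reference, not signal
  destruction.
* **Spectral entropy tracks concentration, with sign depending on the
  noise mix.** Narrowband interference (drift, line tone) *lowers* the raw
  entropy by concentrating the PSD; broadband noise raises it. On
  drift-dominated fixtures a successful denoiser can raise entropy toward
  the clean signal's value; entropy decreases are expected when broadband
  noise dominates, as in typical unshielded clinical recordings.

## The synthetic generator

Clean traces are a train of five Gaussian bumps per beat (P, Q, R, S, T) at
fixed offsets (−170, −25, 0, +25, +250 ms from R) with widths 25/12/12/12/60
ms and amplitudes 0.15/−0.1/1/−0.2/0.3 — plausible cardiac timing, fully
deterministic, with optional seeded beat-onset jitter (default off so
stability tests see strictly periodic signals). Interference defaults:
50 Hz line at 0.3, 0.2 Hz drift at 0.5, white noise σ = 0.1, all relative
to R = 1 — a strongly corrupted regime representative of unshielded
acquisition, where interference rivals or exceeds the signal. No published
amplitude calibration ties these to a particular sensor, so the
signal-to-noise ratio is an explicit free parameter of the generator.

What the generator does *not* emulate: multichannel spatial structure,
beat-morphology variability, non-sinusoidal drift, impulsive motion
artifacts, or sensor-specific coloured noise. Passing tests demonstrate
the pipeline's mechanics and its behaviour under the stated interference
classes — not clinical performance.

## Problem sizes and budgets

The standard experiment is a 10 s recording at 1 kHz with the search ranges
$K \in [4, 10]$, $\alpha \in [500, 3000]$. The package's default test and
reproduction budget scales the published population/iteration setting of
60/50 down to 15/12 — about a quarter in each factor — which the stability
harness shows is already sufficient on the synthetic fixture: ten repeated
searches select the same $K$ in ten of ten runs with an $\alpha$
coefficient of variation of ~2 %. The landscape on the synthetic fixture
has its minimum at the low boundary ($K = 4$, $\alpha = 500$): the
four-component mixture (cardiac + drift + tone + broadband) genuinely
needs only four modes, and smaller $\alpha$ widens the cardiac mode enough
to keep its envelope sparse.

## Known limitations

* The disposal rule keys on the centre frequency alone; a mode whose
  centroid sits marginally below $f_{high}$ keeps a line tone that wavelet
  thresholding cannot remove (thresholding suppresses small coefficients,
  not coherent oscillations). With interference exactly at the cutoff the
  classification can flip with the noise realization; setting `f_high`
  slightly below the line frequency is the practical remedy.
* The decomposition residual is dropped at reconstruction, as the
  procedure prescribes; on nearly clean inputs this bounds the achievable
  correlation with the input (≈ 0.99, verified in tests).
* Comparator settings are deliberately favourable to the comparators
  (e.g. an FIR bandpass spanning exactly the signal band, with re-centred
  taps giving an exact DC null); on synthetic fixtures the FIR's brick-wall
  high-band suppression can exceed the pipeline's HFNSA because the metric
  cannot distinguish suppressed noise from suppressed in-band signal.
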