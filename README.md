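# aovmd — adaptive VMD denoising for magnetocardiography

Magnetocardiography (MCG) measures the picotesla-scale magnetic field of the
beating heart without contact. Outside a shielded room the recording is
buried under power-line pickup (around 50 Hz), sub-0.5 Hz baseline drift
from motion and environmental field changes, and broadband sensor noise.
`aovmd` implements an adaptive denoising pipeline for single-channel MCG
traces, together with the comparator methods and quality metrics needed to
judge it.

## Method

The pipeline has three stages:

1. **Variational mode decomposition (VMD).** The signal s(t) is split into
   K band-limited modes u_k(t) with centre frequencies ω_k by solving

   min Σ_k ‖ ∂_t [ (δ(t) + j/πt) ∗ u_k(t) ] e^(−jω_k t) ‖²  s.t.  Σ_k u_k = s

   via ADMM in the frequency domain: each mode spectrum is updated through
   a Wiener filter with denominator 1 + 2α(ω − ω_k)², each ω_k moves to the
   centre of gravity of its mode's power spectrum, and the loop stops when
   the summed relative spectral change falls below ε. The penalty α sets
   the mode bandwidth.

2. **Adaptive parameter selection.** K and α are chosen by an improved
   arithmetic optimization algorithm (AOA) minimizing the **mean envelope
   entropy** (MEE) of the decomposition — the average Shannon entropy of
   the normalized Hilbert envelopes of the modes. Sparse, pulse-like modes
   (clean cardiac content) have low envelope entropy; noisy modes have high
   entropy. The improvements over vanilla AOA are tent-chaos population
   initialization, a nonlinear accelerated function OMOA(t) = (t/T)² e^(1−t/T)
   gating exploration vs exploitation, and a per-iteration population
   mutation with greedy acceptance.

3. **Frequency-aware modal disposal.** Modes with centre frequency ≥ 50 Hz
   are removed (power-line and high-frequency noise); modes between 0.5 and
   50 Hz are wavelet-threshold denoised (db4, universal threshold
   σ̂√(2 ln N), soft shrinkage); the lowest-frequency mode is additionally
   baseline-corrected (sliding median). The retained processed modes are
   summed into the denoised trace.

Quality is reported with four metrics: high- and low-frequency noise
suppression HFNSA/LFNSA = 10·log₁₀(P_band,raw / P_band,denoised) (dB,
positive = suppression), the signed QRS amplitude change
ΔA = (A_denoised − A_raw)/A_raw × 100 %, and the spectral entropy
−Σ p_i log₁₀(p_i + ε) of the normalized PSD. FIR bandpass (0.5–40 Hz) and
whole-signal wavelet soft/hard thresholding are included as comparators.

Because clinical MCG recordings are generally confidential, the package
ships a synthetic generator: a PQRST-like train of Gaussian bumps plus the
three interference classes, each component separately retrievable so every
stage is testable against known ground truth.

## Worked example

```r
library(aovmd)

cfg <- mcg_sim_config(fs = 1000, duration = 10, seed = 1)   # 60 bpm PQRST + noise
raw <- corrupt_signal(generate_clean_mcg(cfg), cfg)

fit <- denoise_mcg(raw, aoa_config(pop_size = 15, max_iter = 12,
                                   lower = c(4, 500), upper = c(10, 3000),
                                   integer_dims = 1L, seed = 2))
fit
#> <mcg_denoise> K = 4, alpha = 500.0000, mean envelope entropy = 3.8904
#>   modes:
#>     imf_1     0.353 Hz  -> baseline
#>     imf_2    13.784 Hz  -> wavelet
#>     imf_3    50.130 Hz  -> remove
#>     imf_4   280.056 Hz  -> remove

evaluate_denoising(raw, fit$denoised)
#> <mcg_metrics>
#>   HFNSA:   36.322 dB
#>   LFNSA:   16.886 dB
#>   QRSA:   -38.835 %
#>   spectral entropy: 0.9449 (raw) -> 1.4367 (denoised)
```

The optimizer settled on a 4-mode decomposition: the drift mode (0.35 Hz)
is baseline-corrected, the cardiac mode (13.8 Hz) is wavelet denoised, and
the modes carrying the 50 Hz interference and broadband noise are dropped.
High-band noise is suppressed by 36 dB and the drift band by 17 dB. The
QRSA value illustrates a known property of the raw-referenced metric: the
raw amplitude estimate is itself inflated by noise, so strongly corrupted
inputs yield large negative values even for near-ideal denoising (see the
methods vignette). Spectral entropy rises here because the drift spike
concentrates the raw spectrum; on broadband-noise-dominated recordings it
falls.

`autoplot(fit)` overlays raw and denoised traces; `tidy(fit)` returns the
per-mode plan; `glance(fit)` the selected parameters. A thin command-line
wrapper (`inst/cli/aovmd.R`) exposes `simulate`, `denoise`, `metrics`,
`compare` and `stability` subcommands over the same functions.

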