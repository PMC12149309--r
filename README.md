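# esvtbcg

Denoising and validation tools for ballistocardiogram (BCG) recordings.

A BCG records the micro-vibrations the body makes as the heart beats and
ejects blood. Captured unobtrusively (here: an optical-fiber mat under the
subject, sampled at 100 Hz), the signal carries heart rate and hemodynamic
information, but it arrives buried in broadband sensor noise and overlaid on
a large, slow respiratory component. `esvtbcg` is for researchers working
with such recordings: it implements the denoising algorithm used to produce
the cleaned channel of a published multi-pathology BCG dataset, the
simulation machinery used to tune it, and the heart-rate agreement analysis
used to validate it.

## The method

The core is an iterative Hankel-matrix singular-value soft-thresholding
scheme (a Cadzow/SSA-style alternating projection):

1. **Embedding.** The signal *x(n)*, *n* = 1…*N*, is slid through a window of
   *L* samples (default 200, i.e. 2 s at 100 Hz) to form the trajectory
   matrix *X* ∈ ℝ^(*L*×(*N*−*L*+1)) with *X*[i,j] = *x*(i+j−1); its
   anti-diagonals are constant (Hankel structure).
2. **Decomposition.** *X* = *U*Σ*V*ᵀ with singular values
   σ₁ ≥ σ₂ ≥ … ≥ 0. Coherent oscillations concentrate in a few large σᵢ;
   white noise spreads over all of them.
3. **Shrinkage.** Each singular value is soft-thresholded,
   σᵢ ← max(0, σᵢ − τ), and the matrix is rebuilt as *U*Σ_new *V*ᵀ.
4. **Re-projection.** The rebuilt matrix is no longer Hankel; anti-diagonal
   averaging (the orthogonal projection onto Hankel structure) maps it back
   to a signal, which is re-embedded. Steps 2–4 repeat for *i* iterations,
   and the final matrix is averaged back into the denoised series *x*\*(n).

The pair (τ, *i*) is tuned by grid search on synthetic BCG signals — six
cardiac sinusoids at 1.5–9 Hz (amplitudes 0.1, 0.2, 0.1, 0.4, 0.3, 0.6 a.u.)
plus a 0.2 Hz respiratory sinusoid of amplitude 2 — with Gaussian white
noise added at nominal SNRs of 0–15 dB. A multi-level wavelet
soft-threshold denoiser (db4, universal threshold) serves as the comparison
baseline, and Bland–Altman statistics (bias, 1.96·SD limits of agreement)
plus Pearson *r*, RMSE and MAE quantify BCG-vs-ECG heart-rate agreement.

## Worked example

```r
library(esvtbcg)

spec <- bcg_spec()                       # the published simulation conditions
grid <- esvt_grid_search(spec, iter_grid = 1:8, n_realizations = 2,
                         snr_db = 0, seed = 20260926)
grid$optimum
#> $tau
#> [1] 42.63919
#> $iterations
#> [1] 2
#> $snr_db
#> [1] 12.64651

sim <- bcg_simulate(spec, snr_db = 0, seed = 42)
fit <- esvt_denoise(sim$noisy, grid$optimum$tau, grid$optimum$iterations)
measure_snr(sim$noisy, sim$cardiac)            # input, scored against cardiac
#> [1] -11.18874
measure_snr(fit$denoised$value, sim$cardiac)   # output
#> [1] -7.102754
```

The grid search scores candidate parameters by the SNR of the denoised
signal against the full clean waveform (cardiac + respiratory); at the
optimum it reaches ≈ 12.6 dB from a 0 dB-noise input. Applied to a fresh
realization, the tuned filter raises the cardiac-referenced SNR by ≈ 4.1 dB
(−11.2 → −7.1 dB; this reference counts the retained respiratory component
as noise, which is why both numbers are negative). `autoplot(fit)`,
`autoplot(grid)` and `autoplot()` on benchmark/agreement objects draw the
standard figures; `tidy()`/`glance()` return the results as tibbles.

A command-line wrapper over the same functions ships at
`inst/cli/esvt.R` with `simulate`, `denoise`, `tune`, `benchmark`,
`validate-hr` and `dataset-check` subcommands.

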