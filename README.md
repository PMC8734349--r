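# t1net

Accelerated cardiac T1 mapping in R: a neural-network T1 estimator for
single Look-Locker (four-heartbeat, "LL4") acquisitions, alongside the
conventional MOLLI-style curve-fit reconstruction, synthetic training-data
and digital-phantom generators, and the agreement statistics used to
validate parametric mapping methods.

## Who this is for

Quantitative-MRI researchers and methods developers who want to study —
entirely at desk scale — how well a small fully connected network can
estimate myocardial T1 from only four T1-weighted samples of one
inversion-recovery experiment, compared with conventional 3-parameter
fitting.  Everything runs from synthetic data generated by the package; no
scanner data is required (real pixel tables with reference T1 values can
be substituted through the same CSV interface).

## The models

**Signal model.**  Each pixel of a Look-Locker acquisition follows the
3-parameter inversion-recovery model

    S(t) = A − B·exp(−t / T1*),        T1 = T1*·(B/A − 1)

where `T1*` is the apparent (readout-shortened) relaxation time and the
second relation is the Look-Locker correction.  Images are acquired at
inversion times `TI_n = TI1 + (n−1)·RR` within each group of a MOLLI-style
scheme (`"5(3)3"`, `"4(1)3(1)2"`, `"4"`, ...).

**Curve-fit baseline.**  `ir_fit()` / `ir_fit_map()` perform bounded
Levenberg–Marquardt least squares per pixel, with polarity restoration for
magnitude data (all leading-sample sign flips tested, minimum residual
wins) and the Look-Locker correction applied to the converged fit.

**Network estimator.**  `t1net()` trains a fully connected network
(default 2N–400–400–200–200–100–1, leaky-ReLU activations) that maps the N
normalized signals plus their N inversion times directly to T1 in ms,
minimizing the mean absolute error with Adam (lr 0.01, weight decay 1e-4,
batch 64) and early stopping (patience 70) on the validation MAE, with
per-epoch monitoring of the myocardium- (1000–1400 ms) and blood-range
(1500–2000 ms) validation errors.  `predict_map()` reconstructs T1 maps
from image stacks; checkpoints are single-file archives with a JSON header
and raw float32 weights.

See the methods vignette (`vignettes/t1net-methods.Rmd`) for the design
rationale — including why per-pixel min–max normalization is information-
destroying for this estimator and scale-by-max is the default.

## Worked example

```r
library(t1net)

## LL4 timing at 60 bpm
timing <- acquisition_timing("4", rr_ms = 1000, ti1_ms = 100)
print(timing)

## conventional 3-parameter fit of one noiseless pixel (true T1 = 1100 ms)
s <- ir_signal(timing$tis_ms, a = 1, b = 1.9,
               t1_star_ms = apparent_from_true(1100, 1.9))
print(ir_fit(s, timing$tis_ms))

## train a compact network on synthetic pixels (SNR 50) and evaluate it
train <- simulate_pixels(20000, snr = 50, seed = 1)
val   <- simulate_pixels(5000,  snr = 50, seed = 2)
model <- t1net(train, val, hidden = c(64, 32), max_epochs = 15, seed = 3)
print(model)

held <- simulate_pixels(5000, snr = 50, seed = 4)
pred <- predict(model, held)
cat(sprintf("held-out MAE: %.1f ms\n", mean(abs(pred - held$t1_true))))

## agreement with the curve fit on a 4-vial digital phantom at SNR 100
ph <- simulate_phantom(c(400, 800, 1200, 1600), snr = 100, reps = 5, seed = 5)
roi <- ph$rois > 0
net_m <- sapply(1:4, function(v) mean(sapply(ph$stacks, function(st)
  mean(predict_map(model, st, ph$timing, mask = roi)[ph$rois == v]))))
fit_m <- sapply(1:4, function(v) mean(sapply(ph$stacks, function(st)
  mean(ir_fit_map(st, ph$timing, mask = roi)[ph$rois == v]))))
print(bland_altman(fit_m, net_m))

## extracellular volume fraction from paired T1 measurements
print(compute_ecv(1200, 600, 1800, 500, hct = 0.42))
```

Output:

```
Acquisition timing for scheme 4 (RR 1000 ms)
  group 1 TIs (ms): 100, 1100, 2100, 3100
3-parameter inversion-recovery fit (signed)
  A = 1, B = 1.9, T1* = 1222 ms
  Look-Locker corrected T1 = 1100 ms
  residual RMS 5.55e-17, polarity flips 0, converged TRUE
Fully connected T1 estimator (8 inputs -> 64-32 -> 1)
  normalization: scale_max, TI scale 1000; leaky slope 0.01; variant pre_post
  trained 15 epoch(s); best epoch 9, validation MAE 22.06 ms
held-out MAE: 22.4 ms
Bland-Altman agreement (n = 4 pairs)
  bias 2.84, 95% limits of agreement [-2.81, 8.49]
  paired t = 1.97, p = 0.143
ECV 33.46% (hematocrit 0.42)
```

Reading the numbers: the noiseless 4-point fit recovers the generating T1
exactly (1100 ms).  The compact demonstration network reaches ~22 ms mean
absolute T1 error at SNR 50 — close to the per-pixel information limit of
four samples at that noise level (the full-size default architecture, used
by the validation runs below, behaves similarly).  On the high-SNR digital
phantom the network and the curve fit agree within a few ms per vial, and
the ECV example reproduces the hematocrit-corrected ΔR1 ratio.

## Command-line use

A thin Rscript front end wraps the same functions:

```sh
Rscript inst/cli/t1net.R simulate --scheme 4 --rr 1000 --n 1000 --seed 7 --out pixels.csv
Rscript inst/cli/t1net.R train --data pixels.csv --out model.t1net --log history.csv
Rscript inst/cli/t1net.R predict --model model.t1net --stack stack.nii.gz --out map.nii.gz
Rscript inst/cli/t1net.R evaluate --map-a molli.nii.gz --map-b ll4.nii.gz --rois rois.nii.gz --out report
Rscript inst/cli/t1net.R ecv --pre-myo 1200 --post-myo 600 --pre-blood 1800 --post-blood 500 --hct 0.42
```

Commands accept `--config <yaml>` (flags override the file; unknown keys
are rejected) and write JSON provenance sidecars (tool version, seed,
config hash) next to their outputs.

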