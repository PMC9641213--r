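# VoxSR — volumetric super-resolution of anatomical MRI with residual U-Nets

VoxSR is an R toolkit for single-image super-resolution (SR) of 3D
anatomical MRI, aimed at the pediatric setting where long high-resolution
(HR) acquisitions are poorly tolerated and motion-free scan time is
scarce. Since genuine low-resolution (LR) / HR pairs do not exist, the
package simulates LR observations from HR ground truth, trains a
convolutional network to invert the degradation, and evaluates recovered
volumes against the ground truth they came from. A seeded phantom
generator makes the entire pipeline runnable and testable without any
external imaging data.

The forward model is

```
Y = T(X) = (D↓ S) X + N
```

where `S` smooths with a normalized cubic Gaussian kernel (5 voxels,
σ = 1) and `D↓` keeps one of every N voxels per axis (N ∈ {2, 3, 4}).
The LR volume is re-upsampled to the HR grid with separable cubic
interpolation `I↑` and the recovery operator is learned as

```
R̂ = argmin_R Σᵢ ‖ Xᵢ − R(I↑(Yᵢ)) ‖ ,    X̂ = R̂(I↑(Y))
```

with a tissue-masked L1 + gradient loss. `R` is a 9-stage residual U-Net
(encoder 64→512 filters, latent 1024, mirrored decoder; 23 conv blocks,
4 transposed convolutions, a 1-kernel sigmoid head — 28 convolutional
layers in total), available in 3D patch-based and 2D slice-based
variants. Whole volumes are reconstructed from overlapping patch
predictions by inner-cube stitching, and evaluated with PSNR, MAE (on the
[0, 255] scale) and SSIM plus repeated-measures ANOVA and paired Wilcoxon
tests. The network engine — convolutions, batch norm, pooling, transposed
convolutions, Adam — is implemented from scratch in RcppArmadillo; no
deep-learning framework is required.

## Worked example

The default experiment trains the tiny 3D configuration (25 synthetic
64³ phantoms — 20 for training and validation, 5 held out; scaling factor
2; 8 initial filters; 16³ patches; 15 epochs) and compares the trained
network against bicubic interpolation on the held-out phantoms:

```r
library(VoxSR)
cfg <- defaultRunConfig()
cfg$out_dir <- "voxsr-demo"
res <- runExperiment(cfg, verbose = TRUE)
res$summary
#>   method factor psnr_mean   psnr_sd mae255_mean mae255_sd ssim_mean     ssim_sd
#> 1  cnn3d      2  29.60194 0.2107138    3.613734 0.1431262 0.9549915 0.004834278
#> 2 interp      2  28.04084 0.3333685    4.408597 0.2338212 0.9124723 0.007393062
```

Read: on the five held-out phantoms the trained 3D CNN reconstructs at a
mean 29.6 dB PSNR versus 28.0 dB for bicubic interpolation (≈ +1.6 dB),
reduces the mean absolute error from 4.41 to 3.61 intensity units (of
255), and raises SSIM from 0.912 to 0.955 — the network recovers boundary
detail that interpolation smooths away. The run directory contains the
per-volume report, per-epoch training history, the best checkpoint and
the resolved configuration; rerunning with the same config and seed
reproduces the tables exactly.

Smaller building blocks are exported individually — for example:

```r
ph   <- generatePhantom(PhantomSpec(seed = 7))
hr   <- homogenizeBackground(ph$volume, ph$mask)
pair <- simulatePair(hr, ph$mask, DegradationSpec(2))
psnr(pair@lrUp, pair@hr)   # fidelity of bicubic upsampling alone
```

## Scope

Full-scale replication (256³ clinical volumes, 64 initial filters, 50–100
epochs, cohorts of 33–90 subjects, 2D and 3D networks at three scaling
factors) is expressible through the same configuration keys but takes
days of CPU time; the shipped defaults are the desk-scale configuration
the test suite validates. The methods vignette
(`vignettes/voxsr-methods.Rmd`) documents the model, every design
decision left open by the protocol this package follows, the phantom
generator's fidelity and limits, and the numerical conventions.
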