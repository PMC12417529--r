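# trifuse

Lightweight triple-modal fusion network for predicting conversion from mild
cognitive impairment (MCI) to Alzheimer's disease, in R.

Clinicians distinguish *progressive* MCI (pMCI: converts to AD within a few
years) from *stable* MCI (sMCI). `trifuse` trains a compact neural classifier
that fuses three baseline modalities per subject — a 3D structural MRI volume,
a 3D FDG-PET volume, and seven clinical features (age, gender, education,
ApoE4 allele count, P-tau 181, T-tau, FDG/AV45 composite) — into a single
pMCI probability, and explains each prediction with integrated-gradients
attribution maps. It is aimed at methods researchers who want a fully
testable, CPU-runnable reference implementation of this fusion architecture
and its evaluation protocol.

## The model

* **Tabular branch** — a single Kolmogorov–Arnold (KAN) layer with learnable
  B-spline edge functions, `φ(x) = w_b·SiLU(x) + w_s·Σ_r c_r B_r(x)`, lifts
  the 7 standardized features to a 64-dimensional embedding, refined by two
  PoolFormer blocks (`H' = H + AvgPool(LN(H))`, `H = H' + MLP(LN(H'))`).
* **Imaging branches** — per-modality 3D residual encoders (ResNet-style
  basic blocks) produce `C × 3 × 4 × 3` feature maps.
* **HBAM** — hybrid channel attention `F_hc = σ(M_avg + M_max + E_cli) ⊗ F`
  injects the embedded clinical vector into each imaging stream's channel
  gates, followed by CBAM-style spatial attention.
* **MMCA** — cascaded grouped bidirectional cross-attention: tokens are split
  into N = 4 channel groups; each group cross-attends with queries from the
  opposite modality, `softmax(qᵀk/√d_k + b_i)`, with a learnable position
  bias and a cascade that feeds each group's attended output into the next.
* **Head & loss** — mean-pooled tokens → LayerNorm → MLP → one logit,
  trained with focal loss `-α_t (1-p_t)^γ log p_t` (α = 0.75, γ = 2) under
  Adam, a cosine learning-rate schedule and early stopping.

There is no deep-learning framework dependency: the package ships its own
reverse-mode autodiff tape and gemm-based C++ 3D convolution kernels. A
`test` preset (widths ÷4, 24×32×24 inputs, same 3×4×3 token grid) makes the
whole pipeline run in minutes on one CPU core; a bundled synthetic cohort
generator plants class effects (focal intensity decrements, shifted clinical
distributions) so everything is testable without restricted clinical data.

## Worked example

```r
library(trifuse)

cohort <- synth_cohort(n_pos = 20, n_neg = 40, effect_spec(), seed = 7)
split  <- stratified_split(cohort$labels, test_fraction = 0.25, seed = 7)
fit    <- trifuse(cohort, train_ids = split$train_ids,
                  control = train_control(epochs = 15, patience = 50), seed = 7)
print(fit)
#> Triple-modal fusion classifier (pMCI vs sMCI)
#>   preset: test  input: 24x32x24  tokens: 36  channels: 64
#>   parameters: 495,247  forward FLOPs: 39,572,704
#>   trained 15 epochs; best validation focal loss 0.0469 at epoch 15

pred <- predict(fit, cohort, ids = split$test_ids, type = "response")
compute_metrics(NULL, pred$probability, cohort$labels[split$test_ids])
#> n=15  acc=0.6000  sens=1.0000  prec=0.4545  f1=0.6250  bacc=0.7000  auroc=0.9600
```

Fifteen epochs on 36 training subjects already rank the held-out subjects
almost perfectly (AUROC 0.96); the 0.5 threshold is conservative at this
stage (every true pMCI is caught, sensitivity 1.0, at the cost of false
positives). Attribution of one test subject's prediction:

```r
id <- split$test_ids[1]
ig <- integrated_gradients(fit,
        intensity_normalize(cohort$subjects[[id]]$mri),
        intensity_normalize(cohort$subjects[[id]]$pet),
        cli_std, steps = 64)   # cli_std: standardized 7-vector for `id`
print(ig)
#> <trifuse_attribution> m=64  F(x)=0.4526  F(x')=0.8706  completeness gap=0.0151
#> clinical attributions:
#>      age   gender  education    apoe4  ptau181     ttau  fdg_av45_composite
#>  0.23116  0.00000   -0.43753 -0.28539  0.06328 -0.31280             0.35404

export_overlay(ig, cohort$subjects[[id]]$mri, "mri_attribution.nii.gz", "mri")
```

Attributions over the three input blocks sum to the logit change from the
zero baseline up to the reported completeness gap, which shrinks as `steps`
grows; voxel attributions export as NIfTI overlays aligned to the input grid.

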