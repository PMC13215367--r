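# lesionseg

Detection and delineation of multiple small contrast-enhancing lesions
(brain metastases being the motivating case) in 3D volumes, at a
configurable desk scale. The package implements the full training and
evaluation pipeline around the two ideas that target the
small-lesion regime:

* a **patch-level focal loss** (the "local region perceptron", LRP)
  added to the usual Dice + cross-entropy objective,

  L = L_Dice + (1 − w)·L_CE + w·L_LRP,

  where the volume is tiled into non-overlapping 8×8×8-voxel patches,
  patch l gets label y_l = 1 iff it contains any lesion voxel, its
  presence probability q_l is the patch maximum of the voxelwise
  foreground probability, and

  L_LRP = −mean_l [ y_l (1−q_l)^γ log q_l + (1−y_l) q_l^γ log(1−q_l) ],

  with γ = 0.5 and w = 0.4 by default — the focal weight concentrates
  gradient on hard lesion-bearing patches instead of the overwhelming
  empty background;

* **supervised contrastive pretraining** (CLP) of the encoder: the
  lesion mask is max-pool subsampled onto the 8³ grid of transformer
  bottleneck tokens (L = 512), and an InfoNCE objective pulls
  lesion-cell tokens together while pushing them away from background
  tokens, before the decoder is ever trained.

Around these sit a hybrid encoder–ViT–decoder segmentation network with
its own reverse-mode autodiff tape (compiled 3D convolution kernels),
the two-stage SGD/Nesterov schedule (stage 1: encoder+ViT with the
contrastive loss, decoder frozen; stage 2: decoder with the composite
loss, encoder+ViT frozen), a lesion-wise evaluation protocol (1 mm
morphological closing, 26-connected components, coverage matching with
CV = |A∩B|/|B| ≥ 0.5, size-stratified sensitivity/precision at
<3 mm / [3,6] mm / >6 mm, per-lesion Dice for matched lesions ≥ 3 mm),
and a seeded phantom generator producing T1c-like volumes with
ellipsoidal lesions whose size mixture and per-patient counts mimic
published multiple-metastasis cohorts.

Who this is for: researchers in medical image analysis who want a
self-contained, fully testable implementation of the patch-focal /
contrastive-pretraining recipe — to study the losses, reproduce the
directional claims on synthetic data, or evaluate their own masks with
the lesion-wise protocol.

## Worked example

Simulate a small cohort, train the two-stage model, and evaluate it
lesion-wise:

```r
library(lesionseg)

cfg <- phantom_config(shape = 48, n_lesions = 4, d_max = 10,
                      noise_sd = 5, seed = 11)
man <- generate_cohort(cfg, n_patients = 8, out_dir = "cohort")
cohort <- load_cohort(man)

fit <- lesion_segmenter(cohort,
                        net   = net_config(48, base_channels = 4,
                                           vit_layers = 2, vit_dim = 16),
                        train = train_config(epochs_pretrain = 3,
                                             epochs_finetune = 25,
                                             lr0 = 0.005, batch_size = 2),
                        seed  = 2)
print(fit)
#> Two-stage lesion segmentation model
#>   call:  lesion_segmenter(cohort = cohort, net = ..., train = ..., seed = 2)
#>   trained on 8 volumes (seed 2)
#> lesion segmentation network: 48^3 input, 2 down-stages (strides 2,3),
#>   ViT: 2 layers, d = 16, 2 heads over 512 tokens; stage 'finetune'
#>   22382 parameters (encoder 5096, vit 12656, decoder 4630)
#>   pretrain:  3 epochs, contrastive loss -2884.5931 -> -3071.1027
#>   finetune:  25 epochs, composite loss 1.0850 -> 0.9149

summary(fit, cohort)
#> ...
#> Lesion-level metrics (pooled over 32 GT lesions)
#>   TP 23  FP 4  FN 9
#>   sensitivity 0.7188  precision 0.8519
#>   by stratum (sensitivity / precision):
#>     small  0.5385 / 0.7778
#>     medium 0.7500 / 0.8182
#>     large  1.0000 / 1.0000
#>   mean Dice (GT >= 3 mm, n = 16): 0.6900
#>
#> Patient-level metrics over 8 patients (mean +/- SD)
#>   sensitivity 0.7188 +/- 0.2478
#>   precision   0.8438 +/- 0.2457
#>   mean Dice   0.6972 +/- 0.0473
```

The pretraining trace is the contrastive loss (lower = lesion and
background tokens more separated in the latent space); the fine-tuning
trace is the composite loss. `summary()` applies the full lesion-wise
protocol to the fitted model's own predictions: closing of the
predicted mask, 26-connected components, one-to-one coverage matching
at CV ≥ 0.5, stratified sensitivity and precision, and mean per-lesion
Dice over matched lesions at least 3 mm long. Sensitivity rises with
lesion size, as it should — sub-3 mm lesions are the hard stratum the
patch-focal weight targets (see the `sweep_w()` experiment in the
methods vignette). Desk-scale training (here under five minutes on one
CPU) demonstrates the pipeline's behavior, not converged accuracy.

Other entry points: `pretrain()` / `finetune()` / `run_two_stage()`
(the stages individually), `sweep_w()` (the focal-weight comparison),
`evaluate_masks()` / `evaluate_dirs()` (the evaluation protocol on your
own NIfTI masks), `separation_score()` and `tsne_embed()` (latent
diagnostics), and a thin command-line front end in
`inst/cli/lesionseg.R` with `simulate`, `pretrain`, `finetune`,
`run-all`, `sweep-w`, `evaluate` and `embed` subcommands.

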