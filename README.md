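# weedseg

Tools for separating green seedlings from cluttered field backgrounds and
classifying them — aimed at researchers building weed/crop recognition
pipelines who need the preprocessing and the model to be testable at desk
scale, without external image downloads.

The package has three parts:

1. **Background suppression.** Dense turf and soil are fine-grained; broad
   seedling leaves are smooth. The chain exploits this: the excess-green
   index ExG = 2g − r − b (on chromatic coordinates r, g, b, which cancel
   illumination) isolates green matter; a 3×3 local-variance map v(x,y)
   measures texture; the concave normalization V = a·v/(b·v + (a−b))
   (a = 6, b = 5) expands small-variance contrast; the exponential gain
   1/(exp(kV²) − m) (k = 50, m = 0.99) then amplifies gray levels where
   V < V* = √(ln(1+m)/k) ≈ 0.12 and crushes them above it. Otsu
   binarization plus morphological opening/closing yields a plant mask
   that is ANDed with the original image.
2. **Dataset handling.** Manifest bookkeeping, exact dataset doubling by
   seeded noise/flip augmentation, bilinear 256→224 resize/center-crop,
   and seeded train/test splitting.
3. **Attention-DenseNet classifier.** Four densely connected blocks
   (6, 12, 24, 16 connections, growth 32) with an efficient-channel-
   attention (ECA) reweighting after every dense connection — per-channel
   weights σ(Conv1D_k(GAP(x))) with adaptive odd kernel
   k = |log₂(C)/γ + β/γ|_odd, γ = 2, β = 1 — transitions (3×3 conv +
   average pool), one plain dense connection, two 3×3 decoder
   deconvolutions, dropout 0.5, global average pooling and a linear head.
   Training (Adam, lr 1e-4, batch 64, 40 epochs at full scale) runs on a
   compact self-contained engine in R matrix algebra whose gradients are
   verified against finite differences in the test suite.

A synthetic fixture generator produces leaf-on-turf/soil imagery with
exact ground-truth masks and labels, so every stage is exercised without
external data.

## Worked example

```r
library(weedseg)

# --- segmentation on a fixture with known ground truth -------------------
fx  <- make_fixture(fixture_spec(image_size = 128, n_leaves = 2,
                                 leaf_scale = 24, seed = 7))
seg <- segment_plant(fx$image)
sprintf("IoU vs ground truth: %.3f", mask_iou(seg$mask, fx$mask))
#> "IoU vs ground truth: 0.908"
sprintf("gain crossover V*: %.4f", enhancement_crossover())
#> "gain crossover V*: 0.1173"

# --- benchmark-shaped dataset arithmetic ---------------------------------
man <- manifest_from_counts(seedling_class_counts())   # 5,539 raw entries
ext <- expand_dataset(man, seed = 1)                   # doubled: 11,078
sp  <- split_dataset(ext, ratio = 0.8, seed = 1)
c(train = sum(sp$split == "train"), test = sum(sp$split == "test"))
#> train  test
#>  8862  2216

# --- scaled classifier on a 2-class fixture set --------------------------
cs  <- make_classification_set(n_classes = 2, per_class = 20,
                               seed = 11, image_size = 32)
d   <- list(x = stack_images(cs$images), y = cs$labels)
cfg <- eca_dense_config(block_sizes = c(1, 1, 1, 1), growth_rate = 4,
                        dropout = 0.1, input_size = 32, num_classes = 2)
fit <- train_model(build_model(cfg, seed = 3), d,
                   train_config(learning_rate = 3e-3, batch_size = 8,
                                epochs = 30, seed = 3),
                   stop_at_train_acc = 1)
tail(fit$history, 1)
#>    epoch      loss train_acc valid_acc
#> 16    16 0.1088676         1        NA
```

The IoU is the overlap between the recovered mask and the painted leaf
region; 0.908 means the chain recovered the plant almost exactly from a
high-frequency turf background. The 5,539 → 11,078 → 8,862/2,216 chain
reproduces the per-class doubling and 0.8 floor split of the 12-class
seedling benchmark's bookkeeping. The training trace shows the scaled
model reaching 100% training accuracy at epoch 16 — a capacity sanity
check, not a claim about field accuracy.

## Command line

```sh
Rscript inst/cli/weedseg.R synth   --out run/data --seed 1
Rscript inst/cli/weedseg.R segment --in run/data --out run/seg
Rscript inst/cli/weedseg.R augment --in run/data --out run/aug --seed 1
Rscript inst/cli/weedseg.R split   --in run/aug  --out run/split --ratio 0.8
Rscript inst/cli/weedseg.R train   --in run/split --out run/model
Rscript inst/cli/weedseg.R eval    --in run/split --weights run/model/weights.rds --out run/eval
```

Flags `--no-eca` and `--no-preprocess` build the ablation arms; every run
echoes its configuration to `config.yaml` and writes a machine-readable
`summary.json` in the output directory. A YAML with every default is
produced by `write_config(default_config(), "config.yaml")`.

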