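# thermoseg

Integrated segmentation and classification of plantar thermograms for
diabetic-foot-ulcer risk screening, implemented natively in R.

Elevated plantar temperature is an early marker of ulceration risk in
diabetic feet. Given a single-channel thermogram, `thermoseg` (1) segments
hyperthermic lesion regions with a U-shaped network of modified
Swin-transformer blocks (U-MST), (2) extracts a compact feature vector with
a capsule network trained by dynamic routing, and (3) classifies the foot
as control (CG) or diabetic (DM) with an extreme learning machine (ELM)
whose output weights are solved in closed form.

The three tiers, in the field's usual notation:

* **U-MST** — tokens from a patch partition pass through blocks
  `u = x + Attn(Norm(x))`, `out = u + MLP(Norm(u))`, where `Attn` is
  window-restricted multi-head self-attention (W-MHSA), its cyclically
  shifted variant (SW-MHSA, with exact cross-boundary masking and relative
  position bias), or a hybrid channel–spatial gate (SW-HCMA). Patch merging
  halves the grid and doubles the channels per stage; a fusion module
  folds each encoder stage into the next; the decoder mirrors the encoder
  with learned 2× upsampling and skip connections and ends in a per-pixel
  logit map. Segmentation trains on the soft Dice loss
  `1 − (2|S∩T|+ε)/(|S|+|T|+ε)`.
* **Capsules** — primary capsules from the bottleneck are squashed
  (`v ↦ v·‖v‖/(1+‖v‖²)`), routed for 3 iterations
  (`D = softmax(b)`, `S_j = Σ_i D_ij·Ŷ_ij`, `G_j = squash(S_j)`,
  `b_ij += Ŷ_ij·G_j`), and reduced to a feature vector `Z`.
* **ELM** — hidden layer `h(x) = σ(xW + b)` with fixed random weights;
  output weights `β = Hᵀ(I/C + HHᵀ)⁻¹O` (dual form; primal when `N > L`),
  class probabilities `softmax(h(x)β)`.

Training combines both objectives, `L = 0.6·L_seg + 0.4·L_cls`
(Dice + cross-entropy), under ADAM with early stopping; the ELM is then
fitted on the frozen capsule features. Evaluation uses subject-level
stratified five-fold cross-validation with Dice/IoU/precision/recall for
segmentation and accuracy/precision/recall/F1 for classification.

Because the clinical dataset the design targets is not redistributable,
the package includes a synthetic thermogram generator (foot-shaped
support, smooth temperature field, Gaussian hot-spot lesions with
ground-truth masks) emulating the 122 DM / 45 CG study composition, plus
readers/writers for the on-disk layout (16-bit TIFF images, 8-bit PNG
masks, CSV manifest). The trainable tiers run on an in-package
reverse-mode autodiff tape over base-R arrays with a small C++ kernel for
batched matrix products; every gradient rule is finite-difference tested.

## Worked example

```r
library(thermoseg)

# a small synthetic cohort: 8 diabetic feet, 4 controls
recs <- generate_cohort(synth_config(n_dm = 8, n_cg = 4, image_size = 64,
                                     seed = 1))
recs <- lapply(recs, preprocess_record)     # pixel screening + CLAHE
train <- recs[c(1:6, 9:10)]                 # 6 DM + 2 CG
test  <- recs[c(7:8, 11:12)]                # 2 DM + 2 CG

model <- create_model(
  umst_config(image_size = 64, embed_dim = 16, depths = c(1, 1, 1),
              heads = c(2, 2, 2), norm_kind = "layer_norm"),
  caps_config(primary_dim = 8, n_out = 4, out_dim = 8, feature_dim = 16),
  elm_L = 100, seed = 2)

cfg <- train_config(lr = 1e-3, epochs_max = 20, batch_size = 4,
                    early_stop_patience = 6, seed = 2)
model <- train_model(model, train, cfg)
round(evaluate_model(model, test), 3)
```

```
          dsc           iou seg_precision    seg_recall      accuracy
        0.821         0.737         0.739         0.989         1.000
    precision        recall            f1
        1.000         1.000         1.000
```

The first four numbers measure mask overlap on the four held-out feet:
mean Dice 0.821 and IoU 0.737 against the ground-truth lesion masks, with
segmentation recall 0.989 (nearly all true lesion pixels recovered) and
precision 0.739 (the predicted masks are slightly generous). The last
four say all four feet were assigned to the correct group (DM vs CG).

Five-fold cross-validation of the full pipeline, and the command-line
interface:

```r
report <- run_cv(recs, cfg, k = 5)   # needs >= 5 subjects per class
print(report)
```

```sh
Rscript inst/cli/thermoseg.R generate --config cfg.yaml --out data/
Rscript inst/cli/thermoseg.R cv --config cfg.yaml --out results/
```

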