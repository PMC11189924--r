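# pointcell

Instance segmentation of **overlapping cervical cells** (Pap-smear
cytology) with PointRend-style boundary refinement, implemented end to end
in R — model, training, inference, synthetic data, and the
overlapping-cytology challenge evaluation protocol — at a scale that trains
and evaluates in minutes on one CPU.

## Who this is for

Researchers in biomedical image analysis who need (a) a transparent,
fully tested reference implementation of uncertainty-driven mask
refinement for translucent, mutually overlapping objects, and (b) the
cytology challenge metrics (DSC-threshold matching, TPRp/FPRp with the
exclusion rule, object false-negative rate, COCO mask AP, stratified
reports) as reusable, oracle-verified components. Overlap is the defining
property of the task: ground truth is a *set of per-cell binary masks that
may share pixels*, so a label image cannot represent it and ordinary
semantic segmentation does not apply.

## The method

A two-stage detector with a refined mask branch:

1. a backbone + feature pyramid produces `P2..P5` (strides 4/8/16/32);
2. each proposal is cropped by **RoI align** (continuous bilinear
   sampling, no quantization) to 7×7 and up-sampled by transposed
   convolutions to a **coarse 28×28 mask** `Y' = sigmoid(C^T X')`;
3. the `n` most *uncertain* points — foreground probability closest to
   0.5, i.e. boundary-adjacent — are re-classified by a **point head**:
   per point, a fine-grained feature bilinearly sampled from `P2` is
   concatenated with a coarse region feature sampled from the proposal's
   own RoI grid, and an MLP of α layers × width 256 (a 1×1 convolution
   along the point axis) predicts the label. The region feature is what
   lets two overlapping cells label the *same pixel* differently;
4. training minimizes the unweighted sum
   `L = L_mask + L_point + L_box + L_cls`, where
   `L_point = -[y log σ(x) + (1-y) log(1-σ(x))]` over 196 sampled points
   per instance (784 at inference), by SGD (lr 0.002, momentum 0.9);
5. at inference the 28×28 grid is iteratively up-sampled ×2 with the 784
   most uncertain locations re-predicted per pass, then pasted into the
   image frame.

A synthetic scene generator (perturbed-ellipse cells, multiplicative
translucent blending so clump interiors darken, controllable cell count
2–10 and mean overlap rate 0–0.5) supplies reproducible ground truth, so
nothing external is downloaded. All forward *and backward* passes are
written in vectorised base R and verified against finite differences in
the test suite.

## Worked example

Train on 32 synthetic 128×128 scenes (2–6 cells, overlap rates 0–0.3) and
evaluate on 10 held-out scenes:

```r
library(pointcell)

cfg_s <- synth_config(image_size = 128, n_cells_range = c(2, 6),
                      target_overlap_rate = c(0, 0.3),
                      cell = cell_params(128), seed = 11)
train_set <- synth_dataset(32, cfg_s)
eval_set  <- synth_dataset(10, cfg_s, start_index = 1001)

ck    <- train(train_set, model_config(epochs = 25, seed = 7))
preds <- predict_dataset(eval_set, ck)
evaluate_masks(lapply(eval_set, `[[`, "masks"), preds, threshold = 0.7)
```

```
Instance-segmentation report (DSC threshold 0.70, 10 images, 41 gt cells)
  DSC  0.925 +- 0.036   TPRp 0.981 +- 0.027
  FPRp 0.0085 +- 0.0042  FNRo 0.000
  AP 0.711  AP50 1.000  AP75 0.916
```

Reading: each of the 41 held-out cells was matched by a prediction with
Dice overlap ≥ 0.7 (FNRo = 0); matched masks agree with ground truth at
mean Dice 0.925; within matched pairs 98.1% of true cytoplasm pixels are
recovered (TPRp) while 0.85% of each pair's background is falsely claimed
(FPRp). Switching the point head off at inference
(`predict_dataset(eval_set, ck, use_point_head = FALSE)`) drops mean DSC
to 0.868 on the same run — the refinement stage contributes about +0.06
Dice, concentrated at clump boundaries.

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/pointcell.R` (`synth`, `train`, `predict`, `evaluate`, `ablate`,
`report` subcommands).

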