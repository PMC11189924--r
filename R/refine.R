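# PointRend-style inference refinement: iteratively up-sample the coarse
# 28x28 mask probabilities, re-predict only the most uncertain locations with
# the point head, and paste the result into full image coordinates.

#' Point predictor closure from a trained checkpoint
#'
#' Wraps the checkpoint's point head as \code{function(feats, pts_norm,
#' pts_img) -> logits} for use with \code{\link{refine_mask}}; test oracles
#' can supply the same interface while ignoring \code{feats}.
#'
#' @param checkpoint a trained checkpoint.
#' @return a predictor function.
#' @export
make_point_predictor <- function(checkpoint) {
  function(feats, pts_norm, pts_img) point_head(feats, checkpoint)
}

# nearest candidate-grid cell of normalized points
norm_to_cells <- function(pts, hw) {
  i <- pmin(pmax(floor(pts$y * hw[1]) + 1L, 1L), hw[1])
  j <- pmin(pmax(floor(pts$x * hw[2]) + 1L, 1L), hw[2])
  cbind(i, j)
}

#' Refine a coarse mask by re-predicting uncertain points
#'
#' Per pass: bilinearly up-sample the current probability grid x2, select the
#' \code{n_points} most uncertain locations (closest to probability 0.5,
#' i.e. boundary-adjacent), build their concatenated fine (P2) + coarse (RoI
#' feature) point features, and overwrite exactly those locations with the
#' point head's sigmoid output; every other location keeps its interpolated
#' value. The default two passes bring 28 up to 112; \code{passes = 1}
#' reproduces a literal single-pass reading. \code{n_points = 0} (or a NULL
#' head) degenerates to plain bilinear up-sampling.
#'
#' @param coarse 28x28 (or \code{mask_out}-sized) probability matrix.
#' @param pyramid feature pyramid (needs \code{$P2}, a \code{grid_feature}).
#' @param roi_feat the RoI-aligned feature the coarse mask came from.
#' @param box the detection's \code{pc_box} (image coordinates).
#' @param head predictor from \code{\link{make_point_predictor}} (or an
#'   oracle with the same signature), or NULL.
#' @param n_points points re-predicted per pass (inference default 784).
#' @param passes number of x2 subdivision passes (default 2).
#' @param strategy point-selection strategy (default \code{"topk"},
#'   deterministic).
#' @return probability matrix at the refined resolution.
#' @export
refine_mask <- function(coarse, pyramid, roi_feat, box, head,
                        n_points = 784L, passes = 2L, strategy = "topk") {
  cur <- coarse
  roi_out <- dim(roi_feat)[1]
  roi_g <- grid_feature(roi_feat, stride = 1)
  for (p in seq_len(passes)) {
    hw <- 2L * dim(cur)
    up <- upsample_bilinear(cur, hw)
    if (!is.null(head) && n_points >= 1L) {
      n_sel <- min(n_points, prod(hw))
      sel <- select_points(pmin(pmax(up, 0), 1), n_sel, strategy)
      pts_img <- norm_to_image(sel, box)
      fine <- bilinear_sample(pyramid$P2, pts_img)
      coarse_f <- bilinear_sample(roi_g, point_set(sel$x * roi_out, sel$y * roi_out,
                                                   frame = "image"))
      logits <- head(cbind(fine, coarse_f), sel, pts_img)
      up[norm_to_cells(sel, hw)] <- sigmoid(logits)
    }
    cur <- up
  }
  cur
}

#' Paste a box-resolution probability grid into image coordinates
#'
#' Bilinearly resamples the probability grid over the (clipped) box
#' footprint, leaves zero outside the box, and thresholds at
#' \code{threshold}.
#'
#' @param prob probability matrix over the box.
#' @param box a \code{pc_box}.
#' @param image_hw integer c(H, W).
#' @param threshold binarization threshold (default 0.5); \code{NA} returns
#'   the full-image probability map instead of a binary mask.
#' @return H x W logical matrix (or numeric when \code{threshold} is NA);
#'   NULL when the clipped box is empty or the pasted mask has no pixels.
#' @export
paste_mask <- function(prob, box, image_hw, threshold = 0.5) {
  b <- clip_box(box, image_hw)
  if (is.null(b)) return(NULL)
  H <- image_hw[1]; W <- image_hw[2]
  rows <- which((seq_len(H) - 0.5) >= b["y1"] & (seq_len(H) - 0.5) < b["y2"])
  cols <- which((seq_len(W) - 0.5) >= b["x1"] & (seq_len(W) - 0.5) < b["x2"])
  out <- matrix(0, H, W)
  if (length(rows) && length(cols)) {
    g <- grid_feature(prob, stride = 1)
    ph <- nrow(prob); pw <- ncol(prob)
    # pixel centers -> normalized position inside the *unclipped* box -> grid
    u <- (cols - 0.5 - unname(box["x1"])) / box_width(box)
    v <- (rows - 0.5 - unname(box["y1"])) / box_height(box)
    pts <- expand.grid(y = v * ph, x = u * pw)
    out[rows, cols] <- matrix(bilinear_sample(g, point_set(pts$x, pts$y,
                                                           frame = "image"))[, 1],
                              length(rows), length(cols))
  }
  if (is.na(threshold)) return(out)
  m <- out >= threshold
  if (!any(m)) return(NULL)
  m
}

all_zero_params <- function(tree) {
  all(vapply(rapply(tree, function(x) all(x == 0), how = "unlist"), isTRUE, logical(1)))
}

#' End-to-end inference on one image
#'
#' Backbone, proposals, class scoring, per-detection coarse mask, point
#' refinement, and pasting. In \code{gt_boxes} mode the proposals are the
#' (unjittered) tight ground-truth boxes, so \code{gt} must be supplied; in
#' \code{learned_rpn} mode proposals come from the scored anchor grid.
#' Deterministic given checkpoint + image (top-k point selection). Images
#' whose sides are not divisible by 32 are padded for the backbone (with a
#' message) and results are reported in the original frame.
#'
#' @param image H x W matrix in [0, 1].
#' @param checkpoint a trained checkpoint from \code{\link{train}}.
#' @param gt \code{instance_mask_set} (required in gt_boxes proposal mode).
#' @param passes,use_point_head optional overrides of the checkpoint config.
#' @return list of detections, each \code{list(box, score, mask,
#'   mask_prob)}; zero-pixel or low-score detections are dropped.
#' @export
predict_cells <- function(image, checkpoint, gt = NULL, passes = NULL,
                          use_point_head = NULL) {
  cfg <- checkpoint$config
  if (!is.null(passes)) cfg$passes <- as.integer(passes)
  if (!is.null(use_point_head)) cfg$use_point_head <- isTRUE(use_point_head)
  hw0 <- dim(image)
  pad_h <- (32L - hw0[1] %% 32L) %% 32L
  pad_w <- (32L - hw0[2] %% 32L) %% 32L
  if (pad_h || pad_w) {
    message("predict_cells: padding image from ", hw0[1], "x", hw0[2],
            " to the next multiple of 32")
    padded <- matrix(stats::median(image), hw0[1] + pad_h, hw0[2] + pad_w)
    padded[seq_len(hw0[1]), seq_len(hw0[2])] <- image
    image <- padded
  }
  hw <- dim(image)
  params <- checkpoint$params
  bf <- backbone_forward(params, image, cfg)
  P2 <- grid_feature(bf$P$P2, 4)
  pyramid <- list(P2 = P2, P3 = grid_feature(bf$P$P3, 8),
                  P4 = grid_feature(bf$P$P4, 16), P5 = grid_feature(bf$P$P5, 32))

  boxes <- if (cfg$proposal_mode == "gt_boxes") {
    if (is.null(gt)) stop("predict_cells: gt_boxes proposal mode requires gt masks")
    if (length(gt$masks)) lapply(gt$masks, mask_tight_box) else list()
  } else {
    propose_rpn(params, P2, hw, cfg)
  }
  if (!length(boxes)) return(list())

  head_fn <- NULL
  if (cfg$use_point_head) {
    if (all_zero_params(params$point)) {
      warning("predict_cells: point head is all zeros (untrained); refinement skipped",
              call. = FALSE)
    } else head_fn <- make_point_predictor(checkpoint)
  }

  dets <- list()
  for (b in boxes) {
    roi <- roi_align(P2, b, cfg$roi_out, cfg$sampling_ratio)
    pooled <- matrix(apply(roi, 3, mean), 1L)
    h <- pmax(sweep(pooled %*% params$head$fc1$w, 2L, params$head$fc1$b, "+"), 0)
    score <- sigmoid((h %*% params$head$cls$w + params$head$cls$b)[1, 1])
    if (score < cfg$score_threshold) next
    mh <- mask_head_forward(params$mask, roi)
    prob <- if (!is.null(head_fn) && cfg$passes > 0L)
      refine_mask(mh$probs, pyramid, roi, b, head_fn,
                  n_points = cfg$beta_infer, passes = cfg$passes,
                  strategy = cfg$point_strategy_infer)
    else if (cfg$passes > 0L)
      refine_mask(mh$probs, pyramid, roi, b, head = NULL, n_points = 0L,
                  passes = cfg$passes)
    else mh$probs
    mp <- paste_mask(prob, b, hw, threshold = NA)
    m <- mp >= cfg$mask_threshold
    m <- m[seq_len(hw0[1]), seq_len(hw0[2]), drop = FALSE]
    if (!any(m)) next
    dets[[length(dets) + 1L]] <- list(box = b, score = score, mask = m,
                                      mask_prob = mp[seq_len(hw0[1]), seq_len(hw0[2]),
                                                     drop = FALSE])
  }
  dets
}

#' Run inference over a dataset of scenes
#'
#' Convenience wrapper calling \code{\link{predict_cells}} per scene (passing
#' each scene's ground truth through in gt_boxes proposal mode).
#'
#' @param dataset list of scenes (image + masks).
#' @param checkpoint trained checkpoint.
#' @param ... forwarded to \code{\link{predict_cells}}.
#' @return list of per-scene detection lists.
#' @export
predict_dataset <- function(dataset, checkpoint, ...) {
  lapply(dataset, function(sc) predict_cells(sc$image, checkpoint, gt = sc$masks, ...))
}
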