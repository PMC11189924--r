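# Two-stage instance-segmentation network at desk scale: a tiny CNN backbone
# with a feature-pyramid neck, teacher-forced (ground-truth-box) or anchor
# proposals, a box/class head, the 7x7 -> 28x28 transposed-convolution mask
# branch, and the point head that re-predicts uncertain boundary points from
# concatenated fine (P2) + coarse (RoI) features. Forward and backward passes
# are explicit; training is SGD with momentum.

#' Model configuration
#'
#' Defaults follow the reference training recipe: three point-head layers of
#' width 256 (\code{alpha = 3}), 196 training / 784 inference points
#' (\code{beta}), fine-grained point features sampled from P2, learning rate
#' 0.002 with momentum 0.9, two images per batch, and an unweighted four-term
#' loss. The \code{"tiny"} backbone (stage widths 16/32/64/128, pyramid width
#' 32) is the tested desk-scale default; \code{"resnet_like"} doubles widths
#' and depth per stage for larger runs.
#'
#' @param backbone_spec \code{"tiny"} or \code{"resnet_like"}.
#' @param alpha number of point-head layers, one of 2, 3, 4.
#' @param beta_train,beta_infer points selected during training / inference.
#' @param point_head_width hidden width of the point head.
#' @param proposal_mode \code{"gt_boxes"} (jittered tight ground-truth boxes;
#'   the tested default) or \code{"learned_rpn"} (anchor grid scored by the
#'   class head with NMS).
#' @param roi_out RoI-align output side (7); \code{mask_out} is fixed to
#'   \code{4 * roi_out} by the two x2 up-sampling stages.
#' @param sampling_ratio RoI-align samples per output cell side.
#' @param fpn_width channel width of the pyramid.
#' @param lr,momentum,weight_decay,epochs,batch_size SGD settings.
#' @param use_point_head FALSE gives the coarse-mask-only ablation baseline
#'   (no point loss, no refinement).
#' @param point_strategy_train,point_strategy_infer point-selection strategies.
#' @param jitter proposal-box jitter as a fraction of the box side (<= 0.1).
#' @param passes refinement passes at inference (2 brings 28 to 112).
#' @param score_threshold,mask_threshold detection score / mask binarization
#'   cutoffs.
#' @param neg_per_image background boxes sampled per image for the class head.
#' @param augment apply random flip/rotation/scale augmentation during training.
#' @param seed RNG seed controlling initialisation and all training randomness.
#' @return a \code{model_config} list.
#' @export
model_config <- function(backbone_spec = c("tiny", "resnet_like"),
                         alpha = 3L, beta_train = 196L, beta_infer = 784L,
                         point_head_width = 256L,
                         proposal_mode = c("gt_boxes", "learned_rpn"),
                         roi_out = 7L, sampling_ratio = 2L, fpn_width = 32L,
                         lr = 0.002, momentum = 0.9, weight_decay = 0,
                         epochs = 50L, batch_size = 2L,
                         use_point_head = TRUE,
                         point_strategy_train = "oversample_random",
                         point_strategy_infer = "topk",
                         jitter = 0.1, passes = 2L,
                         score_threshold = 0.5, mask_threshold = 0.5,
                         neg_per_image = 2L, augment = TRUE, seed = 1L) {
  backbone_spec <- match.arg(backbone_spec)
  proposal_mode <- match.arg(proposal_mode)
  if (!alpha %in% 2:4) stop("model_config: alpha must be one of 2, 3, 4")
  if (beta_train < 1 || beta_infer < 1) stop("model_config: beta must be >= 1")
  cfg <- list(backbone_spec = backbone_spec,
              widths = if (backbone_spec == "tiny") c(16L, 32L, 64L, 128L, 128L)
                       else c(32L, 64L, 128L, 256L, 256L),
              convs_per_stage = if (backbone_spec == "tiny") 1L else 2L,
              alpha = as.integer(alpha),
              beta_train = as.integer(beta_train),
              beta_infer = as.integer(beta_infer),
              point_head_width = as.integer(point_head_width),
              proposal_mode = proposal_mode,
              roi_out = as.integer(roi_out), mask_out = 4L * as.integer(roi_out),
              sampling_ratio = as.integer(sampling_ratio),
              fpn_width = as.integer(fpn_width),
              lr = lr, momentum = momentum, weight_decay = weight_decay,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              use_point_head = isTRUE(use_point_head),
              point_strategy_train = point_strategy_train,
              point_strategy_infer = point_strategy_infer,
              jitter = jitter, passes = as.integer(passes),
              score_threshold = score_threshold, mask_threshold = mask_threshold,
              neg_per_image = as.integer(neg_per_image),
              augment = isTRUE(augment), seed = as.integer(seed))
  class(cfg) <- "model_config"
  cfg
}

# Parameter initialisation ------------------------------------------------------

init_model <- function(cfg) {
  w <- cfg$widths; F <- cfg$fpn_width
  stage <- function(cin, cout, n) {
    ly <- list(list(w = init_conv(3, 3, cin, cout), b = numeric(cout)))
    for (i in seq_len(n - 1L))
      ly <- c(ly, list(list(w = init_conv(3, 3, cout, cout), b = numeric(cout))))
    ly
  }
  backbone <- list(stage(1L, w[1], 1L),                       # stem, stride 2
                   stage(w[1], w[2], cfg$convs_per_stage),    # -> C2, stride 4
                   stage(w[2], w[3], cfg$convs_per_stage),    # -> C3, stride 8
                   stage(w[3], w[4], cfg$convs_per_stage),    # -> C4, stride 16
                   stage(w[4], w[5], cfg$convs_per_stage))    # -> C5, stride 32
  fpn <- list(lat = lapply(2:5, function(l) list(w = init_conv(1, 1, w[l], F), b = numeric(F))),
              sm  = lapply(2:5, function(l) list(w = init_conv(3, 3, F, F), b = numeric(F))))
  mask <- list(conv1 = list(w = init_conv(3, 3, F, F), b = numeric(F)),
               de1 = list(w = init_conv(2, 2, F, F), b = numeric(F)),
               de2 = list(w = init_conv(2, 2, F, F), b = numeric(F)),
               proj = list(w = init_conv(1, 1, F, 1L), b = numeric(1)))
  head <- list(fc1 = list(w = init_linear(F, 64L), b = numeric(64)),
               cls = list(w = init_linear(64L, 1L), b = numeric(1)),
               box = list(w = init_linear(64L, 4L, scale = 0.1), b = numeric(4)))
  pw <- cfg$point_head_width
  pl <- list(list(w = init_linear(2L * F, pw), b = numeric(pw)))
  for (i in seq_len(cfg$alpha - 1L))
    pl <- c(pl, list(list(w = init_linear(pw, pw), b = numeric(pw))))
  pl <- c(pl, list(list(w = init_linear(pw, 1L), b = numeric(1))))
  list(backbone = backbone, fpn = fpn, mask = mask, head = head, point = pl)
}

# Backbone + FPN ----------------------------------------------------------------

backbone_forward <- function(params, image, cfg) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("backbone: image dims must be divisible by 32, got ", d[1], "x", d[2])
  x <- image - 0.5                       # center gray levels
  caches <- list(); feats_c <- list()
  for (s in seq_along(params$backbone)) {
    st_cache <- list()
    for (li in seq_along(params$backbone[[s]])) {
      ly <- params$backbone[[s]][[li]]
      cf <- conv2d_fwd(x, ly$w, ly$b, stride = if (li == 1L) 2L else 1L, pad = 1L)
      rf <- relu_fwd(cf$out)
      st_cache[[li]] <- list(conv = cf$cache, relu = rf$cache)
      x <- rf$out
    }
    caches[[s]] <- st_cache
    feats_c[[s]] <- x
  }
  # FPN: lateral 1x1 on C2..C5, top-down nearest x2 adds, 3x3 smoothing
  lat_out <- list(); lat_cache <- list()
  for (l in 1:4) {
    cf <- conv2d_fwd(feats_c[[l + 1L]], params$fpn$lat[[l]]$w, params$fpn$lat[[l]]$b)
    lat_out[[l]] <- cf$out; lat_cache[[l]] <- cf$cache
  }
  M <- vector("list", 4L)
  M[[4]] <- lat_out[[4]]
  for (l in 3:1) M[[l]] <- lat_out[[l]] + upsample_nn2_fwd(M[[l + 1L]])
  P <- vector("list", 4L); sm_cache <- vector("list", 4L)
  for (l in 1:4) {
    cf <- conv2d_fwd(M[[l]], params$fpn$sm[[l]]$w, params$fpn$sm[[l]]$b,
                     stride = 1L, pad = 1L)
    P[[l]] <- cf$out; sm_cache[[l]] <- cf$cache
  }
  names(P) <- c("P2", "P3", "P4", "P5")
  list(P = P,
       cache = list(stages = caches, lat = lat_cache, sm = sm_cache,
                    dims = lapply(M, dim)))
}

# dP: list of gradients for P2..P5 (NULL entries allowed).
backbone_backward <- function(params, cache, dP) {
  g_lat <- vector("list", 4L); g_sm <- vector("list", 4L)
  dM <- vector("list", 4L)
  for (l in 1:4) {
    if (is.null(dP[[l]])) {
      dM[[l]] <- array(0, cache$dims[[l]])
      g_sm[[l]] <- list(w = array(0, dim(params$fpn$sm[[l]]$w)),
                        b = numeric(length(params$fpn$sm[[l]]$b)))
    } else {
      bw <- conv2d_bwd(dP[[l]], params$fpn$sm[[l]]$w, cache$sm[[l]])
      g_sm[[l]] <- list(w = bw$dW, b = bw$db)
      dM[[l]] <- bw$dx
    }
  }
  # top-down chain: dM_l feeds dM_{l+1} through the x2 up-sample
  dC <- vector("list", 4L)
  for (l in 1:4) {
    if (l < 4L) dM[[l + 1L]] <- dM[[l + 1L]] + upsample_nn2_bwd(dM[[l]])
    bw <- conv2d_bwd(dM[[l]], params$fpn$lat[[l]]$w, cache$lat[[l]])
    g_lat[[l]] <- list(w = bw$dW, b = bw$db)
    dC[[l]] <- bw$dx
  }
  # backbone stages, top stage first; dC[[l]] is the grad of stage l+1 output
  g_stages <- vector("list", 5L)
  dnext <- NULL
  for (s in 5:1) {
    dout <- if (s >= 2L) dC[[s - 1L]] else NULL
    if (!is.null(dnext)) dout <- if (is.null(dout)) dnext else dout + dnext
    st <- params$backbone[[s]]; st_cache <- cache$stages[[s]]
    g_st <- vector("list", length(st))
    for (li in rev(seq_along(st))) {
      dr <- relu_bwd(dout, st_cache[[li]]$relu)
      bw <- conv2d_bwd(dr, st[[li]]$w, st_cache[[li]]$conv)
      g_st[[li]] <- list(w = bw$dW, b = bw$db)
      dout <- bw$dx
    }
    g_stages[[s]] <- g_st
    dnext <- dout
  }
  list(backbone = g_stages, fpn = list(lat = g_lat, sm = g_sm))
}

#' Build a backbone feature extractor
#'
#' Returns a function mapping an image (H x W matrix, dims divisible by 32)
#' to the feature pyramid P2..P5 (strides 4/8/16/32, common channel width).
#'
#' @param config a \code{model_config}.
#' @param params optional parameter tree (e.g. from a checkpoint); freshly
#'   initialised from \code{config$seed} when NULL.
#' @return function(image) -> named list of \code{grid_feature}s P2..P5.
#' @export
build_backbone <- function(config = model_config(), params = NULL) {
  if (is.null(params)) { set.seed(config$seed); params <- init_model(config) }
  force(config)
  function(image) {
    bf <- backbone_forward(params, image, config)
    list(P2 = grid_feature(bf$P$P2, 4), P3 = grid_feature(bf$P$P3, 8),
         P4 = grid_feature(bf$P$P4, 16), P5 = grid_feature(bf$P$P5, 32))
  }
}

# Proposals ---------------------------------------------------------------------

#' Supply proposal boxes for an image
#'
#' \code{gt_boxes} mode (teacher forcing): tight bounding boxes of the
#' ground-truth masks, each side jittered by up to \code{config$jitter} of
#' the box side (uses the R global random stream; zero jitter returns the
#' exact tight boxes). \code{learned_rpn} mode scores an anchor grid with
#' the trained class head and applies NMS; it needs \code{checkpoint}.
#'
#' @param image H x W image matrix.
#' @param gt an \code{instance_mask_set} (required in gt_boxes mode).
#' @param config a \code{model_config}.
#' @param checkpoint trained checkpoint (learned_rpn mode only).
#' @return list of \code{pc_box} (possibly empty).
#' @export
propose <- function(image, gt = NULL, config = model_config(), checkpoint = NULL) {
  if (config$proposal_mode == "gt_boxes") {
    if (is.null(gt)) stop("propose: gt_boxes mode requires ground-truth masks")
    if (length(gt$masks) == 0L) return(list())
    hw <- dim(image)
    lapply(gt$masks, function(m) jitter_box(mask_tight_box(m), config$jitter, hw))
  } else {
    if (is.null(checkpoint)) stop("propose: learned_rpn mode requires a checkpoint")
    bf <- backbone_forward(checkpoint$params, image, config)
    propose_rpn(checkpoint$params, grid_feature(bf$P$P2, 4), dim(image), config)
  }
}

jitter_box <- function(box, jitter, hw) {
  if (jitter <= 0) return(box)
  w <- box_width(box); h <- box_height(box)
  j <- stats::runif(4, -jitter, jitter)
  b <- clip_box(pc_box(box["x1"] + j[1] * w, box["y1"] + j[2] * h,
                       box["x2"] + j[3] * w, box["y2"] + j[4] * h), hw)
  if (is.null(b)) box else b
}

box_iou <- function(a, b) {
  ix <- max(0, min(a["x2"], b["x2"]) - max(a["x1"], b["x1"]))
  iy <- max(0, min(a["y2"], b["y2"]) - max(a["y1"], b["y1"]))
  inter <- ix * iy
  ua <- box_width(a) * box_height(a) + box_width(b) * box_height(b) - inter
  unname(inter / ua)
}

# Desk-scale anchor proposals: square-ish anchors on a stride-16 grid scored
# by the trained class head, refined by the box head, then NMS.
propose_rpn <- function(params, P2, image_hw, cfg, max_det = 20L) {
  H <- image_hw[1]; W <- image_hw[2]
  centers_x <- seq(8, W - 8, by = 16)
  centers_y <- seq(8, H - 8, by = 16)
  scales <- c(0.15, 0.3, 0.5) * min(H, W)
  aspects <- c(0.6, 1, 1.6)
  cand <- list()
  for (cx in centers_x) for (cy in centers_y) for (s in scales) for (a in aspects) {
    w2 <- s * sqrt(a) / 2; h2 <- s / sqrt(a) / 2
    b <- clip_box(pc_box(cx - w2, cy - h2, cx + w2, cy + h2), image_hw)
    if (!is.null(b) && box_width(b) >= 8 && box_height(b) >= 8) cand[[length(cand) + 1L]] <- b
  }
  if (!length(cand)) return(list())
  scored <- lapply(cand, function(b) {
    roi <- roi_align(P2, b, cfg$roi_out, 1L)
    pooled <- matrix(apply(roi, 3, mean), 1L)
    h <- pmax(pooled %*% params$head$fc1$w + rep(params$head$fc1$b, each = 1L), 0)
    sc <- sigmoid((h %*% params$head$cls$w + params$head$cls$b)[1, 1])
    dl <- (h %*% params$head$box$w + rep(params$head$box$b, each = 1L))[1, ]
    list(box = apply_deltas(b, dl, image_hw), score = sc)
  })
  scored <- Filter(function(s) !is.null(s$box) && s$score >= cfg$score_threshold, scored)
  if (!length(scored)) return(list())
  ord <- order(-vapply(scored, function(s) s$score, numeric(1)))
  keep <- list()
  for (i in ord) {
    b <- scored[[i]]$box
    if (all(vapply(keep, function(k) box_iou(k, b) < 0.5, logical(1))))
      keep[[length(keep) + 1L]] <- b
    if (length(keep) >= max_det) break
  }
  keep
}

box_deltas <- function(prop, gt) {
  pw <- box_width(prop); ph <- box_height(prop)
  px <- (prop["x1"] + prop["x2"]) / 2; py <- (prop["y1"] + prop["y2"]) / 2
  gw <- box_width(gt); gh <- box_height(gt)
  gx <- (gt["x1"] + gt["x2"]) / 2; gy <- (gt["y1"] + gt["y2"]) / 2
  unname(c((gx - px) / pw, (gy - py) / ph, log(gw / pw), log(gh / ph)))
}

apply_deltas <- function(box, deltas, image_hw) {
  pw <- box_width(box); ph <- box_height(box)
  px <- (box["x1"] + box["x2"]) / 2; py <- (box["y1"] + box["y2"]) / 2
  deltas <- pmin(pmax(deltas, -2), 2)
  cx <- px + deltas[1] * pw; cy <- py + deltas[2] * ph
  w <- pw * exp(deltas[3]); h <- ph * exp(deltas[4])
  clip_box(pc_box(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2), image_hw)
}

# Heads --------------------------------------------------------------------------

mask_head_forward <- function(p, roi_feat) {
  c1 <- conv2d_fwd(roi_feat, p$conv1$w, p$conv1$b, stride = 1L, pad = 1L)
  r1 <- relu_fwd(c1$out)
  d1 <- deconv2_fwd(r1$out, p$de1$w, p$de1$b)
  r2 <- relu_fwd(d1$out)
  d2 <- deconv2_fwd(r2$out, p$de2$w, p$de2$b)
  r3 <- relu_fwd(d2$out)
  pj <- conv2d_fwd(r3$out, p$proj$w, p$proj$b)
  logits <- pj$out[, , 1]
  list(logits = logits, probs = sigmoid(logits),
       cache = list(c1 = c1$cache, r1 = r1$cache, d1 = d1$cache, r2 = r2$cache,
                    d2 = d2$cache, r3 = r3$cache, pj = pj$cache))
}

mask_head_backward <- function(p, cache, dlogits) {
  g <- array(dlogits, c(dim(dlogits), 1L))
  bpj <- conv2d_bwd(g, p$proj$w, cache$pj)
  g3 <- relu_bwd(bpj$dx, cache$r3)
  bd2 <- deconv2_bwd(g3, p$de2$w, cache$d2)
  g2 <- relu_bwd(bd2$dx, cache$r2)
  bd1 <- deconv2_bwd(g2, p$de1$w, cache$d1)
  g1 <- relu_bwd(bd1$dx, cache$r1)
  bc1 <- conv2d_bwd(g1, p$conv1$w, cache$c1)
  list(droi = bc1$dx,
       grads = list(conv1 = list(w = bc1$dW, b = bc1$db),
                    de1 = list(w = bd1$dW, b = bd1$db),
                    de2 = list(w = bd2$dW, b = bd2$db),
                    proj = list(w = bpj$dW, b = bpj$db)))
}

#' Coarse 28x28 mask prediction from a RoI feature
#'
#' One 3x3 convolution, two stride-2 2x2 transposed convolutions (7 -> 14 ->
#' 28, each ReLU-activated), and a 1x1 projection to a single logit channel.
#'
#' @param roi_feat \code{roi_out x roi_out x C} array from \code{\link{roi_align}}.
#' @param checkpoint a checkpoint (or list with \code{params}).
#' @return list with \code{logits} and \code{probs} (28 x 28 matrices).
#' @export
mask_head <- function(roi_feat, checkpoint) {
  if (length(dim(roi_feat)) != 3L)
    stop("mask_head: roi_feat must be an out x out x C array")
  mh <- mask_head_forward(checkpoint$params$mask, roi_feat)
  list(logits = mh$logits, probs = mh$probs)
}

point_head_forward <- function(pl, X) {
  caches <- list(); h <- X
  n_hidden <- length(pl) - 1L
  for (i in seq_len(n_hidden)) {
    lf <- linear_fwd(h, pl[[i]]$w, pl[[i]]$b)
    rf <- relu_fwd(lf$out)
    caches[[i]] <- list(lin = lf$cache, relu = rf$cache)
    h <- rf$out
  }
  lf <- linear_fwd(h, pl[[n_hidden + 1L]]$w, pl[[n_hidden + 1L]]$b)
  caches[[n_hidden + 1L]] <- list(lin = lf$cache)
  list(logits = lf$out[, 1], cache = caches)
}

point_head_backward <- function(pl, cache, dlogits) {
  n <- length(pl)
  grads <- vector("list", n)
  g <- matrix(dlogits, ncol = 1L)
  bw <- linear_bwd(g, pl[[n]]$w, cache[[n]]$lin)
  grads[[n]] <- list(w = bw$dW, b = bw$db)
  g <- bw$dx
  for (i in rev(seq_len(n - 1L))) {
    g <- relu_bwd(g, cache[[i]]$relu)
    bw <- linear_bwd(g, pl[[i]]$w, cache[[i]]$lin)
    grads[[i]] <- list(w = bw$dW, b = bw$db)
    g <- bw$dx
  }
  list(dX = g, grads = grads)
}

#' Point-head prediction for a batch of concatenated point features
#'
#' A shared per-point MLP (equivalently, 1x1 convolutions along the point
#' axis): \code{alpha} ReLU layers of the configured width and a final
#' linear map to one logit per point. No mixing across points, so permuting
#' the batch permutes the outputs identically.
#'
#' @param feats n x (2 * fpn_width) matrix of fine+coarse features.
#' @param checkpoint a checkpoint (or list with \code{params}).
#' @return numeric vector of n logits.
#' @export
point_head <- function(feats, checkpoint) {
  point_head_forward(checkpoint$params$point, feats)$logits
}

# Losses --------------------------------------------------------------------------

#' Binary cross-entropy loss of the point head
#'
#' Mean over the batch of \code{-[y log sigma(x) + (1 - y) log(1 - sigma(x))]},
#' computed in the numerically stabilised logit form.
#'
#' @param logits numeric vector of point logits.
#' @param labels 0/1 vector of ground-truth point labels.
#' @return nonnegative scalar loss.
#' @export
point_loss <- function(logits, labels) bce_with_logits(logits, labels)$loss

#' Four-term training loss
#'
#' The unweighted sum \code{L = L_mask + L_point + L_box + L_cls}, with the
#' breakdown retained for logging and loss curves.
#'
#' @param mask,point,box,cls nonnegative finite loss components.
#' @return list of class \code{loss_breakdown} with fields total, mask,
#'   point, box, cls.
#' @export
total_loss <- function(mask, point, box, cls) {
  v <- c(mask = mask, point = point, box = box, cls = cls)
  if (any(!is.finite(v))) stop("total_loss: non-finite loss component: ",
                               paste(names(v)[!is.finite(v)], collapse = ", "))
  if (any(v < 0)) stop("total_loss: negative loss component")
  structure(list(total = sum(v), mask = mask, point = point, box = box, cls = cls),
            class = "loss_breakdown")
}

# Ground-truth helpers ------------------------------------------------------------

# Resample a binary mask into the box at out x out resolution (bilinear on
# the indicator, threshold 0.5).
mask_in_box <- function(mask, box, out) {
  g <- grid_feature(mask * 1, stride = 1)
  u <- (seq_len(out) - 0.5) / out
  pts <- expand.grid(y = unname(box["y1"]) + u * box_height(box),
                     x = unname(box["x1"]) + u * box_width(box))
  matrix(bilinear_sample(g, point_set(pts$x, pts$y, frame = "image"))[, 1], out, out) >= 0.5
}

# Nearest-pixel ground-truth label at real-valued image points.
label_at_points <- function(mask, pts) {
  H <- nrow(mask); W <- ncol(mask)
  cc <- pmin(pmax(floor(pts$x) + 1L, 1L), W)
  rr <- pmin(pmax(floor(pts$y) + 1L, 1L), H)
  as.numeric(mask[cbind(rr, cc)])
}

# Full forward + backward pass on one scene; returns the loss breakdown and
# the parameter-gradient tree.
fb_scene <- function(params, scene, cfg) {
  img <- scene$image
  bf <- backbone_forward(params, img, cfg)
  F <- cfg$fpn_width
  P2 <- grid_feature(bf$P$P2, 4)
  dP2 <- array(0, dim(bf$P$P2))
  grads <- tree_zero_like(params)
  hw <- dim(img)

  gt <- scene$masks
  n_pos <- length(gt$masks)
  boxes <- if (n_pos) propose(img, gt, cfg) else list()

  # background boxes for the class head
  negs <- list()
  if (cfg$neg_per_image > 0L) {
    gtb <- if (n_pos) lapply(gt$masks, mask_tight_box) else list()
    tries <- 0L
    while (length(negs) < cfg$neg_per_image && tries < 30L) {
      tries <- tries + 1L
      s <- stats::runif(1, 12, hw[1] / 2)
      x1 <- stats::runif(1, 0, hw[2] - s); y1 <- stats::runif(1, 0, hw[1] - s)
      b <- pc_box(x1, y1, x1 + s, y1 + s)
      if (!length(gtb) || max(vapply(gtb, function(g) box_iou(g, b), numeric(1))) < 0.2)
        negs[[length(negs) + 1L]] <- b
    }
  }

  loss_mask <- loss_point <- loss_box <- 0
  roi_list <- list(); roi_boxes <- c(boxes, negs)
  cls_labels <- c(rep(1, length(boxes)), rep(0, length(negs)))

  droi_extra <- vector("list", length(boxes))   # point-head coarse-feature grads
  mh_caches <- list()

  for (k in seq_along(boxes)) {
    b <- boxes[[k]]
    roi <- roi_align(P2, b, cfg$roi_out, cfg$sampling_ratio)
    roi_list[[k]] <- roi
    mh <- mask_head_forward(params$mask, roi)
    gt28 <- mask_in_box(gt$masks[[k]], b, cfg$mask_out)
    mb <- bce_with_logits(mh$logits, gt28 * 1)
    loss_mask <- loss_mask + mb$loss / n_pos
    dlog28 <- matrix(mb$grad, cfg$mask_out, cfg$mask_out) / n_pos
    mbw <- mask_head_backward(params$mask, mh$cache, dlog28)
    grads$mask <- tree_map2(`+`, grads$mask, mbw$grads)
    droi <- mbw$droi

    if (cfg$use_point_head) {
      sel <- select_points(mh$probs, cfg$beta_train, cfg$point_strategy_train)
      pts_img <- norm_to_image(sel, b)
      fine <- bilinear_sample(P2, pts_img)
      roi_g <- grid_feature(roi, stride = 1)
      pts_roi <- point_set(sel$x * cfg$roi_out, sel$y * cfg$roi_out, frame = "image")
      coarse <- bilinear_sample(roi_g, pts_roi)
      X <- cbind(fine, coarse)
      ph <- point_head_forward(params$point, X)
      labels <- label_at_points(gt$masks[[k]], pts_img)
      pb <- bce_with_logits(ph$logits, labels)
      loss_point <- loss_point + pb$loss / n_pos
      pbw <- point_head_backward(params$point, ph$cache, pb$grad / n_pos)
      grads$point <- tree_map2(`+`, grads$point, pbw$grads)
      dP2 <- dP2 + bilinear_scatter(dim(bf$P$P2), 4, pts_img,
                                    pbw$dX[, seq_len(F), drop = FALSE])
      droi <- droi + bilinear_scatter(dim(roi), 1, pts_roi,
                                      pbw$dX[, F + seq_len(F), drop = FALSE])
    }
    droi_extra[[k]] <- droi
  }

  # class + box heads over positive and negative RoIs
  loss_cls <- 0
  n_roi <- length(roi_boxes)
  if (n_roi) {
    for (k in seq_along(negs))
      roi_list[[length(boxes) + k]] <- roi_align(P2, negs[[k]], cfg$roi_out, cfg$sampling_ratio)
    pooled <- do.call(rbind, lapply(roi_list, function(r) apply(r, 3, mean)))
    f1 <- linear_fwd(pooled, params$head$fc1$w, params$head$fc1$b)
    r1 <- relu_fwd(f1$out)
    cl <- linear_fwd(r1$out, params$head$cls$w, params$head$cls$b)
    cb <- bce_with_logits(cl$out[, 1], cls_labels)
    loss_cls <- cb$loss
    dcls <- matrix(cb$grad, ncol = 1L)
    bcl <- linear_bwd(dcls, params$head$cls$w, cl$cache)
    grads$head$cls <- tree_map2(`+`, grads$head$cls, list(w = bcl$dW, b = bcl$db))
    dh <- bcl$dx

    if (n_pos) {
      bx <- linear_fwd(r1$out, params$head$box$w, params$head$box$b)
      targ <- t(vapply(seq_along(boxes), function(k)
        box_deltas(boxes[[k]], mask_tight_box(gt$masks[[k]])), numeric(4)))
      sl <- smooth_l1(bx$out[seq_along(boxes), , drop = FALSE], targ)
      loss_box <- sl$loss
      dbx <- matrix(0, n_roi, 4L)
      dbx[seq_along(boxes), ] <- matrix(sl$grad, length(boxes), 4L)
      bbx <- linear_bwd(dbx, params$head$box$w, bx$cache)
      grads$head$box <- tree_map2(`+`, grads$head$box, list(w = bbx$dW, b = bbx$db))
      dh <- dh + bbx$dx
    }
    dh <- relu_bwd(dh, r1$cache)
    bf1 <- linear_bwd(dh, params$head$fc1$w, f1$cache)
    grads$head$fc1 <- tree_map2(`+`, grads$head$fc1, list(w = bf1$dW, b = bf1$db))
    dpooled <- bf1$dx
    for (k in seq_len(n_roi)) {
      droi_k <- array(rep(dpooled[k, ], each = cfg$roi_out^2) / cfg$roi_out^2,
                      c(cfg$roi_out, cfg$roi_out, F))
      if (k <= length(boxes)) droi_k <- droi_k + droi_extra[[k]]
      dP2 <- dP2 + roi_align_backward(dim(bf$P$P2), 4, roi_boxes[[k]], droi_k,
                                      cfg$roi_out, cfg$sampling_ratio)
    }
  } else {
    for (k in seq_along(boxes))
      dP2 <- dP2 + roi_align_backward(dim(bf$P$P2), 4, boxes[[k]], droi_extra[[k]],
                                      cfg$roi_out, cfg$sampling_ratio)
  }

  bb <- backbone_backward(params, bf$cache, list(dP2, NULL, NULL, NULL))
  grads$backbone <- tree_map2(`+`, grads$backbone, bb$backbone)
  grads$fpn <- tree_map2(`+`, grads$fpn, bb$fpn)

  list(loss = total_loss(loss_mask, loss_point, loss_box, loss_cls), grads = grads)
}

#' Train the model on a dataset of scenes
#'
#' SGD with momentum at the configured learning rate; gradients are averaged
#' over \code{batch_size} scenes per step. When \code{config$augment} is TRUE
#' each scene is passed through a random flip/rotation/scale augmentation
#' every epoch. Per-epoch mean loss breakdowns are recorded; training aborts
#' with a diagnostic if the total loss exceeds 10x its initial value for
#' three consecutive epochs. Fixed \code{config$seed} makes the run (and the
#' loss curves) fully reproducible.
#'
#' @param dataset list of scenes, each with \code{image} and \code{masks}
#'   (>= 2 scenes; e.g. from \code{\link{synth_dataset}}).
#' @param config a \code{model_config}.
#' @param params optional initial parameters (resume); default fresh init.
#' @param verbose print per-epoch losses.
#' @return a checkpoint: list(params, momentum state, config, seed, history
#'   data.frame, version).
#' @export
train <- function(dataset, config = model_config(), params = NULL, verbose = FALSE) {
  if (length(dataset) < 2L) stop("train: need at least 2 scenes")
  set.seed(config$seed)
  if (is.null(params)) params <- init_model(config)
  state <- tree_zero_like(params)
  history <- data.frame(epoch = integer(0), total = numeric(0), mask = numeric(0),
                        point = numeric(0), box = numeric(0), cls = numeric(0))
  init_total <- NA_real_; n_diverged <- 0L
  n <- length(dataset)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- c(total = 0, mask = 0, point = 0, box = 0, cls = 0)
    nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      bgrads <- NULL; btot <- NULL
      for (i in idx) {
        sc <- dataset[[i]]
        if (config$augment) {
          au <- augment(sc$image, sc$masks)
          sc <- list(image = au$image, masks = au$masks)
        }
        if (length(sc$masks$masks) == 0L) next
        fb <- fb_scene(params, sc, config)
        bgrads <- if (is.null(bgrads)) fb$grads else tree_map2(`+`, bgrads, fb$grads)
        btot <- if (is.null(btot)) unlist(fb$loss) else btot + unlist(fb$loss)
      }
      if (is.null(bgrads)) next
      k <- length(idx)
      bgrads <- tree_map2(function(g, p) g / k, bgrads, params)
      upd <- sgd_step(params, bgrads, state, config$lr, config$momentum,
                      config$weight_decay)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + btot[c("total", "mask", "point", "box", "cls")] / k
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / max(nb, 1L)
    history <- rbind(history, data.frame(epoch = ep, total = ep_loss["total"],
                                         mask = ep_loss["mask"], point = ep_loss["point"],
                                         box = ep_loss["box"], cls = ep_loss["cls"]))
    if (verbose)
      message(sprintf("epoch %3d  total %.4f (mask %.4f point %.4f box %.4f cls %.4f)",
                      ep, ep_loss["total"], ep_loss["mask"], ep_loss["point"],
                      ep_loss["box"], ep_loss["cls"]))
    if (is.na(init_total)) init_total <- ep_loss["total"]
    n_diverged <- if (ep_loss["total"] > 10 * init_total) n_diverged + 1L else 0L
    if (n_diverged >= 3L)
      stop(sprintf("train: diverged (total loss %.3g > 10x initial %.3g for 3 epochs)",
                   ep_loss["total"], init_total))
  }
  rownames(history) <- NULL
  list(params = params, state = state, config = config, seed = config$seed,
       history = history, version = as.character(utils::packageVersion("pointcell")))
}
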