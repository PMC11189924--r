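# Overlapping-cytology challenge evaluation protocol: Dice-threshold instance
# matching, object false-negative rate, pixelwise TPRp/FPRp with the
# matched-pair exclusion rule, COCO-style mask AP, and stratified reports.

#' Dice similarity coefficient of two binary masks
#'
#' \code{DSC = 2 |A n B| / (|A| + |B|)}. Symmetric; 1 iff the nonempty masks
#' are identical; 0 iff they are disjoint. Two empty masks are defined as
#' DSC 0 with a warning (degenerate input; no area to agree on).
#'
#' @param a,b logical matrices of identical dimension.
#' @param ignore_mask optional logical matrix; TRUE pixels are excluded from
#'   all counts.
#' @return DSC in [0, 1].
#' @export
dsc <- function(a, b, ignore_mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("dsc: mask dimensions differ")
  if (!is.null(ignore_mask)) { a <- a & !ignore_mask; b <- b & !ignore_mask }
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) {
    warning("dsc: both masks empty; returning 0 by convention", call. = FALSE)
    return(0)
  }
  2 * sum(a & b) / (sa + sb)
}

mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Match predicted instances to ground-truth instances by DSC
#'
#' Greedy matching on the full gt x pred DSC matrix in descending DSC order;
#' each ground-truth cell and each prediction is used at most once and pairs
#' below the threshold are rejected. Deterministic: ties are broken by lower
#' gt index, then lower pred index. A ground-truth cell is "successfully
#' segmented" iff it ends up in a pair.
#'
#' @param gt,pred \code{instance_mask_set}s on the same canvas.
#' @param threshold DSC acceptance threshold in (0, 1); pairs with
#'   \code{DSC >= threshold} are accepted (use \code{strict = TRUE} for a
#'   strictly-greater reading).
#' @param strict logical; reject pairs with DSC exactly equal to the threshold.
#' @return list of class \code{match_result}: \code{pairs} (data.frame gt,
#'   pred, dsc), \code{unmatched_gt}, \code{unmatched_pred}, \code{threshold}.
#' @export
match_instances <- function(gt, pred, threshold = 0.7, strict = FALSE) {
  if (threshold <= 0 || threshold >= 1) stop("match_instances: threshold must be in (0, 1)")
  gm <- if (inherits(gt, "instance_mask_set")) gt$masks else gt
  pm <- if (inherits(pred, "instance_mask_set")) pred$masks else pred
  ig <- if (inherits(gt, "instance_mask_set")) gt$ignore_mask else NULL
  ng <- length(gm); np <- length(pm)
  pairs <- data.frame(gt = integer(0), pred = integer(0), dsc = numeric(0))
  if (ng && np) {
    d <- matrix(0, ng, np)
    for (i in seq_len(ng)) for (j in seq_len(np))
      d[i, j] <- dsc(gm[[i]], pm[[j]], ignore_mask = ig)
    cand <- data.frame(gt = rep(seq_len(ng), np),
                       pred = rep(seq_len(np), each = ng),
                       dsc = as.vector(d))
    keep <- if (strict) cand$dsc > threshold else cand$dsc >= threshold
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(-cand$dsc, cand$gt, cand$pred), , drop = FALSE]
    used_g <- logical(ng); used_p <- logical(np)
    for (r in seq_len(nrow(cand))) {
      i <- cand$gt[r]; j <- cand$pred[r]
      if (!used_g[i] && !used_p[j]) {
        used_g[i] <- TRUE; used_p[j] <- TRUE
        pairs <- rbind(pairs, cand[r, ])
      }
    }
  }
  structure(list(pairs = pairs,
                 unmatched_gt = setdiff(seq_len(ng), pairs$gt),
                 unmatched_pred = setdiff(seq_len(np), pairs$pred),
                 threshold = threshold),
            class = "match_result")
}

#' Pixelwise TPRp/FPRp for the matched pairs of a scene
#'
#' For each matched (gt_i, det_j) pair: TP = |gt_i n det_j|, FN = |gt_i \\
#' det_j|, FP = |det_j \\ gt_i|, TN = pixels of the full image outside
#' gt_i u det_j; then TPRp = TP/(TP+FN) and FPRp = FP/(FP+TN). The exclusion
#' rule applies: ground-truth cells with no accepted match contribute to no
#' pixel metric. Pixels of the ignore mask (annotation defects) are excluded
#' from all four counts.
#'
#' @param match a \code{match_result} computed at the report's threshold.
#' @param gt,pred the mask sets given to \code{\link{match_instances}}.
#' @return data.frame with one row per matched pair: gt, pred, dsc, tp, fn,
#'   fp, tn, tprp, fprp.
#' @export
pixel_metrics <- function(match, gt, pred) {
  gm <- if (inherits(gt, "instance_mask_set")) gt$masks else gt
  pm <- if (inherits(pred, "instance_mask_set")) pred$masks else pred
  ig <- if (inherits(gt, "instance_mask_set")) gt$ignore_mask else NULL
  out <- match$pairs
  n <- nrow(out)
  out$tp <- out$fn <- out$fp <- out$tn <- integer(n)
  out$tprp <- out$fprp <- numeric(n)
  for (r in seq_len(n)) {
    a <- gm[[out$gt[r]]]; b <- pm[[out$pred[r]]]
    if (!identical(dim(a), dim(b))) stop("pixel_metrics: mask shape mismatch")
    if (!is.null(ig)) { a <- a & !ig; b <- b & !ig }
    tp <- sum(a & b); fn <- sum(a & !b); fp <- sum(!a & b)
    tot <- length(a) - if (is.null(ig)) 0L else sum(ig)
    tn <- tot - tp - fn - fp
    out$tp[r] <- tp; out$fn[r] <- fn; out$fp[r] <- fp; out$tn[r] <- tn
    out$tprp[r] <- tp / (tp + fn)
    out$fprp[r] <- fp / (fp + tn)
  }
  out
}

#' Object-level false negative rate
#'
#' Fraction of ground-truth cells with no prediction reaching the DSC
#' threshold.
#'
#' @param match a \code{match_result}.
#' @param n_gt total number of ground-truth cells (>= 1).
#' @return FNRo in [0, 1].
#' @export
fnr_object <- function(match, n_gt) {
  if (n_gt < 1) stop("fnr_object: n_gt must be >= 1")
  (n_gt - nrow(match$pairs)) / n_gt
}

# COCO-style mask AP -----------------------------------------------------------

#' COCO-style mask average precision over a dataset
#'
#' Greedy score-ordered matching per IoU threshold (each prediction matches
#' the highest-IoU still-unmatched ground-truth mask of its scene when that
#' IoU reaches the threshold), 101-point interpolated precision, and
#' averaging over IoU thresholds 0.50:0.05:0.95 for AP (AP50 and AP75 are
#' the single-threshold values).
#'
#' @param gt_scenes list of \code{instance_mask_set}s.
#' @param pred_scenes list of lists of predictions, each a list with
#'   \code{mask} (logical matrix) and \code{score} (numeric).
#' @return list(ap, ap50, ap75).
#' @export
coco_ap <- function(gt_scenes, pred_scenes) {
  stopifnot(length(gt_scenes) == length(pred_scenes))
  preds <- data.frame(scene = integer(0), idx = integer(0), score = numeric(0))
  for (s in seq_along(pred_scenes)) {
    ps <- pred_scenes[[s]]
    if (length(ps)) {
      sc <- vapply(ps, function(p) {
        if (is.null(p$score)) stop("coco_ap: prediction without a score")
        p$score
      }, numeric(1))
      preds <- rbind(preds, data.frame(scene = s, idx = seq_along(ps), score = sc))
    }
  }
  n_gt <- sum(vapply(gt_scenes, function(g) length(g$masks), integer(1)))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  if (n_gt == 0L) return(list(ap = NA_real_, ap50 = NA_real_, ap75 = NA_real_))
  if (nrow(preds) == 0L) return(list(ap = 0, ap50 = 0, ap75 = 0))
  preds <- preds[order(-preds$score, preds$scene, preds$idx), , drop = FALSE]

  # IoU tables per scene, computed once
  iou_tab <- lapply(seq_along(gt_scenes), function(s) {
    g <- gt_scenes[[s]]$masks; p <- pred_scenes[[s]]
    if (!length(g) || !length(p)) return(matrix(0, length(g), length(p)))
    m <- matrix(0, length(g), length(p))
    for (i in seq_along(g)) for (j in seq_along(p))
      m[i, j] <- mask_iou(g[[i]], p[[j]]$mask)
    m
  })

  ap_at <- function(t) {
    used <- lapply(gt_scenes, function(g) logical(length(g$masks)))
    tp <- logical(nrow(preds))
    for (r in seq_len(nrow(preds))) {
      s <- preds$scene[r]; j <- preds$idx[r]
      ious <- iou_tab[[s]][, j]
      ious[used[[s]]] <- -1
      if (length(ious) && max(ious) >= t) {
        i <- which.max(ious)
        used[[s]][i] <- TRUE
        tp[r] <- TRUE
      }
    }
    cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
    recall <- cum_tp / n_gt
    precision <- cum_tp / (cum_tp + cum_fp)
    # 101-point interpolation with right-max precision envelope
    rs <- seq(0, 1, by = 0.01)
    penv <- rev(cummax(rev(precision)))
    mean(vapply(rs, function(rr) {
      k <- which(recall >= rr)
      if (length(k)) penv[k[1]] else 0
    }, numeric(1)))
  }

  aps <- vapply(thresholds, ap_at, numeric(1))
  list(ap = mean(aps), ap50 = aps[1], ap75 = aps[6])
}

# Dataset-level reports ---------------------------------------------------------

#' Evaluate predicted instance masks against ground truth over a dataset
#'
#' Applies DSC-threshold matching per scene, pools matched-pair metrics over
#' the whole dataset (mean +- sd over matched cells), reports the pooled
#' object false-negative rate (total unmatched gt / total gt) together with
#' its per-image spread, and the COCO AP family when predictions carry
#' scores.
#'
#' @param gt_scenes list of \code{instance_mask_set}s.
#' @param pred_scenes list whose elements are either \code{instance_mask_set}s
#'   or lists of predictions with \code{mask} and \code{score}.
#' @param threshold DSC threshold (default 0.7; the challenge's recommended value).
#' @param strict strictly-greater threshold reading (default FALSE: >=).
#' @param with_ap compute AP/AP50/AP75 (needs scores; default TRUE when
#'   scores are present).
#' @return list of class \code{eval_report}; see fields in the source.
#' @export
evaluate_masks <- function(gt_scenes, pred_scenes, threshold = 0.7,
                           strict = FALSE, with_ap = NULL) {
  stopifnot(length(gt_scenes) == length(pred_scenes))
  has_scores <- any(vapply(pred_scenes, function(p)
    !inherits(p, "instance_mask_set") && length(p) > 0L && !is.null(p[[1]]$score),
    logical(1)))
  if (is.null(with_ap)) with_ap <- has_scores

  per_cell <- NULL
  per_image <- data.frame(image = integer(0), n_gt = integer(0), n_pred = integer(0),
                          n_matched = integer(0), dsc = numeric(0), fnro = numeric(0))
  tot_gt <- 0L; tot_unmatched <- 0L
  for (s in seq_along(gt_scenes)) {
    gt <- gt_scenes[[s]]
    pm <- as_mask_list_safe(pred_scenes[[s]])
    mr <- match_instances(gt, pm, threshold, strict = strict)
    px <- pixel_metrics(mr, gt, pm)
    if (nrow(px)) { px$image <- s; per_cell <- rbind(per_cell, px) }
    ng <- length(gt$masks)
    tot_gt <- tot_gt + ng
    tot_unmatched <- tot_unmatched + length(mr$unmatched_gt)
    per_image <- rbind(per_image, data.frame(
      image = s, n_gt = ng, n_pred = length(pm$masks), n_matched = nrow(mr$pairs),
      dsc = if (nrow(px)) mean(px$dsc) else NA_real_,
      fnro = if (ng) length(mr$unmatched_gt) / ng else NA_real_))
  }
  agg <- function(v) c(if (length(v)) mean(v) else NA_real_,
                       if (length(v) > 1) stats::sd(v) else 0)
  ap <- if (with_ap) coco_ap(gt_scenes, pred_scenes) else list(ap = NA, ap50 = NA, ap75 = NA)
  structure(list(
    threshold = threshold,
    n_images = length(gt_scenes), n_gt_cells = tot_gt,
    n_matched = if (is.null(per_cell)) 0L else nrow(per_cell),
    dsc_mean = agg(per_cell$dsc)[1], dsc_sd = agg(per_cell$dsc)[2],
    tprp_mean = agg(per_cell$tprp)[1], tprp_sd = agg(per_cell$tprp)[2],
    fprp_mean = agg(per_cell$fprp)[1], fprp_sd = agg(per_cell$fprp)[2],
    fnro = if (tot_gt) tot_unmatched / tot_gt else NA_real_,
    fnro_image_mean = mean(per_image$fnro, na.rm = TRUE),
    fnro_image_sd = if (nrow(per_image) > 1) stats::sd(per_image$fnro, na.rm = TRUE) else 0,
    ap = ap$ap, ap50 = ap$ap50, ap75 = ap$ap75,
    per_cell = per_cell, per_image = per_image), class = "eval_report")
}

as_mask_list_safe <- function(p) {
  if (inherits(p, "instance_mask_set")) return(p)
  if (length(p) == 0L)
    return(structure(list(masks = list(), ignore_mask = NULL),
                     class = "instance_mask_set"))
  instance_mask_set(lapply(p, function(d) d$mask))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Instance-segmentation report (DSC threshold %.2f, %d images, %d gt cells)\n",
              x$threshold, x$n_images, x$n_gt_cells))
  cat(sprintf("  DSC  %.3f +- %.3f   TPRp %.3f +- %.3f\n",
              x$dsc_mean, x$dsc_sd, x$tprp_mean, x$tprp_sd))
  cat(sprintf("  FPRp %.4f +- %.4f  FNRo %.3f\n", x$fprp_mean, x$fprp_sd, x$fnro))
  if (!is.na(x$ap)) cat(sprintf("  AP %.3f  AP50 %.3f  AP75 %.3f\n", x$ap, x$ap50, x$ap75))
  invisible(x)
}

#' Metrics stratified by cell count and overlap rate
#'
#' Bins scenes by ground-truth cell count and by achieved mean overlap rate
#' (bins of width 0.1 over [0, 0.5]) and evaluates each nonempty stratum
#' separately; empty strata are absent from the output. Scenes lacking
#' metadata land in an "unknown" stratum with a message.
#'
#' @param gt_scenes list of \code{instance_mask_set}s.
#' @param pred_scenes predictions, as in \code{\link{evaluate_masks}}.
#' @param meta list of per-scene metadata (with n_cells and achieved_overlap),
#'   e.g. the \code{meta} elements of \code{\link{synth_scene}} output.
#' @param threshold DSC threshold.
#' @return list of class \code{strat_report}: \code{global} (the pooled
#'   \code{eval_report}), \code{strata} (data.frame with one row per
#'   nonempty stratum).
#' @export
stratified_report <- function(gt_scenes, pred_scenes, meta, threshold = 0.7) {
  stopifnot(length(gt_scenes) == length(meta))
  key <- vapply(seq_along(meta), function(s) {
    m <- meta[[s]]
    if (is.null(m$n_cells) || is.null(m$achieved_overlap)) {
      message("stratified_report: scene ", s, " lacks metadata; stratum 'unknown'")
      return("unknown")
    }
    ob <- min(floor(m$achieved_overlap / 0.1), 4)
    sprintf("cells=%d|overlap=[%.1f,%.1f)", m$n_cells, ob * 0.1, ob * 0.1 + 0.1)
  }, character(1))
  strata <- NULL
  for (k in unique(key)) {
    idx <- which(key == k)
    r <- evaluate_masks(gt_scenes[idx], pred_scenes[idx], threshold, with_ap = FALSE)
    strata <- rbind(strata, data.frame(
      stratum = k,
      n_cells = if (k == "unknown") NA else meta[[idx[1]]]$n_cells,
      overlap_bin = if (k == "unknown") NA else min(floor(meta[[idx[1]]]$achieved_overlap / 0.1), 4) * 0.1,
      n_images = length(idx), n_gt = r$n_gt_cells,
      dsc = r$dsc_mean, dsc_sd = r$dsc_sd, tprp = r$tprp_mean,
      fprp = r$fprp_mean, fnro = r$fnro))
  }
  structure(list(global = evaluate_masks(gt_scenes, pred_scenes, threshold),
                 strata = strata, threshold = threshold),
            class = "strat_report")
}

#' Heat-map of a stratified report
#'
#' Renders mean DSC per (cell count, overlap bin) stratum as an image plot.
#'
#' @param report a \code{strat_report}.
#' @param metric column of the strata table to plot (default "dsc").
#' @param file optional PNG path; when given the plot is written there.
#' @return the plotted matrix, invisibly.
#' @export
plot_strata <- function(report, metric = "dsc", file = NULL) {
  st <- report$strata
  st <- st[st$stratum != "unknown", , drop = FALSE]
  cells <- sort(unique(st$n_cells)); bins <- sort(unique(st$overlap_bin))
  z <- matrix(NA_real_, length(cells), length(bins),
              dimnames = list(cells, sprintf("[%.1f,%.1f)", bins, bins + 0.1)))
  for (r in seq_len(nrow(st)))
    z[as.character(st$n_cells[r]), sprintf("[%.1f,%.1f)", st$overlap_bin[r], st$overlap_bin[r] + 0.1)] <- st[[metric]][r]
  draw <- function() {
    graphics::image(seq_along(cells), seq_along(bins), z, axes = FALSE,
                    xlab = "cells per image", ylab = "overlap-rate bin",
                    main = paste("mean", toupper(metric), "per stratum"),
                    col = grDevices::hcl.colors(32, "viridis"))
    graphics::axis(1, at = seq_along(cells), labels = cells)
    graphics::axis(2, at = seq_along(bins), labels = colnames(z), las = 2)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    draw()
  } else draw()
  invisible(z)
}
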