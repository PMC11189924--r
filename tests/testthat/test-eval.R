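# Challenge evaluation protocol: DSC, instance matching, pixel metrics with
# the exclusion rule, FNRo, COCO AP, stratified reports.

sq <- function(hw, r, c) { m <- matrix(FALSE, hw[1], hw[2]); m[r, c] <- TRUE; m }

test_that("dsc matches its set definition on constructed masks", {
  a <- sq(c(8, 8), 2:5, 2:5)
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, sq(c(8, 8), 7:8, 7:8)), 0)
  # |A| = 4, |B| = 4, |A n B| = 2 -> 0.5
  a2 <- sq(c(6, 8), 2, 2:5); b2 <- sq(c(6, 8), 2, 4:7)
  expect_equal(sum(a2), 4); expect_equal(sum(a2 & b2), 2)
  expect_equal(dsc(a2, b2), 0.5)
  expect_warning(d0 <- dsc(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), "empty")
  expect_equal(d0, 0)
  expect_error(dsc(a, matrix(TRUE, 3, 3)), "differ")
})

test_that("greedy DSC matching pairs each side at most once and rejects sub-threshold pairs", {
  gt <- instance_mask_set(list(sq(c(12, 12), 1:4, 1:4), sq(c(12, 12), 8:11, 8:11)))

  # pred = gt -> all matched at DSC 1
  mr <- match_instances(gt, gt, 0.7)
  expect_equal(nrow(mr$pairs), 2)
  expect_equal(mr$pairs$dsc, c(1, 1))
  expect_length(mr$unmatched_gt, 0)

  # one prediction straddling two gt cells: only one gt can be matched
  straddle <- sq(c(12, 12), 1:4, 1:4) | sq(c(12, 12), 8:11, 8:11)
  straddle <- instance_mask_set(list(straddle))
  mr2 <- match_instances(gt, straddle, 0.5)
  expect_equal(nrow(mr2$pairs), 1)
  expect_length(mr2$unmatched_gt, 1)
  # oracle agreement on the same construction
  or <- oracle_match(gt$masks, straddle$masks, 0.5)
  expect_equal(mr2$pairs$gt, or$g)
  expect_equal(mr2$pairs$dsc, or$d)

  # empty prediction set -> everything unmatched
  mr3 <- match_instances(gt, list(), 0.7)
  expect_equal(mr3$unmatched_gt, 1:2)
  expect_equal(fnr_object(mr3, 2), 1)

  expect_error(match_instances(gt, gt, 1.2), "threshold")
})

test_that("raising the threshold never decreases FNRo nor increases matches", {
  set.seed(5)
  for (rep in 1:20) {
    gt <- rand_mask_set(c(24, 24), sample(1:4, 1))
    pred <- rand_mask_set(c(24, 24), sample(1:4, 1))
    prev_pairs <- Inf
    for (thr in c(0.3, 0.5, 0.7, 0.9)) {
      mr <- match_instances(gt, pred, thr)
      expect_lte(nrow(mr$pairs), prev_pairs)
      prev_pairs <- nrow(mr$pairs)
    }
  }
})

test_that("pixel metrics follow the pairwise TP/FN/FP/TN definition with full-image TN", {
  # 10x10 image, gt 4x4 square, pred shifted right by 1
  gt <- instance_mask_set(list(sq(c(10, 10), 3:6, 3:6)))
  pred <- instance_mask_set(list(sq(c(10, 10), 3:6, 4:7)))
  mr <- match_instances(gt, pred, 0.7)   # DSC = 24/32 = 0.75 >= 0.7
  expect_equal(mr$pairs$dsc, 0.75)
  px <- pixel_metrics(mr, gt, pred)
  expect_equal(px$tp, 12); expect_equal(px$fn, 4); expect_equal(px$fp, 4)
  expect_equal(px$tn, 80)
  expect_equal(px$tprp, 0.75)
  expect_equal(px$fprp, 4 / 84)

  # perfect pair
  mr0 <- match_instances(gt, gt, 0.7)
  px0 <- pixel_metrics(mr0, gt, gt)
  expect_equal(px0$tprp, 1); expect_equal(px0$fprp, 0)

  # exclusion rule: an unmatched extra gt cell changes no pooled pixel metric
  gt2 <- instance_mask_set(list(gt$masks[[1]], sq(c(10, 10), 9:10, 9:10)))
  mr2 <- match_instances(gt2, pred, 0.7)
  px2 <- pixel_metrics(mr2, gt2, pred)
  expect_equal(nrow(px2), 1)
  expect_equal(px2$tprp, px$tprp)
  expect_equal(px2$fprp, px$fprp)
  # but FNRo sees it
  expect_equal(fnr_object(mr2, 2), 0.5)
})

test_that("ignore-mask pixels are excluded from all pixel counts", {
  gt <- sq(c(10, 10), 3:6, 3:6)
  pred <- sq(c(10, 10), 3:6, 4:7)
  ig <- sq(c(10, 10), 3:6, 7)        # ignore the rightmost predicted column
  gts <- instance_mask_set(list(gt), ignore_mask = ig)
  prs <- instance_mask_set(list(pred))
  mr <- match_instances(gts, prs, 0.7)
  px <- pixel_metrics(mr, gts, prs)
  expect_equal(px$fp, 0)             # the only FP pixels were ignored
  expect_equal(px$tp + px$fn + px$fp + px$tn, 100 - sum(ig))
})

test_that("coco_ap reproduces hand-walked PR curves and the self-evaluation identity", {
  gt <- list(instance_mask_set(list(sq(c(10, 10), 1:4, 1:4), sq(c(10, 10), 6:9, 6:9))))

  # perfect predictions, score 1 -> AP = AP50 = AP75 = 1
  pred_perfect <- list(lapply(gt[[1]]$masks, function(m) list(mask = m, score = 1)))
  ap <- coco_ap(gt, pred_perfect)
  expect_equal(ap$ap, 1); expect_equal(ap$ap50, 1); expect_equal(ap$ap75, 1)

  # no predictions -> 0
  expect_equal(coco_ap(gt, list(list()))$ap, 0)

  # one of two cells detected perfectly: interpolated AP50 = 51/101
  pred_half <- list(list(list(mask = gt[[1]]$masks[[1]], score = 1)))
  ap2 <- coco_ap(gt, pred_half)
  expect_equal(ap2$ap50, 51 / 101, tolerance = 1e-12)
  expect_equal(ap2$ap50, oracle_coco_ap(gt, pred_half)$ap50, tolerance = 1e-12)

  expect_error(coco_ap(gt, list(list(list(mask = gt[[1]]$masks[[1]])))), "score")
})

test_that("metrics are invariant under a joint flip of gt and pred", {
  set.seed(6)
  gt <- rand_mask_set(c(20, 20), 3)
  pred <- rand_mask_set(c(20, 20), 3)
  fl <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  gt_f <- instance_mask_set(lapply(gt$masks, fl))
  pred_f <- instance_mask_set(lapply(pred$masks, fl))
  r1 <- evaluate_masks(list(gt), list(pred), 0.5)
  r2 <- evaluate_masks(list(gt_f), list(pred_f), 0.5)
  for (f in c("dsc_mean", "tprp_mean", "fprp_mean", "fnro", "n_matched"))
    expect_equal(r1[[f]], r2[[f]])
})

test_that("stratified reports partition scenes and agree with per-stratum recomputation", {
  set.seed(8)
  mk <- function() {
    g <- rand_mask_set(c(24, 24), 2)
    list(gt = g, pred = g)
  }
  scenes <- replicate(4, mk(), simplify = FALSE)
  gts <- lapply(scenes, `[[`, "gt"); preds <- lapply(scenes, `[[`, "pred")

  # all scenes in one stratum -> stratum metrics equal global metrics
  meta1 <- replicate(4, list(n_cells = 2L, achieved_overlap = 0.05), simplify = FALSE)
  sr <- stratified_report(gts, preds, meta1, 0.7)
  expect_equal(nrow(sr$strata), 1)
  expect_equal(sr$strata$dsc[1], sr$global$dsc_mean)

  # two strata: each equals its own recomputation; empty strata are absent
  meta2 <- meta1; meta2[[3]]$achieved_overlap <- 0.45; meta2[[4]]$achieved_overlap <- 0.45
  sr2 <- stratified_report(gts, preds, meta2, 0.7)
  expect_equal(nrow(sr2$strata), 2)
  lo <- evaluate_masks(gts[1:2], preds[1:2], 0.7, with_ap = FALSE)
  expect_equal(sr2$strata$dsc[sr2$strata$overlap_bin == 0], lo$dsc_mean)
  expect_false(any(sr2$strata$overlap_bin == 0.2))
})
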