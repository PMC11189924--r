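# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; heavier fixtures (trained checkpoints, datasets) are
# memoized so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# random blob mask: a filled disc with random center/radius on an H x W canvas
rand_blob <- function(hw, rmin = 2, rmax = max(3, min(hw) / 3)) {
  H <- hw[1]; W <- hw[2]
  repeat {
    cx <- stats::runif(1, 1, W - 1); cy <- stats::runif(1, 1, H - 1)
    r <- stats::runif(1, rmin, rmax)
    xs <- (seq_len(W) - 0.5); ys <- (seq_len(H) - 0.5)
    m <- outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
    if (any(m)) return(m)
  }
}

rand_mask_set <- function(hw, n_masks) {
  instance_mask_set(lapply(seq_len(n_masks), function(i) rand_blob(hw)))
}

# --- exhaustive pixel-counting oracles (independent of the package's code) ---

oracle_dsc <- function(a, b) {
  inter <- 0L; sa <- 0L; sb <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j]) sa <- sa + 1L
    if (b[i, j]) sb <- sb + 1L
    if (a[i, j] && b[i, j]) inter <- inter + 1L
  }
  if (sa + sb == 0L) return(0)
  2 * inter / (sa + sb)
}

oracle_pixel_counts <- function(gt, pred) {
  tp <- sum(gt & pred); fn <- sum(gt & !pred)
  fp <- sum(!gt & pred); tn <- sum(!gt & !pred)
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       tprp = tp / (tp + fn), fprp = fp / (fp + tn))
}

# greedy descending-DSC matching, written as a plain full-sort loop
oracle_match <- function(gt_masks, pred_masks, threshold) {
  ng <- length(gt_masks); np <- length(pred_masks)
  cand <- NULL
  for (i in seq_len(ng)) for (j in seq_len(np)) {
    d <- oracle_dsc(gt_masks[[i]], pred_masks[[j]])
    if (d >= threshold) cand <- rbind(cand, data.frame(g = i, p = j, d = d))
  }
  pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(-cand$d, cand$g, cand$p), , drop = FALSE]
    ug <- logical(ng); up <- logical(np)
    for (r in seq_len(nrow(cand))) {
      if (!ug[cand$g[r]] && !up[cand$p[r]]) {
        ug[cand$g[r]] <- TRUE; up[cand$p[r]] <- TRUE
        pairs <- rbind(pairs, cand[r, ])
      }
    }
  }
  pairs
}

# independent COCO-style AP reference: same metric definition, written as a
# separate direct implementation (explicit per-threshold loops, precision
# envelope computed point-by-point without cummax)
oracle_coco_ap <- function(gt_scenes, pred_scenes) {
  n_gt <- sum(vapply(gt_scenes, function(g) length(g$masks), integer(1)))
  allp <- NULL
  for (s in seq_along(pred_scenes))
    for (j in seq_along(pred_scenes[[s]]))
      allp <- rbind(allp, data.frame(s = s, j = j, score = pred_scenes[[s]][[j]]$score))
  if (is.null(allp)) return(list(ap = 0, ap50 = 0, ap75 = 0))
  allp <- allp[order(-allp$score, allp$s, allp$j), , drop = FALSE]
  one_t <- function(t) {
    taken <- lapply(gt_scenes, function(g) logical(length(g$masks)))
    flags <- logical(nrow(allp))
    for (r in seq_len(nrow(allp))) {
      s <- allp$s[r]; j <- allp$j[r]
      best <- 0; bi <- 0L
      for (i in seq_along(gt_scenes[[s]]$masks)) {
        if (taken[[s]][i]) next
        a <- gt_scenes[[s]]$masks[[i]]; b <- pred_scenes[[s]][[j]]$mask
        u <- sum(a | b)
        iou <- if (u == 0) 0 else sum(a & b) / u
        if (iou > best) { best <- iou; bi <- i }
      }
      if (best >= t) { taken[[s]][bi] <- TRUE; flags[r] <- TRUE }
    }
    prec <- cumsum(flags) / seq_along(flags)
    rec <- cumsum(flags) / n_gt
    # interpolated precision at recall rr = max precision over positions
    # whose recall reaches rr
    ap <- 0
    for (rr in seq(0, 1, by = 0.01)) {
      idx <- which(rec >= rr)
      ap <- ap + if (length(idx)) max(prec[idx]) else 0
    }
    ap / 101
  }
  ts <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(ts, one_t, numeric(1))
  list(ap = mean(aps), ap50 = aps[1], ap75 = aps[6])
}

# --- shared generated datasets and trained models ---

small_synth_config <- function(seed = 11, size = 128L, cells = c(2L, 6L),
                               overlap = c(0, 0.3)) {
  synth_config(image_size = size, n_cells_range = cells,
               target_overlap_rate = overlap, cell = cell_params(size), seed = seed)
}

# a very small trained checkpoint on 64x64 scenes, for wiring-level tests
tiny_checkpoint <- function() memo("tiny_ckpt", function() {
  cfg_s <- small_synth_config(seed = 31, size = 64L, cells = c(1L, 3L),
                              overlap = c(0, 0.2))
  ds <- suppressWarnings(synth_dataset(6, cfg_s))
  cfg <- model_config(epochs = 4L, seed = 5L, augment = FALSE)
  list(ckpt = suppressWarnings(train(ds, cfg)), data = ds, synth_config = cfg_s)
})

# ablation fixture: a compact train/eval split plus the full alpha x beta x
# point-head grid trained from a shared seed
ablation_fixture <- function() memo("ablation", function() {
  cfg_s <- small_synth_config(seed = 21, cells = c(2L, 5L), overlap = c(0, 0.25))
  train_set <- suppressWarnings(synth_dataset(16, cfg_s))
  eval_set <- suppressWarnings(synth_dataset(12, cfg_s, start_index = 2001L))
  cfg <- model_config(epochs = 12L, seed = 7L, augment = TRUE)
  tab <- suppressWarnings(ablate(train_set, eval_set, cfg,
                                 alphas = c(2L, 3L, 4L), betas = c(196L, 784L),
                                 include_no_point_head = TRUE))
  list(table = tab, train_set = train_set, eval_set = eval_set)
})

# the end-to-end fixture: train on 32 held-in 128x128 scenes, evaluate on 10
# held-out scenes (also reused for the stratified trend check)
e2e_fixture <- function() memo("e2e", function() {
  cfg_s <- small_synth_config(seed = 11)
  train_set <- suppressWarnings(synth_dataset(32, cfg_s))
  eval_set <- suppressWarnings(synth_dataset(10, cfg_s, start_index = 1001L))
  cfg <- model_config(epochs = 25L, seed = 7L, augment = TRUE)
  ckpt <- suppressWarnings(train(train_set, cfg))
  list(ckpt = ckpt, train_set = train_set, eval_set = eval_set, synth_config = cfg_s)
})
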