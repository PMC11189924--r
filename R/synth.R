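# Synthetic overlapping cervical-cell scenes with dense per-instance ground
# truth. Cells are star-shaped (radially perturbed ellipses) so rasterization
# under the pixel-center convention is exact; overlapping cytoplasm is
# rendered by multiplicative translucent blending, which darkens clump
# interiors the way extended-depth-of-field cytology images do.

#' Collection of possibly-overlapping per-instance binary masks
#'
#' Masks are logical H x W matrices sharing one canvas; they may mutually
#' overlap (the union is not a partition), which is exactly why a single
#' label image cannot represent this ground truth. An optional
#' \code{ignore_mask} marks unlabeled/defect pixels excluded from pixel
#' counts at evaluation time.
#'
#' @param masks list of logical matrices, all the same dimension, each with
#'   at least one TRUE pixel.
#' @param ignore_mask optional logical matrix of the same dimension.
#' @return an object of class \code{instance_mask_set}.
#' @export
instance_mask_set <- function(masks, ignore_mask = NULL) {
  stopifnot(is.list(masks))
  if (length(masks)) {
    d <- dim(masks[[1]])
    for (k in seq_along(masks)) {
      m <- masks[[k]]
      if (!is.logical(m)) { m <- m > 0.5; masks[[k]] <- m }
      if (!identical(dim(m), d))
        stop("instance_mask_set: mask ", k, " has mismatched dimensions")
      if (!any(m)) stop("instance_mask_set: mask ", k, " is empty")
    }
  }
  if (!is.null(ignore_mask)) {
    if (!is.logical(ignore_mask)) ignore_mask <- ignore_mask > 0.5
    if (length(masks) && !identical(dim(ignore_mask), dim(masks[[1]])))
      stop("instance_mask_set: ignore_mask dimension mismatch")
  }
  structure(list(masks = masks, ignore_mask = ignore_mask),
            class = "instance_mask_set")
}

#' @export
print.instance_mask_set <- function(x, ...) {
  d <- if (length(x$masks)) dim(x$masks[[1]]) else c(0L, 0L)
  cat(sprintf("<instance_mask_set: %d masks on a %dx%d canvas%s>\n",
              length(x$masks), d[1], d[2],
              if (is.null(x$ignore_mask)) "" else ", with ignore mask"))
  invisible(x)
}

#' Shape/intensity parameter ranges for synthetic cells
#'
#' Defaults scale with the canvas so a 512 px scene holds ISBI2014-like cell
#' sizes (cytoplasm major semi-axis roughly 12--22% of the image side).
#' Intensities are transmittances in (0, 1]: the rendered image multiplies
#' the background by each covering cell's transmittance, so stacked cells
#' darken.
#'
#' @param image_size canvas side in pixels the ranges should suit.
#' @return named list of ranges consumed by \code{\link{sample_cell}}.
#' @export
cell_params <- function(image_size = 512) {
  s <- image_size
  list(radius_range = c(0.12, 0.22) * s,
       aspect_range = c(0.55, 0.95),
       perturb_amp_range = c(0.02, 0.08),
       perturb_harmonics = 2:5,
       nucleus_scale_range = c(0.22, 0.38),
       nucleus_offset_frac = 0.35,
       cyto_transmittance_range = c(0.62, 0.85),
       nucleus_transmittance_range = c(0.35, 0.6),
       texture_amp_range = c(0.01, 0.04))
}

check_range <- function(r, name) {
  if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
    stop("sample_cell: invalid range for ", name, " (need min <= max)")
}

# Radius of the perturbed ellipse at polar angle theta (about the cell center).
cell_radius <- function(tpl, theta) {
  t2 <- theta - tpl$phi
  base <- tpl$a * tpl$b / sqrt((tpl$b * cos(t2))^2 + (tpl$a * sin(t2))^2)
  pert <- rep(1, length(theta))
  for (h in seq_along(tpl$perturb$k))
    pert <- pert + tpl$perturb$amp[h] * cos(tpl$perturb$k[h] * theta + tpl$perturb$phase[h])
  base * pert
}

#' Draw one random cell template
#'
#' A template is a cytoplasm contour (ellipse with a smooth low-order radial
#' perturbation, hence simple and star-shaped), a smaller nucleus contour
#' strictly inside it, and intensity parameters. Uses the R global random
#' stream; seed with \code{set.seed} for reproducibility.
#'
#' @param params ranges from \code{\link{cell_params}}.
#' @return an object of class \code{cell_template}.
#' @export
sample_cell <- function(params = cell_params()) {
  for (nm in c("radius_range", "aspect_range", "perturb_amp_range",
               "nucleus_scale_range", "cyto_transmittance_range",
               "nucleus_transmittance_range", "texture_amp_range"))
    check_range(params[[nm]], nm)
  if (any(params$radius_range <= 0)) stop("sample_cell: radii must be positive")
  a <- stats::runif(1, params$radius_range[1], params$radius_range[2])
  b <- a * stats::runif(1, params$aspect_range[1], params$aspect_range[2])
  phi <- stats::runif(1, 0, pi)
  nk <- length(params$perturb_harmonics)
  amp_tot <- stats::runif(1, params$perturb_amp_range[1], params$perturb_amp_range[2])
  w <- stats::runif(nk); w <- if (sum(w) > 0) w / sum(w) else rep(1 / nk, nk)
  perturb <- list(k = params$perturb_harmonics, amp = amp_tot * w,
                  phase = stats::runif(nk, 0, 2 * pi))
  nuc_scale <- stats::runif(1, params$nucleus_scale_range[1], params$nucleus_scale_range[2])
  nuc_phi <- stats::runif(1, 0, pi)
  # offset kept small enough that the nucleus stays strictly inside the
  # (worst-case shrunken) cytoplasm radius
  min_cyto <- b * (1 - amp_tot)
  max_off <- max(0, params$nucleus_offset_frac * (min_cyto - nuc_scale * a))
  off_r <- stats::runif(1, 0, max_off)
  off_t <- stats::runif(1, 0, 2 * pi)
  tpl <- list(a = a, b = b, phi = phi, perturb = perturb,
              nucleus = list(a = nuc_scale * a, b = nuc_scale * b, phi = nuc_phi,
                             dx = off_r * cos(off_t), dy = off_r * sin(off_t)),
              intensity = list(
                cyto_t = stats::runif(1, params$cyto_transmittance_range[1],
                                      params$cyto_transmittance_range[2]),
                nucleus_t = stats::runif(1, params$nucleus_transmittance_range[1],
                                         params$nucleus_transmittance_range[2]),
                texture_amp = stats::runif(1, params$texture_amp_range[1],
                                           params$texture_amp_range[2])))
  class(tpl) <- "cell_template"
  tpl
}

#' Closed contour of a template's cytoplasm (or nucleus) outline
#' @param tpl a \code{cell_template}.
#' @param n number of vertices.
#' @param what \code{"cytoplasm"} or \code{"nucleus"}.
#' @return two-column matrix of (x, y) vertices about the cell center.
#' @export
cell_outline <- function(tpl, n = 360, what = c("cytoplasm", "nucleus")) {
  what <- match.arg(what)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  if (what == "cytoplasm") {
    r <- cell_radius(tpl, th)
    cbind(x = r * cos(th), y = r * sin(th))
  } else {
    nu <- tpl$nucleus
    t2 <- th - nu$phi
    r <- nu$a * nu$b / sqrt((nu$b * cos(t2))^2 + (nu$a * sin(t2))^2)
    cbind(x = nu$dx + r * cos(th), y = nu$dy + r * sin(th))
  }
}

# Rasterize the cytoplasm (and optionally nucleus) of a template placed at
# `center` on an image_size canvas. Pixel-center convention: pixel (r, c)
# belongs to the mask iff its center (c - 0.5, r - 0.5) lies inside the
# star-shaped contour.
rasterize_cell <- function(tpl, center, image_hw, nucleus = FALSE) {
  H <- image_hw[1]; W <- image_hw[2]
  cx <- rep((seq_len(W) - 0.5) - center[1], each = H)
  cy <- rep((seq_len(H) - 0.5) - center[2], times = W)
  theta <- atan2(cy, cx)
  rho <- sqrt(cx^2 + cy^2)
  cyto <- matrix(rho <= cell_radius(tpl, theta), H, W)
  if (!nucleus) return(cyto)
  nu <- tpl$nucleus
  dx <- cx - nu$dx; dy <- cy - nu$dy
  t2 <- atan2(dy, dx)
  rn <- nu$a * nu$b / sqrt((nu$b * cos(t2 - nu$phi))^2 + (nu$a * sin(t2 - nu$phi))^2)
  list(cyto = cyto, nucleus = matrix(sqrt(dx^2 + dy^2) <= rn, H, W) & cyto)
}

#' Configuration of the synthetic-scene generator
#'
#' Defaults mirror the ISBI2014 synthetic set: 512 x 512 canvases holding
#' 2--10 cells with mean per-cell overlap rates between 0 and 0.5.
#'
#' @param image_size canvas side in pixels (>= 64).
#' @param n_cells_range integer interval for the number of cells.
#' @param target_overlap_rate desired mean per-cell overlap rate in [0, 0.5];
#'   a length-2 vector is a range from which each scene draws its own target.
#' @param background_level background gray level in [0, 1] (bright field).
#' @param brightness_jitter half-width of the uniform per-image brightness jitter.
#' @param blend_opacity exponent in (0, 1] applied to cell transmittances
#'   before multiplicative blending (1 = full opacity of the translucent model).
#' @param noise_sd standard deviation of additive pixel noise.
#' @param seed integer RNG seed; identical (config, seed) gives identical scenes.
#' @param cell list of shape/intensity ranges; default \code{cell_params(image_size)}.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(image_size = 512, n_cells_range = c(2L, 10L),
                         target_overlap_rate = 0.2, background_level = 0.88,
                         brightness_jitter = 0.04, blend_opacity = 1,
                         noise_sd = 0.01, seed = 1L, cell = NULL) {
  if (image_size < 64) stop("synth_config: image_size must be >= 64")
  if (any(n_cells_range < 1) || n_cells_range[1] > n_cells_range[2])
    stop("synth_config: invalid n_cells_range")
  if (any(target_overlap_rate < 0) || any(target_overlap_rate > 0.5) ||
      !length(target_overlap_rate) %in% 1:2)
    stop("synth_config: target_overlap_rate must be in [0, 0.5] (scalar or range)")
  if (blend_opacity <= 0 || blend_opacity > 1)
    stop("synth_config: blend_opacity must be in (0, 1]")
  structure(list(image_size = as.integer(image_size),
                 n_cells_range = as.integer(n_cells_range),
                 target_overlap_rate = target_overlap_rate,
                 background_level = background_level,
                 brightness_jitter = brightness_jitter,
                 blend_opacity = blend_opacity,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 cell = if (is.null(cell)) cell_params(image_size) else cell),
            class = "synth_config")
}

#' Mean per-cell overlap rate of a mask set
#'
#' For each cell: the fraction of its pixels shared with at least one other
#' cell; the scene's overlap rate is the mean over cells. Disjoint masks give
#' 0; two identical masks give 1.
#'
#' @param masks an \code{instance_mask_set} (or list of logical matrices).
#' @return a number in [0, 1].
#' @export
measure_overlap_rate <- function(masks) {
  ml <- if (inherits(masks, "instance_mask_set")) masks$masks else masks
  if (length(ml) == 0L) stop("measure_overlap_rate: empty mask set")
  if (length(ml) == 1L) return(0)
  cover <- Reduce(`+`, lapply(ml, function(m) m * 1L))
  mean(vapply(ml, function(m) sum(m & cover >= 2L) / sum(m), numeric(1)))
}

#' Compose an image and ground-truth masks from placed cell templates
#'
#' Places cells on the canvas aiming for the configured mean overlap rate
#' (best-effort candidate search with bounded retries: if the achieved rate
#' misses the target by more than 0.1 a warning is raised and the achieved
#' value is still reported), then renders by multiplicative translucent
#' blending: the image is \code{background * prod(transmittance^opacity)}
#' over covering cells, darkest where cells stack, plus cell texture and
#' pixel noise. Uses the R global random stream.
#'
#' @param cells list of \code{cell_template}s (>= 1).
#' @param config a \code{synth_config}.
#' @return list with \code{image} (H x W matrix in [0, 1]), \code{masks}
#'   (an \code{instance_mask_set}), and \code{meta} (n_cells, achieved
#'   overlap rate, per-cell boxes).
#' @export
compose_image <- function(cells, config = synth_config()) {
  stopifnot(length(cells) >= 1L)
  n <- length(cells)
  sz <- config$image_size
  hw <- c(sz, sz)
  target <- config$target_overlap_rate
  masks <- vector("list", n)
  nuclei <- vector("list", n)
  centers <- vector("list", n)
  cover <- matrix(0L, sz, sz)
  rmax <- function(tpl) tpl$a * (1 + sum(tpl$perturb$amp))

  for (k in seq_len(n)) {
    tpl <- cells[[k]]
    m <- min(rmax(tpl), sz / 2 - 1)
    lo <- m * 0.8; hi <- sz - m * 0.8   # keep most of the cell on canvas
    n_try <- if (k == 1L) 1L else 40L
    best <- NULL; best_err <- Inf
    for (t in seq_len(n_try)) {
      if (k == 1L || target == 0) {
        ctr <- stats::runif(2, lo, hi)
      } else {
        # bias candidates toward an existing cell so overlap is reachable
        anchor <- centers[[sample.int(k - 1L, 1L)]]
        dist <- stats::runif(1, 0.3, 1.6) * m
        ang <- stats::runif(1, 0, 2 * pi)
        ctr <- pmin(pmax(anchor + dist * c(cos(ang), sin(ang)), lo), hi)
      }
      cand <- rasterize_cell(tpl, ctr, hw)
      area <- sum(cand)
      if (area == 0L) next
      frac <- sum(cand & cover > 0L) / area
      err <- abs(frac - target)
      if (err < best_err) { best <- list(ctr = ctr, mask = cand); best_err <- err }
      if (err <= 0.03) break
    }
    if (is.null(best)) stop("compose_image: failed to rasterize a cell")
    centers[[k]] <- best$ctr
    rc <- rasterize_cell(tpl, best$ctr, hw, nucleus = TRUE)
    masks[[k]] <- rc$cyto
    nuclei[[k]] <- rc$nucleus
    cover <- cover + rc$cyto
  }

  achieved <- measure_overlap_rate(masks)
  if (abs(achieved - target) > 0.1)
    warning(sprintf(paste0("compose_image: achieved overlap rate %.3f misses ",
                           "target %.3f by more than 0.1 (best-effort placement)"),
                    achieved, target), call. = FALSE)

  bg <- config$background_level +
    stats::runif(1, -config$brightness_jitter, config$brightness_jitter)
  img <- matrix(bg, sz, sz)
  for (k in seq_len(n)) {
    tr <- matrix(1, sz, sz)
    it <- cells[[k]]$intensity
    tr[masks[[k]]] <- it$cyto_t *
      (1 + stats::rnorm(sum(masks[[k]]), sd = it$texture_amp))
    tr[nuclei[[k]]] <- tr[nuclei[[k]]] * it$nucleus_t
    img <- img * pmin(pmax(tr, 0.05), 1.2)^config$blend_opacity
  }
  img <- img + stats::rnorm(sz * sz, sd = config$noise_sd)
  img <- pmin(pmax(img, 0), 1)

  boxes <- lapply(masks, mask_tight_box)
  list(image = img,
       masks = instance_mask_set(masks),
       meta = list(n_cells = n, achieved_overlap = achieved,
                   target_overlap = target, boxes = boxes))
}

#' Tight half-open bounding box of a binary mask
#' @param mask logical matrix with at least one TRUE pixel.
#' @return a \code{pc_box}: for a mask occupying rows r1..r2 and cols c1..c2
#'   the box is (c1-1, r1-1, c2, r2).
#' @export
mask_tight_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask_tight_box: empty mask")
  pc_box(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

#' Generate one reproducible synthetic scene
#'
#' Seeds the RNG from \code{config$seed} (plus \code{index}) and draws the
#' cell count, the templates, and the composition, so identical
#' (config, seed, index) produce byte-identical scenes.
#'
#' @param config a \code{synth_config}.
#' @param index scene index used to derive the per-scene seed (default 1).
#' @return list(image, masks, meta) as \code{\link{compose_image}}, with the
#'   seed recorded in meta.
#' @export
synth_scene <- function(config = synth_config(), index = 1L) {
  seed <- (config$seed + 7919L * (as.integer(index) - 1L)) %% .Machine$integer.max
  set.seed(seed)
  n <- if (config$n_cells_range[1] == config$n_cells_range[2]) config$n_cells_range[1]
       else sample(seq.int(config$n_cells_range[1], config$n_cells_range[2]), 1L)
  if (length(config$target_overlap_rate) == 2L)   # draw a per-scene rate from the range
    config$target_overlap_rate <- stats::runif(1, config$target_overlap_rate[1],
                                               config$target_overlap_rate[2])
  cells <- replicate(n, sample_cell(config$cell), simplify = FALSE)
  sc <- compose_image(cells, config)
  sc$meta$seed <- seed
  sc$meta$index <- as.integer(index)
  sc
}

#' Generate a synthetic dataset of scenes
#' @param n_images number of scenes.
#' @param config a \code{synth_config}; per-scene seeds derive from its seed.
#' @param start_index index offset (scenes i = start_index .. start_index+n-1),
#'   handy for disjoint train/held-out splits from one config.
#' @return list of scenes.
#' @export
synth_dataset <- function(n_images, config = synth_config(), start_index = 1L) {
  lapply(seq.int(start_index, length.out = n_images),
         function(i) synth_scene(config, index = i))
}

# Geometric augmentation -------------------------------------------------------

rot90_mat <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])  # one CW quarter turn
  m
}

scale_mat <- function(m, factor, nearest = TRUE) {
  H <- nrow(m); W <- ncol(m)
  # resample about the canvas center on the same canvas
  src_r <- ((seq_len(H) - 0.5) - H / 2) / factor + H / 2 + 0.5
  src_c <- ((seq_len(W) - 0.5) - W / 2) / factor + W / 2 + 0.5
  ri <- round(src_r); ci <- round(src_c)
  ok_r <- ri >= 1 & ri <= H; ok_c <- ci >= 1 & ci <= W
  out <- matrix(if (is.logical(m)) FALSE else 0, H, W)
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

#' Apply a fixed geometric transform to an image and its masks
#'
#' @param image H x W numeric matrix.
#' @param masks an \code{instance_mask_set} sharing the image's dimensions.
#' @param transform list with any of \code{hflip}, \code{vflip} (logicals),
#'   \code{rot90} (integer quarter-turns), \code{scale} (positive factor).
#' @return list(image, masks, transform); instances whose mask becomes empty
#'   (possible when scaling down) are dropped with a warning.
#' @export
apply_transform <- function(image, masks, transform) {
  stopifnot(inherits(masks, "instance_mask_set"))
  if (length(masks$masks) && !identical(dim(image), dim(masks$masks[[1]])))
    stop("apply_transform: image and masks dimensions differ")
  tf <- modifyList(list(hflip = FALSE, vflip = FALSE, rot90 = 0L, scale = 1), transform)
  one <- function(m) {
    if (tf$hflip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (tf$vflip) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (tf$rot90 %% 4L != 0L) m <- rot90_mat(m, tf$rot90)
    if (tf$scale != 1) m <- scale_mat(m, tf$scale)
    m
  }
  img2 <- one(image)
  ms2 <- lapply(masks$masks, one)
  keep <- vapply(ms2, any, logical(1))
  if (!all(keep))
    warning(sum(!keep), " instance(s) became empty under the transform and were dropped",
            call. = FALSE)
  ig <- masks$ignore_mask
  if (!is.null(ig)) ig <- one(ig)
  list(image = img2, masks = instance_mask_set(ms2[keep], ig), transform = tf)
}

#' Random augmentation: flips, quarter-turn rotation, mild scaling
#'
#' Draws a transform (each component applied with probability 1/2; scaling
#' bounded to [0.8, 1.2] so instances stay non-degenerate) and applies the
#' identical transform to image and masks. Uses the R global random stream.
#'
#' @inheritParams apply_transform
#' @return list(image, masks, transform).
#' @export
augment <- function(image, masks) {
  tf <- list(hflip = stats::runif(1) < 0.5,
             vflip = stats::runif(1) < 0.5,
             rot90 = sample(0:3, 1L),
             scale = if (stats::runif(1) < 0.5) stats::runif(1, 0.8, 1.2) else 1)
  apply_transform(image, masks, tf)
}
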