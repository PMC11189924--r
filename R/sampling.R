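# Geometry and sampling kernels shared by the model and the refinement head.
#
# Package-wide coordinate convention:
#  * image coordinates are continuous, origin at the top-left corner,
#    x along columns, y along rows;
#  * the center of pixel (row r, col c) (1-based) is (c - 0.5, r - 0.5);
#  * a feature-grid node (i, j) with stride s sits at ((j - 0.5) * s, (i - 0.5) * s);
#  * boxes are half-open [x1, x2) x [y1, y2) in image coordinates.
# Continuous sampling everywhere ("align corners = FALSE" semantics);
# out-of-range queries clamp to the border node centers.

#' Multi-channel feature grid with a stride
#'
#' A thin container for an H x W x C array of feature values plus the stride
#' (in image pixels) between adjacent grid nodes. Node \code{(i, j)} sits at
#' image point \code{((j - 0.5) * stride, (i - 0.5) * stride)}.
#'
#' @param values numeric matrix (H x W, treated as one channel) or H x W x C array.
#' @param stride positive number of image pixels per grid cell.
#' @return an object of class \code{grid_feature}.
#' @export
grid_feature <- function(values, stride = 1) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (d[1] < 2L || d[2] < 2L)
    stop("grid_feature: grid must be at least 2x2 for interpolation, got ",
         d[1], "x", d[2])
  if (!is.numeric(stride) || length(stride) != 1L || stride <= 0)
    stop("grid_feature: stride must be a single positive number")
  structure(list(values = values, stride = stride), class = "grid_feature")
}

#' @export
print.grid_feature <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_feature %dx%dx%d, stride %g>\n", d[1], d[2], d[3], x$stride))
  invisible(x)
}

#' Set of real-valued sample points
#'
#' @param x,y numeric vectors of equal length, finite.
#' @param frame either \code{"image"} (absolute image coordinates) or
#'   \code{"norm"} (normalized box coordinates in \code{[0,1]^2}).
#' @return a data.frame with columns \code{x}, \code{y} and a \code{frame} attribute.
#' @export
point_set <- function(x, y, frame = c("image", "norm")) {
  frame <- match.arg(frame)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("point_set: x and y lengths differ")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("point_set: coordinates must be finite")
  structure(data.frame(x = x, y = y), frame = frame, class = c("point_set", "data.frame"))
}

point_frame <- function(points) {
  f <- attr(points, "frame")
  if (is.null(f)) "image" else f
}

#' Axis-aligned box in image coordinates
#'
#' Half-open box \code{[x1, x2) x [y1, y2)} with positive area.
#' @param x1,y1,x2,y2 numeric scalars, \code{x2 > x1}, \code{y2 > y1}.
#' @return a named numeric vector of class \code{pc_box}.
#' @export
pc_box <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (!all(is.finite(b))) stop("pc_box: coordinates must be finite")
  if (b["x2"] <= b["x1"] || b["y2"] <= b["y1"])
    stop("pc_box: box must have positive area")
  structure(b, class = "pc_box")
}

box_width  <- function(box) unname(box["x2"] - box["x1"])
box_height <- function(box) unname(box["y2"] - box["y1"])

#' Clip a box to image bounds
#' @param box a \code{pc_box}.
#' @param image_hw integer c(H, W).
#' @return clipped \code{pc_box}, or NULL if the clipped area is empty.
#' @export
clip_box <- function(box, image_hw) {
  x1 <- max(box["x1"], 0); y1 <- max(box["y1"], 0)
  x2 <- min(box["x2"], image_hw[2]); y2 <- min(box["y2"], image_hw[1])
  if (x2 <= x1 || y2 <= y1) return(NULL)
  pc_box(x1, y1, x2, y2)
}

# Bilinear interpolation plumbing ---------------------------------------------

# Map image-frame coordinates to continuous (1-based) grid coordinates and
# compute the four corner indices plus convex weights. Queries outside the
# convex hull of node centers clamp to the border.
bilinear_weights <- function(dims_hw, stride, x, y) {
  H <- dims_hw[1]; W <- dims_hw[2]
  gx <- pmin(pmax(x / stride + 0.5, 1), W)   # continuous col index in [1, W]
  gy <- pmin(pmax(y / stride + 0.5, 1), H)   # continuous row index in [1, H]
  j0 <- pmin(floor(gx), W - 1); i0 <- pmin(floor(gy), H - 1)
  fx <- gx - j0; fy <- gy - i0                # in [0, 1]
  list(i0 = as.integer(i0), j0 = as.integer(j0),
       w00 = (1 - fy) * (1 - fx),   # node (i0, j0)
       w01 = (1 - fy) * fx,         # node (i0, j0+1)
       w10 = fy * (1 - fx),         # node (i0+1, j0)
       w11 = fy * fx)               # node (i0+1, j0+1)
}

#' Bilinear sampling of a feature grid at real-valued points
#'
#' Each sampled value is the convex combination of the four nearest grid-node
#' values; the interpolation is exact at node centers and exactly reproduces
#' any function of the form \code{a + b*x + c*y + d*x*y} in the interior.
#'
#' @param grid a \code{grid_feature}.
#' @param points a \code{point_set} in the image frame of the grid.
#' @return numeric matrix, one row per point, one column per channel.
#' @export
bilinear_sample <- function(grid, points) {
  stopifnot(inherits(grid, "grid_feature"))
  d <- dim(grid$values); H <- d[1]; W <- d[2]; C <- d[3]
  n <- nrow(points)
  if (n == 0L) return(matrix(numeric(0), 0, C))
  bw <- bilinear_weights(c(H, W), grid$stride, points$x, points$y)
  v <- matrix(grid$values, H * W, C)     # column-major: node (i,j) -> row i + (j-1)*H
  r00 <- bw$i0 + (bw$j0 - 1L) * H
  out <- bw$w00 * v[r00, , drop = FALSE] +
         bw$w01 * v[r00 + H, , drop = FALSE] +
         bw$w10 * v[r00 + 1L, , drop = FALSE] +
         bw$w11 * v[r00 + H + 1L, , drop = FALSE]
  out
}

# Adjoint of bilinear_sample: scatter per-point gradients (n x C) back onto
# the grid nodes with the same convex weights. Returns an H x W x C array.
bilinear_scatter <- function(dims_hwc, stride, points, grad) {
  H <- dims_hwc[1]; W <- dims_hwc[2]; C <- dims_hwc[3]
  out <- matrix(0, H * W, C)
  n <- nrow(points)
  if (n == 0L) return(array(out, dims_hwc))
  bw <- bilinear_weights(c(H, W), stride, points$x, points$y)
  r00 <- bw$i0 + (bw$j0 - 1L) * H
  idx <- c(r00, r00 + H, r00 + 1L, r00 + H + 1L)
  wts <- c(bw$w00, bw$w01, bw$w10, bw$w11)
  for (ch in seq_len(C)) {
    g <- rep.int(grad[, ch], 4L) * wts
    acc <- rowsum(g, idx)               # sums duplicate node hits
    out[as.integer(rownames(acc)), ch] <- out[as.integer(rownames(acc)), ch] + acc[, 1]
  }
  array(out, dims_hwc)
}

# Regular sub-grid of sample points used by roi_align: for out_size x out_size
# output cells with sampling_ratio^2 samples each, in image coordinates.
roi_sample_points <- function(box, out_size, sampling_ratio) {
  bw <- box_width(box); bh <- box_height(box)
  s <- sampling_ratio
  # centers of an (out_size*s) x (out_size*s) uniform sub-grid over the box
  u <- (seq_len(out_size * s) - 0.5) / (out_size * s)
  x <- unname(box["x1"]) + u * bw
  y <- unname(box["y1"]) + u * bh
  pts <- expand.grid(y = y, x = x)      # y varies fastest (column-major cells)
  point_set(pts$x, pts$y, frame = "image")
}

#' RoI align: continuous-coordinate crop-and-resize of a feature map
#'
#' Averages \code{sampling_ratio^2} bilinear samples per output cell, placed
#' on a regular sub-grid; no coordinate quantization (this is RoI align, not
#' RoI pooling). Deterministic.
#'
#' @param map a \code{grid_feature}.
#' @param box a \code{pc_box} with positive area.
#' @param out_size output spatial side (default 7).
#' @param sampling_ratio samples per output cell side (default 2).
#' @return an \code{out_size x out_size x C} array.
#' @export
roi_align <- function(map, box, out_size = 7L, sampling_ratio = 2L) {
  stopifnot(inherits(map, "grid_feature"))
  if (!inherits(box, "pc_box")) stop("roi_align: box must be a pc_box")
  C <- dim(map$values)[3]
  pts <- roi_sample_points(box, out_size, sampling_ratio)
  v <- bilinear_sample(map, pts)        # (out*s)^2 x C
  s <- sampling_ratio
  # average each s x s block of the fine sub-grid down to out_size x out_size
  out <- array(0, c(out_size, out_size, C))
  fine <- array(v, c(out_size * s, out_size * s, C))
  ri <- rep(seq_len(out_size), each = s)
  for (ch in seq_len(C))
    out[, , ch] <- t(rowsum(t(rowsum(fine[, , ch], ri)), ri)) / (s * s)
  out
}

# Adjoint of roi_align: spread an out x out x C gradient back onto the map.
roi_align_backward <- function(map_dims_hwc, stride, box, grad_out,
                               out_size = 7L, sampling_ratio = 2L) {
  s <- sampling_ratio
  C <- map_dims_hwc[3]
  pts <- roi_sample_points(box, out_size, sampling_ratio)
  # each fine sample gets 1/s^2 of its cell's gradient
  gm <- matrix(0, (out_size * s)^2, C)
  idx_block <- rep(seq_len(out_size), each = s)
  cell_of_fine <- outer(idx_block, (idx_block - 1L) * out_size, "+") # fine (i,j) -> cell id
  gflat <- matrix(grad_out, out_size * out_size, C)
  gm[] <- gflat[as.vector(cell_of_fine), ] / (s * s)
  bilinear_scatter(map_dims_hwc, stride, pts, gm)
}

# Uncertainty and point selection ---------------------------------------------

#' Uncertainty score of a binary-mask probability grid
#'
#' Scores each probability by closeness to 0.5: the returned value is
#' \code{-|p - 0.5|}, so the most uncertain locations (p near 0.5, i.e.
#' boundary-adjacent pixels) have the highest score (0) and saturated
#' predictions the lowest (-0.5).
#'
#' @param prob numeric vector/matrix/array with values in \code{[0, 1]}.
#' @return object of the same shape with the uncertainty scores.
#' @export
uncertainty <- function(prob) {
  if (any(!is.finite(prob)) || any(prob < 0 | prob > 1))
    stop("uncertainty: probabilities must lie in [0, 1]")
  -abs(prob - 0.5)
}

#' Select uncertain points on a probability grid
#'
#' Returns point coordinates in the normalized \code{[0,1]^2} frame of the
#' grid. \code{"topk"} picks exactly the \code{n} most uncertain grid cells
#' (ties broken by row-major index; fully deterministic) and is the inference
#' default. \code{"oversample_random"} draws \code{oversample * n} uniform
#' candidate points, keeps the \code{importance_frac} most uncertain among
#' them (scored by bilinear interpolation of the uncertainty surface), and
#' fills the remainder with fresh uniform points; it is the training default
#' and uses the R global random stream (seed with \code{set.seed}).
#'
#' @param prob probability matrix in \code{[0, 1]} at the candidate resolution.
#' @param n number of points to select; at most \code{length(prob)} for topk.
#' @param strategy \code{"topk"} or \code{"oversample_random"}.
#' @param oversample oversampling factor k for the random strategy (default 3).
#' @param importance_frac fraction of points taken by uncertainty ranking
#'   (default 0.75).
#' @return a \code{point_set} in the \code{"norm"} frame.
#' @export
select_points <- function(prob, n, strategy = c("topk", "oversample_random"),
                          oversample = 3, importance_frac = 0.75) {
  strategy <- match.arg(strategy)
  if (!is.matrix(prob)) stop("select_points: prob must be a matrix")
  if (any(prob < 0 | prob > 1)) stop("select_points: probabilities outside [0, 1]")
  H <- nrow(prob); W <- ncol(prob)
  if (n < 1) stop("select_points: n must be >= 1")
  if (strategy == "topk") {
    if (n > H * W)
      stop("select_points: n (", n, ") exceeds the ", H * W, " candidate points")
    u <- as.vector(t(uncertainty(prob)))           # row-major order
    ord <- order(-u, seq_along(u))                 # ties -> lower row-major index
    sel <- ord[seq_len(n)] - 1L
    i <- sel %/% W + 1L; j <- sel %% W + 1L
    point_set((j - 0.5) / W, (i - 0.5) / H, frame = "norm")
  } else {
    k <- max(1L, as.integer(ceiling(oversample)))
    n_imp <- min(n, floor(importance_frac * n))
    cand_x <- stats::runif(k * n); cand_y <- stats::runif(k * n)
    ugrid <- grid_feature(uncertainty(prob), stride = 1)
    # normalized -> grid-image coords of the H x W uncertainty grid
    sc <- bilinear_sample(ugrid, point_set(cand_x * W, cand_y * H, frame = "image"))[, 1]
    keep <- order(-sc)[seq_len(n_imp)]
    n_fill <- n - n_imp
    fx <- stats::runif(n_fill); fy <- stats::runif(n_fill)
    point_set(c(cand_x[keep], fx), c(cand_y[keep], fy), frame = "norm")
  }
}

# Map points between the normalized frame of a box and image coordinates.
norm_to_image <- function(points, box) {
  point_set(unname(box["x1"]) + points$x * box_width(box),
            unname(box["y1"]) + points$y * box_height(box), frame = "image")
}

# Bilinear up-sampling of a probability/score matrix to a target H x W,
# treating the input as a grid over the same (normalized) domain.
upsample_bilinear <- function(mat, out_hw) {
  g <- grid_feature(mat, stride = 1)
  H <- nrow(mat); W <- ncol(mat)
  ho <- out_hw[1]; wo <- out_hw[2]
  xs <- ((seq_len(wo) - 0.5) / wo) * W
  ys <- ((seq_len(ho) - 0.5) / ho) * H
  pts <- expand.grid(y = ys, x = xs)
  matrix(bilinear_sample(g, point_set(pts$x, pts$y, frame = "image"))[, 1], ho, wo)
}
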