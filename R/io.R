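# Formats and configuration: scene directories (PNG masks + JSON index),
# YAML run configuration with strict key checking, checkpoints, and the
# ablation-grid driver.

#' Write a scene (image + instance masks + metadata) to a directory
#'
#' Layout: \code{image.png} (8-bit gray), one binary \code{cell_000.png} per
#' instance, and \code{index.json} with the image path, mask file list,
#' per-cell tight bounding boxes, achieved overlap rate and a config echo.
#' \code{\link{read_scene}} round-trips the masks bit-exactly.
#'
#' @param scene list with \code{image}, \code{masks}
#'   (\code{instance_mask_set}), optional \code{meta}.
#' @param dir output directory (created if needed).
#' @param config optional \code{synth_config} echoed into the index.
#' @return \code{dir}, invisibly.
#' @export
write_scene <- function(scene, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- pmin(pmax(scene$image, 0), 1)
  png::writePNG(img, file.path(dir, "image.png"))
  masks <- scene$masks$masks
  files <- sprintf("cell_%03d.png", seq_along(masks) - 1L)
  for (k in seq_along(masks))
    png::writePNG(masks[[k]] * 1, file.path(dir, files[k]))
  if (!is.null(scene$masks$ignore_mask))
    png::writePNG(scene$masks$ignore_mask * 1, file.path(dir, "ignore.png"))
  boxes <- lapply(masks, function(m) as.numeric(mask_tight_box(m)))
  meta <- scene$meta
  if (!is.null(meta$boxes)) meta$boxes <- lapply(meta$boxes, as.numeric)
  idx <- list(image = "image.png", masks = files,
              has_ignore = !is.null(scene$masks$ignore_mask),
              height = nrow(img), width = ncol(img),
              n_cells = length(masks), boxes = boxes,
              meta = meta,
              config = if (!is.null(config)) unclass(config) else NULL)
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a scene directory written by \code{\link{write_scene}}
#'
#' Validates the index against the files on disk: every listed mask must
#' exist, be nonempty and match the image dimensions; violations raise a
#' format error naming the offending file.
#'
#' @param dir scene directory.
#' @return list(image, masks, meta).
#' @export
read_scene <- function(dir) {
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path)) stop("read_scene: missing index.json in ", dir)
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  img_path <- file.path(dir, idx$image)
  if (!file.exists(img_path)) stop("read_scene: missing image file ", img_path)
  img <- png::readPNG(img_path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  masks <- vector("list", length(idx$masks))
  for (k in seq_along(idx$masks)) {
    f <- file.path(dir, idx$masks[k])
    if (!file.exists(f)) stop("read_scene: mask file listed in index is missing: ", f)
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (!identical(dim(m), dim(img)))
      stop("read_scene: mask dimensions differ from image: ", f)
    m <- m > 0.5
    if (!any(m)) stop("read_scene: empty mask: ", f)
    masks[[k]] <- m
  }
  ig <- NULL
  if (isTRUE(idx$has_ignore)) {
    f <- file.path(dir, "ignore.png")
    if (!file.exists(f)) stop("read_scene: index promises ignore.png but it is missing")
    ig <- png::readPNG(f) > 0.5
  }
  meta <- idx$meta
  list(image = img, masks = instance_mask_set(masks, ig), meta = meta)
}

#' Write / read a dataset of scenes under one root
#' @param dataset list of scenes.
#' @param root directory; scenes go to \code{scene_0001} etc.
#' @param config optional config echo.
#' @return \code{root}, invisibly.
#' @export
write_dataset <- function(dataset, root, config = NULL) {
  for (i in seq_along(dataset))
    write_scene(dataset[[i]], file.path(root, sprintf("scene_%04d", i)), config)
  invisible(root)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(root) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  dirs <- dirs[file.exists(file.path(dirs, "index.json"))]
  lapply(dirs, read_scene)
}

# Run configuration --------------------------------------------------------------

run_config_keys <- function() {
  c(names(formals(synth_config)), names(formals(model_config)),
    "threshold", "strict", "n_images", "out_dir", "data_dir", "log_level")
}

#' Read a YAML run configuration with strict key checking
#'
#' Unknown keys are rejected with a message naming them, so typos fail loudly
#' rather than being silently ignored. \code{\link{write_run_config}} is the
#' exact inverse (round-trip identity on the stored values).
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("read_run_config: malformed config file ", path)
  bad <- setdiff(names(cfg), run_config_keys())
  if (length(bad))
    stop("read_run_config: unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @param config named list to store.
#' @export
write_run_config <- function(config, path) {
  bad <- setdiff(names(config), run_config_keys())
  if (length(bad))
    stop("write_run_config: unknown configuration key(s): ", paste(bad, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

# Checkpoints ---------------------------------------------------------------------

#' Save / load a training checkpoint
#'
#' A checkpoint is a single file holding the weights, optimizer state, the
#' full config echo, the seed and the package version; loading verifies the
#' config is structurally compatible (same alpha / widths / point-head
#' shape).
#'
#' @param checkpoint checkpoint from \code{\link{train}}.
#' @param path file path.
#' @return \code{path} (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config optional \code{model_config} to verify against.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (is.null(ck$params) || is.null(ck$config))
    stop("load_checkpoint: not a checkpoint file: ", path)
  if (!is.null(config)) {
    for (key in c("alpha", "fpn_width", "point_head_width", "backbone_spec", "roi_out"))
      if (!identical(ck$config[[key]], config[[key]]))
        stop("load_checkpoint: checkpoint incompatible with config (field ", key, ")")
  }
  ck
}

# Ablation grid -------------------------------------------------------------------

#' Ablation over point-head depth, point count, and the point head itself
#'
#' Trains and evaluates one model per grid cell (alpha x beta, plus an
#' optional "without point head" baseline) from a shared seed and returns a
#' table of DSC/TPRp/FPRp/FNRo (mean +- sd). A failing cell is marked
#' \code{status = "failed"} and the run continues.
#'
#' @param train_set,eval_set scene lists.
#' @param base_config \code{model_config} supplying everything but the grid.
#' @param alphas point-head depths to try (default 2:4).
#' @param betas training point counts to try (default c(196, 784)).
#' @param include_no_point_head add the coarse-only baseline row.
#' @param threshold DSC threshold for evaluation.
#' @return data.frame with one row per grid cell.
#' @export
ablate <- function(train_set, eval_set, base_config,
                   alphas = c(2L, 3L, 4L), betas = c(196L, 784L),
                   include_no_point_head = TRUE, threshold = 0.7) {
  grid <- expand.grid(alpha = alphas, beta = betas, point_head = TRUE)
  if (include_no_point_head)
    grid <- rbind(grid, data.frame(alpha = base_config$alpha,
                                   beta = base_config$beta_train, point_head = FALSE))
  rows <- NULL
  for (r in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$alpha <- as.integer(grid$alpha[r])
    cfg$beta_train <- as.integer(grid$beta[r])
    cfg$use_point_head <- grid$point_head[r]
    row <- tryCatch({
      ck <- train(train_set, cfg)
      preds <- predict_dataset(eval_set, ck)
      rep_ <- evaluate_masks(lapply(eval_set, `[[`, "masks"), preds,
                             threshold = threshold)
      data.frame(alpha = cfg$alpha, beta = cfg$beta_train,
                 point_head = cfg$use_point_head,
                 dsc = rep_$dsc_mean, dsc_sd = rep_$dsc_sd,
                 tprp = rep_$tprp_mean, tprp_sd = rep_$tprp_sd,
                 fprp = rep_$fprp_mean, fprp_sd = rep_$fprp_sd,
                 fnro = rep_$fnro, status = "ok")
    }, error = function(e) {
      data.frame(alpha = grid$alpha[r], beta = grid$beta[r],
                 point_head = grid$point_head[r],
                 dsc = NA, dsc_sd = NA, tprp = NA, tprp_sd = NA,
                 fprp = NA, fprp_sd = NA, fnro = NA,
                 status = paste("failed:", conditionMessage(e)))
    })
    rows <- rbind(rows, row)
  }
  rows
}
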