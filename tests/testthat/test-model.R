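# Backbone/FPN contract, proposals, mask and point heads, losses, training.

test_that("config validation enforces the supported hyperparameter space", {
  expect_error(model_config(alpha = 5), "alpha")
  expect_error(model_config(beta_train = 0), "beta")
  cfg <- model_config()
  expect_equal(cfg$mask_out, 4L * cfg$roi_out)
  expect_equal(cfg$alpha, 3L)
  expect_equal(cfg$beta_train, 196L)
  expect_equal(cfg$beta_infer, 784L)
  expect_equal(cfg$lr, 0.002)
  expect_equal(cfg$momentum, 0.9)
})

test_that("backbone produces a stride-4/8/16/32 pyramid with deterministic outputs", {
  cfg <- model_config(seed = 3)
  bb <- build_backbone(cfg)
  img <- matrix(stats::runif(128 * 128), 128, 128)
  pyr <- bb(img)
  expect_named(pyr, c("P2", "P3", "P4", "P5"))
  expect_equal(dim(pyr$P2$values)[1:2], c(32, 32))
  expect_equal(dim(pyr$P5$values)[1:2], c(4, 4))
  expect_equal(pyr$P3$stride, 8)
  widths <- vapply(pyr, function(p) dim(p$values)[3], integer(1))
  expect_true(all(widths == cfg$fpn_width))

  # determinism: same weights, same input
  expect_identical(pyr, bb(img))

  # doubling the input side doubles every level's side
  img2 <- matrix(stats::runif(256 * 256), 256, 256)
  pyr2 <- bb(img2)
  expect_equal(dim(pyr2$P2$values)[1:2], c(64, 64))
  expect_equal(dim(pyr2$P5$values)[1:2], c(8, 8))

  expect_error(bb(matrix(0, 100, 100)), "divisible by 32")
})

test_that("gt_boxes proposals are (jittered) tight mask boxes", {
  m <- matrix(FALSE, 64, 64); m[10:19, 20:39] <- TRUE
  gt <- instance_mask_set(list(m))
  img <- matrix(0.5, 64, 64)

  # half-open tight box of rows 10..19, cols 20..39 is (19, 9, 39, 19)
  b <- mask_tight_box(m)
  expect_equal(as.numeric(b), c(19, 9, 39, 19))

  cfg0 <- model_config(jitter = 0)
  expect_equal(as.numeric(propose(img, gt, cfg0)[[1]]), as.numeric(b))

  cfgj <- model_config(jitter = 0.1)
  set.seed(2)
  bj <- propose(img, gt, cfgj)[[1]]
  expect_true(all(abs(as.numeric(bj) - as.numeric(b)) <= 0.1 * max(20, 10) + 1e-9))

  # empty scene -> empty proposal list
  empty <- structure(list(masks = list(), ignore_mask = NULL), class = "instance_mask_set")
  expect_length(propose(img, empty, cfg0), 0)
})

test_that("mask head maps 7x7 RoI features to a 28x28 sigmoid grid", {
  cfg <- model_config(seed = 5)
  set.seed(5); params <- pointcell:::init_model(cfg)
  roi <- array(stats::rnorm(7 * 7 * cfg$fpn_width), c(7, 7, cfg$fpn_width))
  out <- mask_head(roi, list(params = params))
  expect_equal(dim(out$logits), c(28, 28))
  expect_true(all(out$probs > 0 & out$probs < 1))
  expect_equal(out$probs, pointcell:::sigmoid(out$logits))

  # zero-initialized projection -> all probabilities exactly 0.5
  p0 <- params; p0$mask$proj$w[] <- 0; p0$mask$proj$b[] <- 0
  out0 <- mask_head(roi, list(params = p0))
  expect_true(all(out0$probs == 0.5))

  # doubling the projection weights pushes every probability away from 0.5
  p2 <- params; p2$mask$proj$w <- 2 * p2$mask$proj$w; p2$mask$proj$b <- 2 * p2$mask$proj$b
  out2 <- mask_head(roi, list(params = p2))
  expect_true(all(abs(out2$probs - 0.5) >= abs(out$probs - 0.5) - 1e-12))

  expect_error(mask_head(matrix(0, 7, 7), list(params = params)), "array")
})

test_that("point head is a pointwise MLP: permutation-equivariant, depth-consistent", {
  cfg <- model_config(seed = 6)
  set.seed(6); params <- pointcell:::init_model(cfg)
  X <- matrix(stats::rnorm(50 * 2 * cfg$fpn_width), 50)
  lg <- point_head(X, list(params = params))
  expect_length(lg, 50)

  # permuting the point order permutes outputs identically
  perm <- sample(50)
  expect_equal(point_head(X[perm, ], list(params = params)), lg[perm])

  # zero final layer -> all probabilities 0.5
  p0 <- params; n <- length(p0$point)
  p0$point[[n]]$w[] <- 0; p0$point[[n]]$b[] <- 0
  expect_true(all(pointcell:::sigmoid(point_head(X, list(params = p0))) == 0.5))

  # alpha = 3 with an identity-initialized middle layer equals alpha = 2
  cfg2 <- model_config(alpha = 2, seed = 6)
  set.seed(6); params2 <- pointcell:::init_model(cfg2)
  pw <- cfg$point_head_width
  p3 <- params2
  p3$point <- list(params2$point[[1]],
                   list(w = diag(pw), b = numeric(pw)),   # identity + ReLU on nonneg input
                   params2$point[[2]],
                   params2$point[[3]])
  expect_equal(point_head(X, list(params = p3)), point_head(X, list(params = params2)),
               tolerance = 1e-12)
})

test_that("point BCE loss matches hand-computed values and rejects bad labels", {
  expect_lt(point_loss(rep(20, 5), rep(1, 5)), 1e-6)
  expect_equal(point_loss(0, 1), log(2))
  expect_equal(point_loss(0, 0), log(2))
  expect_equal(point_loss(c(0, 0), c(0, 1)), log(2))
  # symmetry check against the naive formula at moderate logits
  x <- c(-2, 0.5, 3); y <- c(0, 1, 1)
  naive <- mean(-(y * log(stats::plogis(x)) + (1 - y) * log(1 - stats::plogis(x))))
  expect_equal(point_loss(x, y), naive, tolerance = 1e-12)
  expect_error(point_loss(c(0, 1), c(0, 2)), "0/1")
})

test_that("total loss is the exact unweighted four-term sum", {
  lb <- total_loss(0, 0, 0, 0)
  expect_equal(lb$total, 0)
  lb <- total_loss(1, 2, 3, 4)
  expect_equal(lb$total, 10)
  expect_equal(lb$total, lb$mask + lb$point + lb$box + lb$cls)
  expect_error(total_loss(NaN, 0, 0, 0), "non-finite")
  expect_error(total_loss(-1, 0, 0, 0), "negative")
})

test_that("scene gradients match finite differences through the whole graph", {
  cfg_s <- small_synth_config(seed = 51, size = 64, cells = c(2L, 2L),
                              overlap = c(0.1, 0.1))
  sc <- suppressWarnings(synth_scene(cfg_s, 1))
  cfg <- model_config(seed = 5, augment = FALSE, beta_train = 16L)
  set.seed(5); params <- pointcell:::init_model(cfg)
  loss_fn <- function(p) { set.seed(77); pointcell:::fb_scene(p, sc, cfg)$loss$total }
  set.seed(77); fb <- pointcell:::fb_scene(params, sc, cfg)

  get_path <- function(tree, pth) { for (k in pth) tree <- tree[[k]]; tree }
  set_path <- function(tree, pth, val) {
    if (length(pth) == 1L) { tree[[pth[[1]]]] <- val; return(tree) }
    tree[[pth[[1]]]] <- set_path(tree[[pth[[1]]]], pth[-1], val)
    tree
  }
  paths <- list(
    stem   = list("backbone", 1L, 1L, "w"),
    lat2   = list("fpn", "lat", 1L, "w"),
    deconv = list("mask", "de1", "w"),
    point1 = list("point", 1L, "w"),
    fc1    = list("head", "fc1", "w"))
  set.seed(123)
  for (nm in names(paths)) {
    pth <- paths[[nm]]
    g <- get_path(fb$grads, pth)
    v0 <- get_path(params, pth)
    i <- sample(length(v0), 1)
    eps <- 1e-5
    bump <- function(delta) { v <- v0; v[i] <- v[i] + delta; set_path(params, pth, v) }
    g_num <- (loss_fn(bump(eps)) - loss_fn(bump(-eps))) / (2 * eps)
    expect_equal(g[i], g_num, tolerance = 1e-4,
                 label = paste("analytic grad of", nm))
  }
})

test_that("training is reproducible, trains with zero epochs as identity, and records history", {
  fx <- tiny_checkpoint()
  ck <- fx$ckpt
  expect_s3_class(ck$history, "data.frame")
  expect_equal(nrow(ck$history), 4)
  expect_true(all(is.finite(ck$history$total)))
  expect_equal(ck$history$total,
               ck$history$mask + ck$history$point + ck$history$box + ck$history$cls,
               tolerance = 1e-12)

  # epochs = 0 leaves the initialization untouched
  cfg0 <- model_config(epochs = 0L, seed = 5L)
  ck0 <- train(fx$data, cfg0)
  set.seed(5L); init <- pointcell:::init_model(cfg0)
  expect_identical(ck0$params, init)

  # same config + seed twice -> identical loss curves
  cfg2 <- model_config(epochs = 2L, seed = 9L, augment = TRUE)
  h1 <- suppressWarnings(train(fx$data, cfg2))$history
  h2 <- suppressWarnings(train(fx$data, cfg2))$history
  expect_identical(h1, h2)

  expect_error(train(fx$data[1], model_config(epochs = 1L)), "at least 2")
})
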