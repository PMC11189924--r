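# Synthetic overlapping-cell scene generation: templates, composition,
# overlap measurement, augmentation.

test_that("sample_cell honors parameter ranges and its invariants", {
  p <- cell_params(128)

  # determinism under the same seed
  set.seed(42); t1 <- sample_cell(p)
  set.seed(42); t2 <- sample_cell(p)
  expect_identical(t1, t2)

  # zero perturbation amplitude -> exact ellipse contour
  p0 <- p; p0$perturb_amp_range <- c(0, 0)
  set.seed(1); tpl <- sample_cell(p0)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  r <- pointcell:::cell_radius(tpl, th)
  want <- tpl$a * tpl$b / sqrt((tpl$b * cos(th - tpl$phi))^2 + (tpl$a * sin(th - tpl$phi))^2)
  expect_equal(r, want, tolerance = 1e-12)

  # nucleus strictly smaller than cytoplasm, by pixel rasterization
  set.seed(7)
  for (i in 1:5) {
    tpl <- sample_cell(p)
    rc <- pointcell:::rasterize_cell(tpl, c(64, 64), c(128, 128), nucleus = TRUE)
    expect_gt(sum(rc$cyto), 0)
    expect_lt(sum(rc$nucleus), sum(rc$cyto))
    expect_true(all(rc$cyto[rc$nucleus]))   # nucleus contained in cytoplasm
  }

  bad <- p; bad$radius_range <- c(30, 10)
  expect_error(sample_cell(bad), "min <= max")
})

test_that("measure_overlap_rate matches brute-force pixel counting", {
  # disjoint masks and a single mask both give 0
  a <- matrix(FALSE, 10, 10); a[1:3, 1:3] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(measure_overlap_rate(instance_mask_set(list(a, b))), 0)
  expect_equal(measure_overlap_rate(instance_mask_set(list(a))), 0)

  # |A| = 100, |B| = 100, |A n B| = 50 -> 0.5
  A <- matrix(FALSE, 20, 20); A[1:10, 1:10] <- TRUE
  B <- matrix(FALSE, 20, 20); B[1:10, 6:15] <- TRUE
  expect_equal(sum(A), 100); expect_equal(sum(A & B), 50)
  expect_equal(measure_overlap_rate(instance_mask_set(list(A, B))), 0.5)

  # identical co-located masks -> rate 1
  expect_equal(measure_overlap_rate(instance_mask_set(list(A, A))), 1)

  expect_error(measure_overlap_rate(list()), "empty")
})

test_that("compose_image returns one nonempty mask per cell and tracks the target overlap", {
  cfg <- synth_config(image_size = 128, n_cells_range = c(5, 5),
                      target_overlap_rate = 0.2, cell = cell_params(128), seed = 3)
  set.seed(3)
  cells <- replicate(5, sample_cell(cfg$cell), simplify = FALSE)
  sc <- suppressWarnings(compose_image(cells, cfg))
  expect_length(sc$masks$masks, 5)
  expect_true(all(vapply(sc$masks$masks, any, logical(1))))
  expect_equal(sc$meta$achieved_overlap, measure_overlap_rate(sc$masks))
  expect_true(all(dim(sc$image) == 128))
  expect_true(all(sc$image >= 0 & sc$image <= 1))

  # single cell: no partner to overlap
  set.seed(4)
  one <- compose_image(list(sample_cell(cfg$cell)),
                       synth_config(image_size = 128, n_cells_range = c(1, 1),
                                    target_overlap_rate = 0, cell = cfg$cell))
  expect_length(one$masks$masks, 1)
  expect_equal(one$meta$achieved_overlap, 0)
})

test_that("scenes are reproducible and overlap responds monotonically to the target", {
  cfg <- synth_config(image_size = 128, n_cells_range = c(3, 5),
                      target_overlap_rate = 0.2, cell = cell_params(128), seed = 17)
  s1 <- suppressWarnings(synth_scene(cfg, 2))
  s2 <- suppressWarnings(synth_scene(cfg, 2))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$masks, s2$masks)

  rates <- vapply(c(0, 0.2, 0.4), function(tg) {
    cfgt <- synth_config(image_size = 128, n_cells_range = c(4, 4),
                         target_overlap_rate = tg, cell = cell_params(128), seed = 23)
    mean(vapply(1:4, function(i)
      suppressWarnings(synth_scene(cfgt, i))$meta$achieved_overlap, numeric(1)))
  }, numeric(1))
  expect_gte(rates[2], rates[1] - 0.05)
  expect_gte(rates[3], rates[2] - 0.05)

  # overlapping clump interiors are darker than single-covered cytoplasm
  cfg2 <- synth_config(image_size = 128, n_cells_range = c(2, 2),
                       target_overlap_rate = 0.4, cell = cell_params(128),
                       noise_sd = 0, seed = 29)
  sc <- suppressWarnings(synth_scene(cfg2, 1))
  cover <- Reduce(`+`, lapply(sc$masks$masks, function(m) m * 1L))
  if (any(cover >= 2)) {
    nuc_free <- sc$image > 0.2   # avoid nucleus pixels dominating
    expect_lt(mean(sc$image[cover >= 2 & nuc_free]),
              mean(sc$image[cover == 1 & nuc_free]))
  }
})

test_that("augmentation applies one geometric transform to image and masks alike", {
  cfg <- small_synth_config(seed = 41, size = 64, cells = c(2L, 3L))
  sc <- suppressWarnings(synth_scene(cfg, 1))

  # horizontal flip is an involution
  f1 <- apply_transform(sc$image, sc$masks, list(hflip = TRUE))
  f2 <- apply_transform(f1$image, f1$masks, list(hflip = TRUE))
  expect_identical(f2$image, sc$image)
  expect_identical(f2$masks$masks, sc$masks$masks)

  # quarter-turn rotation preserves every mask's pixel count
  r1 <- apply_transform(sc$image, sc$masks, list(rot90 = 1L))
  expect_equal(vapply(r1$masks$masks, sum, integer(1)),
               vapply(sc$masks$masks, sum, integer(1)))

  # DSC between two masks is invariant under flipping both together
  m1 <- sc$masks$masks[[1]]; m2 <- sc$masks$masks[[2]]
  d0 <- dsc(m1, m2)
  fl <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  expect_equal(dsc(fl(m1), fl(m2)), d0)

  # random augmentation keeps mask binariness and nonemptiness
  set.seed(10)
  au <- suppressWarnings(augment(sc$image, sc$masks))
  expect_true(all(vapply(au$masks$masks, is.logical, logical(1))))
  expect_true(all(vapply(au$masks$masks, any, logical(1))))
  expect_identical(dim(au$image), dim(sc$image))
})
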