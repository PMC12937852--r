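test_that("phantom volumes round-trip through NIfTI", {
  spec <- phantom_spec(n_volumes = 2, slices_per_volume = 3, image_size = 24,
                       seed = 3)
  dir <- tempfile("phantom")
  manifest <- write_dataset(spec, dir)
  v <- load_volume(manifest$image[1], manifest$label[1])
  ref <- generate_volume(spec, 1)
  expect_equal(v$image, ref$image, tolerance = 1e-6)
  expect_equal(v$labels, ref$mask, tolerance = 1e-6)
  expect_equal(v$spacing, c(1, 1, 5))
  expect_error(load_volume(manifest$image[1], file.path(dir, "nope.nii.gz")),
               "nope")
})

test_that("anisotropic header spacing flows into distance metrics", {
  spec <- phantom_spec(n_volumes = 1, slices_per_volume = 2, image_size = 24,
                       spacing = c(0.5, 0.5, 4), seed = 4)
  dir <- tempfile("spacing")
  manifest <- write_dataset(spec, dir)
  v <- load_volume(manifest$image[1], manifest$label[1])
  expect_equal(v$spacing, c(0.5, 0.5, 4))
  pair <- mask_pair(v$labels, v$labels, spacing = v$spacing)
  expect_equal(pair$spacing, c(0.5, 0.5, 4))
})

test_that("label mapping follows the multi-class and binary schemes", {
  labs <- array(c(0, 1, 2, 3, 4, 5), c(6, 1, 1))
  expect_equal(as.vector(map_labels(labs, "aisd")), c(0, 1, 1, 1, 0, 1))
  expect_equal(as.vector(map_labels(labs * 0, "aisd")), rep(0, 6))
  labs2 <- array(c(0, 7), c(2, 1, 1))
  expect_equal(as.vector(map_labels(labs2, "binary")), c(0, 1))
  expect_error(map_labels(labs, "other"))
})

test_that("slice normalization clips, scales and replicates channels", {
  flat <- matrix(5, 8, 8)
  out <- normalize_slice(flat, "dwi")
  expect_equal(out, array(-1, c(8, 8, 3)))  # constant -> 0 -> standardized
  set.seed(16)
  sl <- matrix(runif(64), 8, 8)
  out <- normalize_slice(sl, "phantom")
  expect_equal(out[, , 1], out[, , 2])
  expect_equal(out[, , 1], out[, , 3])
  expect_true(all(out >= -1 - 1e-12 & out <= 1 + 1e-12))
  # HU windowing: values above 80 HU saturate
  hu <- matrix(c(-50, 0, 40, 80, 500, 20), 2, 3)
  u <- strokevit:::to_unit(hu, "ncct")
  expect_equal(max(u), 1)
  expect_equal(u[1, 3], u[1, 1] + 1)  # 500 and -50 both clip to the window ends
})

test_that("augmentation is deterministic and transforms image and mask together", {
  set.seed(17)
  msk <- matrix(0, 24, 24)
  msk[8:16, 10:18] <- 1
  pair <- list(image = msk, mask = msk)  # image equal to its mask
  pol <- augment_policy(noise_sd = 0, intensity_range = c(1, 1))
  set.seed(99); a1 <- augment(pair, pol)
  set.seed(99); a2 <- augment(pair, pol)
  expect_identical(a1, a2)
  # replicate the sampled transform: image and mask move together
  set.seed(99)
  ang <- runif(1, -10, 10)
  ref_mask <- (rotate_slice(msk, ang, "nearest") > 0.5) * 1
  ref_img <- rotate_slice(msk, ang, "bilinear")
  if (runif(1) < pol$hflip_prob) {
    ref_mask <- ref_mask[, rev(seq_len(ncol(ref_mask)))]
    ref_img <- ref_img[, rev(seq_len(ncol(ref_img)))]
  }
  expect_identical(a1$mask, ref_mask)
  expect_equal(a1$image, ref_img)
  expect_true(all(a1$mask %in% c(0, 1)))
  # disabled policy is the identity
  expect_identical(augment(pair, augment_policy(enabled = FALSE)), pair)
})

test_that("rotation within 10 degrees changes blob mask area only mildly", {
  msk <- matrix(0, 32, 32)
  ii <- matrix(seq_len(32), 32, 32); jj <- t(ii)
  msk[(ii - 16)^2 + (jj - 16)^2 <= 64] <- 1  # disc radius 8
  pol <- augment_policy(noise_sd = 0)
  set.seed(18)
  for (rep in 1:180) {
    a <- augment(list(image = msk, mask = msk), pol)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_lte(abs(sum(a$mask) - sum(msk)) / sum(msk), 0.15)
  }
})

test_that("slice extraction filters by brain area in training mode only", {
  spec <- phantom_spec(n_volumes = 2, slices_per_volume = 4, image_size = 24,
                       seed = 5)
  vols <- generate_dataset(spec)
  ev <- slice_dataset(vols, "eval")
  expect_length(ev, 8)  # every slice kept
  air <- list(list(image = array(0, c(24, 24, 3)),
                   mask = array(0, c(24, 24, 3)),
                   spacing = c(1, 1, 1), id = "air"))
  expect_length(slice_dataset(air, "train"), 0)
  expect_length(slice_dataset(air, "eval"), 3)
  # restacking eval slices reproduces the volume shape
  stacked <- simplify2array(lapply(ev[1:4], `[[`, "image"))
  expect_equal(stacked, vols[[1]]$image)
})

test_that("prepared slices are standardized with binary masks", {
  spec <- phantom_spec(n_volumes = 1, slices_per_volume = 2, image_size = 24,
                       lesions_range = c(1L, 2L), seed = 6)
  v <- generate_volume(spec, 1)
  sl <- slice_dataset(list(v), "eval")[[1]]
  prep <- prepare_slice(sl, 16L, "phantom")
  expect_identical(dim(prep$image), c(16L, 16L, 3L))
  expect_true(all(prep$mask %in% c(0, 1)))
  expect_true(all(is.finite(prep$image)))
})

test_that("yaml configuration round-trips through the constructors", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "backbone:",
    "  patch_size: 8",
    "  embed_dim: 32",
    "  depth: 2",
    "  num_heads: 4",
    "  adapter_layers: [1, 2]",
    "  adapter_bottleneck: 8",
    "  num_register_tokens: 0",
    "  img_size: 32",
    "decoder:",
    "  branch_channels: 8",
    "  stage_channels: [16, 8, 8, 4]",
    "loss:",
    "  aux_weight: 0.3",
    "train:",
    "  epochs: 2",
    "  batch_size: 4",
    "  regime: frozen_backbone"
  ), path)
  cfg <- read_config(path)
  expect_identical(cfg$backbone$embed_dim, 32L)
  expect_identical(cfg$backbone$adapter_layers, c(1L, 2L))
  expect_identical(cfg$decoder$stage_channels, c(16L, 8L, 8L, 4L))
  expect_identical(cfg$train$regime, "frozen_backbone")
  expect_equal(cfg$loss$aux_weight, 0.3)
  m <- strokevit_model(cfg$backbone, cfg$decoder, seed = 1)
  expect_s3_class(m, "strokevit_model")
})
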