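make_tiny_data <- function(n_train = 6, n_val = 2, size = 16L, seed = 41) {
  spec <- phantom_spec(n_volumes = 2, slices_per_volume = ceiling((n_train + n_val) / 2),
                       image_size = size, modality = "dwi_like",
                       lesions_range = c(1L, 2L), lesion_radius = c(2, 4),
                       seed = seed)
  slices <- slice_dataset(generate_dataset(spec), "eval")
  list(train = slices[seq_len(n_train)],
       val = slices[n_train + seq_len(n_val)])
}

test_that("the component ablation matrix instantiates and trains one step", {
  data <- make_tiny_data()
  for (backbone_trainable in c(TRUE, FALSE)) {
    for (adapters_on in c(TRUE, FALSE)) {
      for (attention_on in c(TRUE, FALSE)) {
        cfgb <- tiny_backbone(
          adapter_layers = if (adapters_on) c(1L, 2L) else integer(0))
        cfgd <- tiny_decoder(use_attention = attention_on)
        m <- strokevit_model(cfgb, cfgd, seed = 1)
        cfg <- train_config(
          epochs = 1, batch_size = 4, max_steps = 1, seed = 2,
          regime = if (backbone_trainable) "unfrozen" else "frozen_backbone")
        res <- train(m, data, cfg, policy = augment_policy(enabled = FALSE))
        expect_true(is.finite(res$history$train_loss[1]))
      }
    }
  }
})

test_that("training is reproducible at identical seeds", {
  data <- make_tiny_data()
  cfg <- train_config(epochs = 1, batch_size = 4, max_steps = 2, seed = 7)
  r1 <- train(tiny_model(seed = 5), data, cfg)
  r2 <- train(tiny_model(seed = 5), data, cfg)
  expect_identical(r1$history$train_loss, r2$history$train_loss)
  expect_identical(r1$final_model$params, r2$final_model$params)
})

test_that("frozen backbone stays bitwise unchanged while adapters move", {
  data <- make_tiny_data()
  m <- tiny_model(seed = 9)
  before_backbone <- m$params$backbone
  before_adapters <- m$params$adapters
  cfg <- train_config(epochs = 2, batch_size = 4, max_steps = 4, seed = 3,
                      regime = "frozen_backbone")
  res <- train(m, data, cfg, policy = augment_policy(enabled = FALSE))
  expect_identical(res$final_model$params$backbone, before_backbone)
  expect_false(identical(res$final_model$params$adapters, before_adapters))
  expect_false(identical(res$final_model$params$decoder, m$params$decoder))
})

test_that("unfrozen training moves backbone parameters", {
  data <- make_tiny_data()
  m <- tiny_model(seed = 10)
  cfg <- train_config(epochs = 1, batch_size = 4, max_steps = 2, seed = 3)
  res <- train(m, data, cfg, policy = augment_policy(enabled = FALSE))
  expect_false(identical(res$final_model$params$backbone, m$params$backbone))
})

test_that("learning rates never increase across epochs", {
  data <- make_tiny_data()
  cfg <- train_config(epochs = 6, batch_size = 4, plateau_patience = 1,
                      seed = 4)
  res <- train(tiny_model(seed = 11), data, cfg,
               policy = augment_policy(enabled = FALSE))
  lr <- res$history$lr_decoder
  expect_true(all(diff(lr) <= 1e-15))
})

test_that("volume prediction aligns, thresholds and repeats deterministically", {
  spec <- phantom_spec(n_volumes = 1, slices_per_volume = 4, image_size = 24,
                       lesions_range = c(1L, 2L), seed = 42)
  v <- generate_volume(spec, 1)
  m <- tiny_model(seed = 12)
  p1 <- predict_volume(m, v)
  expect_identical(dim(p1$mask), dim(v$image))
  expect_true(all(p1$mask %in% c(0, 1)))
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  p2 <- predict_volume(m, v)
  expect_identical(p1$mask, p2$mask)
  expect_identical(p1$prob, p2$prob)
})

test_that("checkpoints round-trip the full model", {
  m <- tiny_model(seed = 13)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "unit"))
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg, m$cfg)
  expect_identical(attr(m2, "extra")$note, "unit")
  img <- rand_image(16, seed = 14)
  expect_identical(predict_slices(m, list(img)), predict_slices(m2, list(img)))
})

test_that("external backbone weights import by name with shape checks", {
  m <- tiny_model(seed = 15)
  W <- matrix(1, nrow(m$params$backbone$W_patch), 8)
  m2 <- import_backbone_weights(m, list(patch_w = W),
                                c("W_patch" = "patch_w"))
  expect_identical(m2$params$backbone$W_patch, W)
  expect_error(import_backbone_weights(m, list(patch_w = W[, 1:2]),
                                       c("W_patch" = "patch_w")), "shape")
  expect_error(import_backbone_weights(m, list(), c("W_patch" = "nope")),
               "not found")
})
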