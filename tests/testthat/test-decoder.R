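test_that("multi-scale aggregation preserves shape and the residual path", {
  m <- tiny_model()
  tg <- encode(m, rand_image(16, seed = 1))
  fused <- multi_scale_aggregate(tg, m)
  expect_identical(dim(fused), dim(tg$grid))
  expect_true(all(is.finite(fused)))
  # zero branch + refine weights reduce the module to a passthrough
  m0 <- m
  for (nm in c("branch1", "branch3", "branch3d2", "branch3d4", "refine")) {
    m0$params$decoder[[nm]]$W[] <- 0
    m0$params$decoder[[nm]]$b[] <- 0
  }
  expect_equal(multi_scale_aggregate(tg, m0), tg$grid, tolerance = 1e-12)
})

test_that("dilated branch convolutions match the sliding-window oracle", {
  set.seed(21)
  for (rep in 1:6) {
    C <- sample(2:4, 1)
    x <- rand_chw(C, 6, 7)
    for (cfg in list(c(1, 1), c(3, 1), c(3, 2), c(3, 4))) {
      k <- cfg[1]; dil <- cfg[2]
      W <- matrix(rnorm(k * k * C * 2), k * k * C, 2)
      b <- rnorm(2)
      f <- strokevit:::chw_to_fmap(x)
      got <- strokevit:::fmap_to_chw(strokevit:::conv2d_fwd(f, W, b, k, dil)$y)
      expect_equal(got, oracle_conv2d(x, W, b, k, dil), tolerance = 1e-6)
    }
  }
})

test_that("channel attention matches the loop-based oracle", {
  set.seed(22)
  for (rep in 1:50) {
    C <- sample(2:6, 1)
    h <- sample(2:5, 1); w <- sample(2:5, 1)
    hid <- sample(1:4, 1)
    p <- list(W1 = matrix(rnorm(C * hid), C, hid), b1 = rnorm(hid),
              W2 = matrix(rnorm(hid * C), hid, C), b2 = rnorm(C))
    x <- rand_chw(C, h, w)
    expect_equal(channel_attention(x, p), oracle_channel_attention(x, p),
                 tolerance = 1e-6)
  }
})

test_that("channel attention weights stay inside (0,1)", {
  set.seed(23)
  C <- 4L
  p <- list(W1 = matrix(rnorm(8), 4, 2), b1 = rnorm(2),
            W2 = matrix(rnorm(8), 2, 4), b2 = numeric(4))
  # zero input with zero biases: sigmoid(0) = 0.5 everywhere
  p0 <- list(W1 = p$W1, b1 = numeric(2), W2 = p$W2, b2 = numeric(4))
  x0 <- array(0, c(4, 3, 3))
  expect_equal(channel_attention(x0, p0), x0)
  x <- rand_chw(4, 3, 3) * 10
  y <- channel_attention(x, p)
  ratio <- y / x
  expect_true(all(ratio > 0 & ratio < 1))
})

test_that("spatial attention matches the loop-based oracle", {
  set.seed(24)
  for (rep in 1:50) {
    C <- sample(2:5, 1)
    h <- sample(3:8, 1); w <- sample(3:8, 1)
    k <- sample(c(3, 7), 1)
    p <- list(W = matrix(rnorm(k * k * 2), k * k * 2, 1), b = rnorm(1))
    x <- rand_chw(C, h, w)
    expect_equal(spatial_attention(x, p, k), oracle_spatial_attention(x, p, k),
                 tolerance = 1e-6)
  }
})

test_that("spatial attention preserves shape and halves a zero input", {
  k <- 7L
  p <- list(W = matrix(0, k * k * 2, 1), b = 0)
  x <- rand_chw(3, 5, 5)
  y <- spatial_attention(x, p, k)
  expect_identical(dim(y), dim(x))
  expect_equal(y, x * 0.5)  # sigmoid(0) on every pixel
})

test_that("decoder follows the doubling shape chain with aux heads", {
  m <- tiny_model()  # patch 4 on 16x16 -> grid 4x4
  out <- strokevit:::model_fwd(m, list(rand_image(16, seed = 31)))
  expect_identical(c(out$main$h, out$main$w), c(16L, 16L))
  expect_setequal(names(out$aux), c("stage1", "stage2"))
  expect_identical(c(out$aux$stage1$h, out$aux$stage1$w), c(8L, 8L))
  expect_identical(c(out$aux$stage2$h, out$aux$stage2$w), c(16L, 16L))
})

test_that("aux heads and attention toggle off without changing shapes", {
  cfg_no_aux <- decoder_config(branch_channels = 4L,
                               stage_channels = c(8L, 8L, 4L, 4L),
                               attention_reduction = 2L, spatial_kernel = 3L,
                               aux_stages = integer(0))
  m1 <- strokevit_model(tiny_backbone(), cfg_no_aux, seed = 1)
  out1 <- strokevit:::model_fwd(m1, list(rand_image(16, seed = 32)))
  expect_length(out1$aux, 0)
  expect_identical(c(out1$main$h, out1$main$w), c(16L, 16L))
  cfg_no_attn <- decoder_config(branch_channels = 4L,
                                stage_channels = c(8L, 8L, 4L, 4L),
                                attention_reduction = 2L, spatial_kernel = 3L,
                                use_attention = FALSE)
  m2 <- strokevit_model(tiny_backbone(), cfg_no_attn, seed = 1)
  out2 <- strokevit:::model_fwd(m2, list(rand_image(16, seed = 33)))
  expect_identical(c(out2$main$h, out2$main$w), c(16L, 16L))
  expect_false("ca" %in% names(m2$params$decoder$stage1))
})

test_that("deep-supervision gradients reach the fused map from every head", {
  m <- tiny_model()
  out <- strokevit:::model_fwd(m, list(rand_image(16, seed = 34)),
                               training = TRUE)
  for (nm in names(out$aux)) {
    daux <- list()
    daux[[nm]] <- matrix(rnorm(nrow(out$aux[[nm]]$x)), ncol = 1)
    db <- strokevit:::decoder_bwd(matrix(0, nrow(out$main$x), 1), daux,
                                  out$cache$decoder, m)
    expect_gt(sqrt(sum(db$dgrid^2)), 0)
  }
})
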