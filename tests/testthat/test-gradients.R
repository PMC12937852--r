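# Backpropagation is validated against central finite differences through
# the entire network (encoder, adapters, decoder attention, batch norm,
# deep-supervised loss) on a miniature configuration.

test_that("analytic gradients match finite differences across the model", {
  set.seed(7)
  cfgb <- backbone_config(patch_size = 4L, embed_dim = 8L, depth = 2L,
                          num_heads = 2L, adapter_layers = 2L,
                          adapter_bottleneck = 3L, num_register_tokens = 2L,
                          img_size = 8L)
  cfgd <- decoder_config(branch_channels = 3L, stage_channels = c(6L, 5L, 4L, 3L),
                         attention_reduction = 2L, spatial_kernel = 3L)
  m <- strokevit_model(cfgb, cfgd, seed = 3)
  # push adapters off their identity init so that path carries gradient
  for (nm in names(m$params$adapters)) {
    m$params$adapters[[nm]]$W_up[] <-
      rnorm(length(m$params$adapters[[nm]]$W_up), sd = 0.05)
    m$params$adapters[[nm]]$b_up[] <-
      rnorm(length(m$params$adapters[[nm]]$b_up), sd = 0.05)
  }
  imgs <- list(array(rnorm(192), c(8, 8, 3)), array(rnorm(192), c(8, 8, 3)))
  msk <- matrix(rbinom(64, 1, 0.4), 8, 8)
  tgt <- matrix(rep(as.vector(t(msk)), 2), ncol = 1)
  lcfg <- loss_config()
  lossfn <- function(model) {
    out <- strokevit:::model_fwd(model, imgs, training = TRUE)
    strokevit:::total_loss_fmap(out$main, out$aux, tgt, lcfg)$total
  }
  out <- strokevit:::model_fwd(m, imgs, training = TRUE)
  lo <- strokevit:::total_loss_fmap(out$main, out$aux, tgt, lcfg)
  gr <- strokevit:::model_bwd(m, lo$dmain, lo$daux, out$cache)
  paths <- strokevit:::param_paths(m$params)
  set.seed(99)
  eps <- 1e-5
  # spot-check two random coordinates of every parameter tensor
  for (p in paths) {
    th <- pget_ <- strokevit:::pget(m$params, p)
    for (i in sample(length(th), min(2, length(th)))) {
      m2 <- m
      th2 <- th; th2[i] <- th[i] + eps
      m2$params <- strokevit:::pset(m2$params, p, th2)
      lp <- lossfn(m2)
      th2[i] <- th[i] - eps
      m2$params <- strokevit:::pset(m2$params, p, th2)
      lm <- lossfn(m2)
      num <- (lp - lm) / (2 * eps)
      ana <- strokevit:::pget(gr, p)[i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3,
                label = sprintf("gradient at %s[%d]",
                                paste(p, collapse = "/"), i))
    }
  }
})

test_that("bilinear resize backward is the exact adjoint of forward", {
  set.seed(31)
  f <- strokevit:::fmap(matrix(rnorm(2 * 5 * 4 * 3), 2 * 5 * 4, 3), 2L, 5L, 4L)
  fw <- strokevit:::resize_bilinear_fwd(f, 9L, 7L)
  u <- matrix(rnorm(length(fw$y$x)), nrow(fw$y$x), 3)
  bw <- strokevit:::resize_bilinear_bwd(u, fw$cache)
  # adjoint identity <R x, u> == <x, R* u>
  expect_equal(sum(fw$y$x * u), sum(f$x * bw), tolerance = 1e-9)
})

test_that("transpose convolution doubles resolution with exact gradients", {
  set.seed(32)
  f <- strokevit:::fmap(matrix(rnorm(12 * 2), 12, 2), 1L, 3L, 4L)
  W <- matrix(rnorm(2 * 4 * 3), 2, 12)
  b <- rnorm(3)
  fw <- strokevit:::tconv2x_fwd(f, W, b)
  expect_identical(c(fw$y$h, fw$y$w), c(6L, 8L))
  dy <- matrix(rnorm(48 * 3), 48, 3)
  bw <- strokevit:::tconv2x_bwd(dy, fw$cache, W)
  eps <- 1e-6
  for (i in sample(length(f$x), 5)) {
    f2 <- f; f2$x[i] <- f$x[i] + eps
    lp <- sum(strokevit:::tconv2x_fwd(f2, W, b)$y$x * dy)
    f2$x[i] <- f$x[i] - eps
    lm <- sum(strokevit:::tconv2x_fwd(f2, W, b)$y$x * dy)
    expect_equal((lp - lm) / (2 * eps), bw$dx[i], tolerance = 1e-6)
  }
})
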