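# ---------------------------------------------------------------------------
# Attention-enhanced multi-scale decoder.
#
# The token grid (embed_dim channels at 1/patch resolution) is first fused
# by four parallel convolution branches (1x1; 3x3; 3x3 dilation 2; 3x3
# dilation 4 -> branch_channels each), whose concatenation is refined by a
# 3x3 convolution with a residual connection back to the grid. Four
# upsampling stages then double the resolution each: 2x transpose
# convolution -> batch norm -> GELU -> channel attention -> spatial
# attention (serial, channel first). Auxiliary 1x1 classifiers on the
# configured stages provide deep supervision; the final head is a 3x3
# convolution, batch norm, GELU, 1x1 classifier, and a bilinear resize to
# the input size.
# ---------------------------------------------------------------------------

ca_hidden <- function(C, r) max(1L, min(C, max(C %/% r, 8L)))

build_decoder_params <- function(cfg, embed_dim) {
  D <- embed_dim
  bc <- cfg$branch_channels
  conv_p <- function(cin, cout, k) {
    list(W = mat_init(k * k * cin, cout), b = numeric(cout))
  }
  bn_p <- function(c) list(gamma = rep(1, c), beta = numeric(c))
  ca_p <- function(c) {
    h <- ca_hidden(c, cfg$attention_reduction)
    list(W1 = mat_init(c, h), b1 = numeric(h),
         W2 = mat_init(h, c), b2 = numeric(c))
  }
  sa_p <- function() conv_p(2L, 1L, cfg$spatial_kernel)
  params <- list(
    branch1 = conv_p(D, bc, 1L),
    branch3 = conv_p(D, bc, 3L),
    branch3d2 = conv_p(D, bc, 3L),
    branch3d4 = conv_p(D, bc, 3L),
    refine = conv_p(4L * bc, D, 3L),
    refine_bn = bn_p(D)
  )
  cin <- D
  for (i in 1:4) {
    cout <- cfg$stage_channels[i]
    st <- list(
      W_up = mat_init(cin, 4L * cout), b_up = numeric(cout),
      bn = bn_p(cout)
    )
    if (cfg$use_attention) {
      st$ca <- ca_p(cout)
      st$sa <- sa_p()
    }
    if (i %in% cfg$aux_stages) st$aux <- conv_p(cout, 1L, 1L)
    params[[paste0("stage", i)]] <- st
    cin <- cout
  }
  params$head <- conv_p(cin, cin, 3L)
  params$head_bn <- bn_p(cin)
  params$classifier <- conv_p(cin, 1L, 1L)
  params
}

build_decoder_state <- function(cfg, embed_dim) {
  bn_s <- function(c) list(mean = numeric(c), var = rep(1, c))
  st <- list(refine_bn = bn_s(embed_dim))
  for (i in 1:4) st[[paste0("stage", i)]] <- bn_s(cfg$stage_channels[i])
  st$head_bn <- bn_s(cfg$stage_channels[4])
  st
}

# ---- channel attention ----------------------------------------------------

ca_fwd <- function(f, p) {
  b <- f$b; hw <- f$h * f$w; C <- ncol(f$x)
  y <- f$x
  per <- vector("list", b)
  for (s in seq_len(b)) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    X <- f$x[rows, , drop = FALSE]
    avg <- colMeans(X)
    amax <- max.col(t(X), ties.method = "first")   # argmax row per channel
    vmax <- X[cbind(amax, seq_len(C))]
    h_a <- pmax(matrix(avg, 1L) %*% p$W1 + matrix(p$b1, 1L), 0)
    o_a <- h_a %*% p$W2 + matrix(p$b2, 1L)
    h_m <- pmax(matrix(vmax, 1L) %*% p$W1 + matrix(p$b1, 1L), 0)
    o_m <- h_m %*% p$W2 + matrix(p$b2, 1L)
    mc <- sigmoid(drop(o_a + o_m))
    y[rows, ] <- sweep(X, 2L, mc, "*")
    per[[s]] <- list(X = X, avg = avg, vmax = vmax, amax = amax,
                     h_a = drop(h_a), h_m = drop(h_m), mc = mc)
  }
  list(y = fmap(y, f$b, f$h, f$w), cache = list(per = per, hw = hw, C = C))
}

ca_bwd <- function(dy, cache, p) {
  C <- cache$C; hw <- cache$hw
  b <- length(cache$per)
  dx <- dy
  g <- list(W1 = p$W1 * 0, b1 = p$b1 * 0, W2 = p$W2 * 0, b2 = p$b2 * 0)
  for (s in seq_len(b)) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    pc <- cache$per[[s]]
    dYs <- dy[rows, , drop = FALSE]
    dx[rows, ] <- sweep(dYs, 2L, pc$mc, "*")
    dmc <- colSums(dYs * pc$X)
    ds <- dmc * pc$mc * (1 - pc$mc)          # through sigmoid
    # shared MLP, two input branches
    branch <- function(v, h) {
      dh <- drop(matrix(ds, 1L) %*% t(p$W2))
      dh[h <= 0] <- 0
      g$W2 <<- g$W2 + outer(h, ds)
      g$b2 <<- g$b2 + ds
      g$W1 <<- g$W1 + outer(v, dh)
      g$b1 <<- g$b1 + dh
      drop(matrix(dh, 1L) %*% t(p$W1))       # dv
    }
    dv_a <- branch(pc$avg, pc$h_a)
    dv_m <- branch(pc$vmax, pc$h_m)
    dx[rows, ] <- sweep(dx[rows, , drop = FALSE], 2L, dv_a / hw, "+")
    idx <- cbind(rows[pc$amax], seq_len(C))
    dx[idx] <- dx[idx] + dv_m
  }
  list(dx = dx, grads = g)
}

# ---- spatial attention ----------------------------------------------------

sa_fwd <- function(f, p, k) {
  C <- ncol(f$x)
  mu <- rowMeans(f$x)
  amax <- max.col(f$x, ties.method = "first")
  mx <- f$x[cbind(seq_len(nrow(f$x)), amax)]
  stats <- fmap(cbind(mu, mx), f$b, f$h, f$w)
  cv <- conv2d_fwd(stats, p$W, p$b, k)
  ms <- sigmoid(cv$y$x[, 1])
  y <- f$x * ms
  list(y = fmap(y, f$b, f$h, f$w),
       cache = list(f = f, amax = amax, cv = cv$cache, ms = ms, C = C))
}

sa_bwd <- function(dy, cache, p) {
  ms <- cache$ms
  X <- cache$f$x
  dx <- dy * ms
  dz <- rowSums(dy * X) * ms * (1 - ms)
  cb <- conv2d_bwd(matrix(dz, ncol = 1L), cache$cv, p$W)
  dstats <- cb$dx
  dx <- dx + dstats[, 1] / cache$C
  idx <- cbind(seq_len(nrow(X)), cache$amax)
  dx[idx] <- dx[idx] + dstats[, 2]
  list(dx = dx, grads = list(W = cb$dW, b = cb$db))
}

# ---- exported single-sample wrappers (oracle surface) ----------------------

#' Channel attention on a single feature map
#'
#' Global average and maximum pooling over space each produce a C-vector;
#' one shared two-layer MLP (C -> C/r -> C, ReLU between) processes both,
#' and the sigmoid of the summed outputs gives per-channel weights in
#' (0,1) that rescale the input.
#'
#' @param x array of dim (C, H, W)
#' @param params list with `W1` (C x hidden), `b1`, `W2` (hidden x C), `b2`
#' @return array of dim (C, H, W)
#' @export
channel_attention <- function(x, params) {
  f <- chw_to_fmap(x)
  out <- ca_fwd(f, params)$y
  fmap_to_chw(out)
}

#' Spatial attention on a single feature map
#'
#' The channel-wise mean and maximum maps are concatenated to a 2-channel
#' map, convolved with a same-padded k x k kernel, and passed through a
#' sigmoid; the resulting (0,1) map rescales every channel.
#'
#' @param x array of dim (C, H, W)
#' @param params list with `W` ((k*k*2) x 1) and `b` (length 1)
#' @param kernel odd kernel size (default 7)
#' @return array of dim (C, H, W)
#' @export
spatial_attention <- function(x, params, kernel = 7L) {
  f <- chw_to_fmap(x)
  out <- sa_fwd(f, params, kernel)$y
  fmap_to_chw(out)
}

chw_to_fmap <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  C <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  m <- matrix(0, h * w, C)
  for (c in seq_len(C)) m[, c] <- as.vector(t(x[c, , ]))
  fmap(m, 1L, h, w)
}

fmap_to_chw <- function(f) {
  C <- ncol(f$x)
  out <- array(0, c(C, f$h, f$w))
  for (c in seq_len(C)) out[c, , ] <- matrix(f$x[, c], f$h, f$w, byrow = TRUE)
  out
}

# ---- multi-scale aggregation ----------------------------------------------

msa_fwd <- function(f, dp) {
  b1 <- conv2d_fwd(f, dp$branch1$W, dp$branch1$b, 1L)
  b3 <- conv2d_fwd(f, dp$branch3$W, dp$branch3$b, 3L)
  b32 <- conv2d_fwd(f, dp$branch3d2$W, dp$branch3d2$b, 3L, dil = 2L)
  b34 <- conv2d_fwd(f, dp$branch3d4$W, dp$branch3d4$b, 3L, dil = 4L)
  cat <- fmap(cbind(b1$y$x, b3$y$x, b32$y$x, b34$y$x), f$b, f$h, f$w)
  rf <- conv2d_fwd(cat, dp$refine$W, dp$refine$b, 3L)
  list(y = rf, cat = cat, branches = list(b1, b3, b32, b34))
}

#' Multi-scale aggregation of a token grid
#'
#' Four parallel convolution branches (1x1; 3x3; 3x3 dilation 2; 3x3
#' dilation 4), each embed_dim -> branch_channels with spatial size
#' preserved, concatenated and refined by a 3x3 convolution (batch norm +
#' GELU) with a residual connection adding the input grid.
#'
#' @param grid a `token_grid` from [encode()] or an array (C, h, w)
#' @param model a [strokevit_model()]
#' @return array (C, h, w), the fused map
#' @export
multi_scale_aggregate <- function(grid, model) {
  x <- if (inherits(grid, "token_grid")) grid$grid else grid
  f <- chw_to_fmap(x)
  dp <- model$params$decoder
  if (nrow(dp$branch1$W) != ncol(f$x)) {
    stop(sprintf("fused-map residual expects %d channels, grid has %d",
                 nrow(dp$branch1$W), ncol(f$x)), call. = FALSE)
  }
  ms <- msa_fwd(f, dp)
  bn <- batchnorm_fwd(ms$y$y, dp$refine_bn$gamma, dp$refine_bn$beta,
                      model$state$decoder$refine_bn, training = FALSE)
  fused <- fmap(f$x + gelu(bn$y$x), f$b, f$h, f$w)
  fmap_to_chw(fused)
}

# ---- full decoder ---------------------------------------------------------

decoder_fwd <- function(model, grid_f, out_h, out_w, training = FALSE) {
  cfg <- model$cfg$decoder
  dp <- model$params$decoder
  st <- model$state$decoder
  if (out_h %% grid_f$h != 0L || out_w %% grid_f$w != 0L) {
    stop(sprintf(
      "fused map %dx%d is not an integer downscale of output %dx%d",
      grid_f$h, grid_f$w, out_h, out_w), call. = FALSE)
  }
  cache <- list(grid = grid_f)
  ms <- msa_fwd(grid_f, dp)
  bn0 <- batchnorm_fwd(ms$y$y, dp$refine_bn$gamma, dp$refine_bn$beta,
                       st$refine_bn, training)
  st$refine_bn <- bn0$state
  act0 <- gelu(bn0$y$x)
  fused <- fmap(grid_f$x + act0, grid_f$b, grid_f$h, grid_f$w)
  cache$ms <- ms; cache$bn0 <- bn0$cache; cache$bn0pre <- bn0$y$x
  x <- fused
  aux <- list()
  stages <- vector("list", 4L)
  for (i in 1:4) {
    sp <- dp[[paste0("stage", i)]]
    sc <- list()
    up <- tconv2x_fwd(x, sp$W_up, sp$b_up)
    bn <- batchnorm_fwd(up$y, sp$bn$gamma, sp$bn$beta,
                        st[[paste0("stage", i)]], training)
    st[[paste0("stage", i)]] <- bn$state
    a <- gelu(bn$y$x)
    x <- fmap(a, up$y$b, up$y$h, up$y$w)
    sc$up <- up$cache; sc$bn <- bn$cache; sc$bnpre <- bn$y$x
    if (cfg$use_attention) {
      caf <- ca_fwd(x, sp$ca)
      saf <- sa_fwd(caf$y, sp$sa, cfg$spatial_kernel)
      x <- saf$y
      sc$ca <- caf$cache; sc$sa <- saf$cache
    }
    if (i %in% cfg$aux_stages) {
      ax <- conv2d_fwd(x, sp$aux$W, sp$aux$b, 1L)
      aux[[paste0("stage", i)]] <- ax$y
      sc$aux <- ax$cache
    }
    stages[[i]] <- sc
    cache[[paste0("x", i)]] <- x
  }
  hd <- conv2d_fwd(x, dp$head$W, dp$head$b, 3L)
  bnh <- batchnorm_fwd(hd$y, dp$head_bn$gamma, dp$head_bn$beta,
                       st$head_bn, training)
  st$head_bn <- bnh$state
  ah <- gelu(bnh$y$x)
  hf <- fmap(ah, x$b, x$h, x$w)
  cl <- conv2d_fwd(hf, dp$classifier$W, dp$classifier$b, 1L)
  rs <- resize_bilinear_fwd(cl$y, out_h, out_w)
  cache$stages <- stages
  cache$head <- hd$cache; cache$bnh <- bnh$cache; cache$bnhpre <- bnh$y$x
  cache$hf <- hf; cache$cl <- cl$cache; cache$rs <- rs$cache
  list(main = rs$y, aux = aux, cache = cache, state = st)
}

decoder_bwd <- function(dmain, daux, cache, model) {
  cfg <- model$cfg$decoder
  dp <- model$params$decoder
  g <- list()
  dy <- resize_bilinear_bwd(dmain, cache$rs)
  cb <- conv2d_bwd(dy, cache$cl, dp$classifier$W)
  g$classifier <- list(W = cb$dW, b = cb$db)
  dah <- cb$dx * gelu_grad(cache$bnhpre)
  bnb <- batchnorm_bwd(dah, cache$bnh)
  g$head_bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  hb <- conv2d_bwd(bnb$dx, cache$head, dp$head$W)
  g$head <- list(W = hb$dW, b = hb$db)
  dx <- hb$dx
  for (i in 4:1) {
    sp <- dp[[paste0("stage", i)]]
    sc <- cache$stages[[i]]
    gs <- list()
    if (i %in% cfg$aux_stages) {
      da <- daux[[paste0("stage", i)]]
      if (!is.null(da)) {
        axb <- conv2d_bwd(da, sc$aux, sp$aux$W)
        gs$aux <- list(W = axb$dW, b = axb$db)
        dx <- dx + axb$dx
      } else {
        gs$aux <- list(W = sp$aux$W * 0, b = sp$aux$b * 0)
      }
    }
    if (cfg$use_attention) {
      sab <- sa_bwd(dx, sc$sa, sp$sa)
      gs$sa <- sab$grads
      cab <- ca_bwd(sab$dx, sc$ca, sp$ca)
      gs$ca <- cab$grads
      dx <- cab$dx
    }
    da <- dx * gelu_grad(sc$bnpre)
    bnb <- batchnorm_bwd(da, sc$bn)
    gs$bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    ub <- tconv2x_bwd(bnb$dx, sc$up, sp$W_up)
    gs$W_up <- ub$dW; gs$b_up <- ub$db
    dx <- ub$dx
    g[[paste0("stage", i)]] <- gs
  }
  # residual: dfused goes both into the refine path and straight to the grid
  da0 <- dx * gelu_grad(cache$bn0pre)
  bnb0 <- batchnorm_bwd(da0, cache$bn0)
  g$refine_bn <- list(gamma = bnb0$dgamma, beta = bnb0$dbeta)
  rb <- conv2d_bwd(bnb0$dx, cache$ms$y$cache, dp$refine$W)
  g$refine <- list(W = rb$dW, b = rb$db)
  dcat <- rb$dx
  bc <- ncol(dp$branch1$W)
  dgrid <- dx
  brn <- c("branch1", "branch3", "branch3d2", "branch3d4")
  for (j in 1:4) {
    cols <- ((j - 1L) * bc + 1L):(j * bc)
    bb <- conv2d_bwd(dcat[, cols, drop = FALSE],
                     cache$ms$branches[[j]]$cache, dp[[brn[j]]]$W)
    g[[brn[j]]] <- list(W = bb$dW, b = bb$db)
    dgrid <- dgrid + bb$dx
  }
  list(dgrid = dgrid, grads = g)
}
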