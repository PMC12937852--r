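# ---------------------------------------------------------------------------
# Vision-transformer encoder.
#
# Pre-norm ViT: each block is x + Attn(LN(x)) followed by x + MLP(LN(x)),
# with a final layer norm after the last block. A class token and an
# optional set of register tokens travel through the encoder but are
# discarded before decoding; only patch tokens form the spatial grid.
# Bottleneck adapters are applied token-wise to the output of selected
# blocks (after the second residual), the common sequential-adapter
# convention.
# ---------------------------------------------------------------------------

build_backbone_params <- function(cfg) {
  D <- cfg$embed_dim
  p <- cfg$patch_size
  g0 <- cfg$img_size %/% p
  mlp_dim <- as.integer(round(D * cfg$mlp_ratio))
  blocks <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    blocks[[i]] <- list(
      ln1_g = rep(1, D), ln1_b = numeric(D),
      Wqkv = mat_init(D, 3L * D), bqkv = numeric(3L * D),
      Wproj = mat_init(D, D), bproj = numeric(D),
      ln2_g = rep(1, D), ln2_b = numeric(D),
      Wmlp1 = mat_init(D, mlp_dim), bmlp1 = numeric(mlp_dim),
      Wmlp2 = mat_init(mlp_dim, D), bmlp2 = numeric(D)
    )
  }
  names(blocks) <- paste0("block", seq_len(cfg$depth))
  params <- list(
    W_patch = mat_init(3L * p * p, D), b_patch = numeric(D),
    pos_patch = mat_init(g0 * g0, D),
    cls = mat_init(1L, D),
    lnf_g = rep(1, D), lnf_b = numeric(D)
  )
  if (cfg$num_register_tokens > 0L) {
    params$reg <- mat_init(cfg$num_register_tokens, D)
  }
  c(params, blocks)
}

build_adapter_params <- function(cfg) {
  if (!length(cfg$adapter_layers)) return(list())
  out <- lapply(cfg$adapter_layers, function(i) {
    adapter_init(cfg$embed_dim, cfg$adapter_bottleneck)
  })
  names(out) <- paste0("layer", cfg$adapter_layers)
  out
}

#' Tokenize one slice into the transformer input sequence
#'
#' Splits the image into non-overlapping `patch_size` squares (row-major
#' grid order), flattens and linearly projects each into an
#' `embed_dim`-dimensional token, adds learned positional embeddings
#' (bilinearly resampled when the grid differs from the configured
#' `img_size` grid), and prepends the class and register tokens.
#'
#' @param image array of dim (H, W, 3), normalized
#' @param model a [strokevit_model()]
#' @return token matrix ((1 + registers + h*w) x embed_dim) with attributes
#'   `n_special` and `grid` (c(h, w))
#' @export
patchify <- function(image, model) {
  cfg <- model$cfg$backbone
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  if (dim(image)[3] == 1L) image <- image[, , c(1L, 1L, 1L), drop = FALSE]
  H <- dim(image)[1]; W <- dim(image)[2]
  p <- cfg$patch_size
  if (H %% p != 0L) {
    stop(sprintf("input height %d is not divisible by patch_size %d", H, p),
         call. = FALSE)
  }
  if (W %% p != 0L) {
    stop(sprintf("input width %d is not divisible by patch_size %d", W, p),
         call. = FALSE)
  }
  gh <- H %/% p; gw <- W %/% p
  np <- gh * gw
  # gather patch pixels: columns ordered channel-major then row-major taps,
  # matching the W_patch layout (3*p*p rows)
  X <- matrix(0, np, 3L * p * p)
  pi0 <- rep((seq_len(gh) - 1L) * p, each = gw)   # row offset per patch
  pj0 <- rep((seq_len(gw) - 1L) * p, times = gh)  # col offset per patch
  col <- 0L
  for (c in 1:3) {
    for (di in seq_len(p)) {
      for (dj in seq_len(p)) {
        col <- col + 1L
        X[, col] <- image[cbind(pi0 + di, pj0 + dj, c)]
      }
    }
  }
  bp <- model$params$backbone
  tok <- sweep(X %*% bp$W_patch, 2L, bp$b_patch, "+")
  tok <- tok + resample_pos(bp$pos_patch, cfg$img_size %/% p, gh, gw)
  special <- bp$cls
  if (cfg$num_register_tokens > 0L) special <- rbind(special, bp$reg)
  out <- rbind(special, tok)
  attr(out, "n_special") <- nrow(special)
  attr(out, "grid") <- c(gh, gw)
  out
}

# learned positional grid (g0 x g0) resampled to (gh x gw)
resample_pos <- function(pos, g0, gh, gw) {
  if (gh == g0 && gw == g0) return(pos)
  f <- fmap(pos, 1L, g0, g0)
  resize_bilinear_fwd(f, gh, gw)$y$x
}

attn_fwd <- function(x, blk, n, b, num_heads) {
  D <- ncol(x)
  dh <- D %/% num_heads
  qkv <- sweep(x %*% blk$Wqkv, 2L, blk$bqkv, "+")
  y <- matrix(0, nrow(x), D)
  per <- vector("list", b)
  scale <- 1 / sqrt(dh)
  for (s in seq_len(b)) {
    rows <- ((s - 1L) * n + 1L):(s * n)
    heads <- vector("list", num_heads)
    for (h in seq_len(num_heads)) {
      cq <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- qkv[rows, cq, drop = FALSE]
      K <- qkv[rows, D + cq, drop = FALSE]
      V <- qkv[rows, 2L * D + cq, drop = FALSE]
      A <- softmax_rows(tcrossprod(Q, K) * scale)
      y[rows, cq] <- A %*% V
      heads[[h]] <- list(A = A, Q = Q, K = K, V = V)
    }
    per[[s]] <- heads
  }
  proj <- linear_fwd(y, blk$Wproj, blk$bproj)
  list(y = proj$y,
       cache = list(x = x, qkv = qkv, concat = y, per = per, n = n, b = b,
                    num_heads = num_heads, scale = scale))
}

attn_bwd <- function(dy, cache, blk) {
  D <- ncol(cache$x)
  dh <- D %/% cache$num_heads
  pb <- linear_bwd(dy, cache$concat, blk$Wproj)
  dconcat <- pb$dx
  dqkv <- matrix(0, nrow(cache$x), 3L * D)
  for (s in seq_len(cache$b)) {
    rows <- ((s - 1L) * cache$n + 1L):(s * cache$n)
    for (h in seq_len(cache$num_heads)) {
      cq <- ((h - 1L) * dh + 1L):(h * dh)
      hc <- cache$per[[s]][[h]]
      dO <- dconcat[rows, cq, drop = FALSE]
      dA <- tcrossprod(dO, hc$V)
      dV <- crossprod(hc$A, dO)
      dS <- softmax_rows_bwd(dA, hc$A) * cache$scale
      dQ <- dS %*% hc$K
      dK <- crossprod(dS, hc$Q)
      dqkv[rows, cq] <- dQ
      dqkv[rows, D + cq] <- dK
      dqkv[rows, 2L * D + cq] <- dV
    }
  }
  list(dx = dqkv %*% t(blk$Wqkv),
       dWqkv = crossprod(cache$x, dqkv), dbqkv = colSums(dqkv),
       dWproj = pb$dW, dbproj = pb$db)
}

block_fwd <- function(x, blk, n, b, num_heads) {
  ln1 <- layernorm_fwd(x, blk$ln1_g, blk$ln1_b)
  at <- attn_fwd(ln1$y, blk, n, b, num_heads)
  x1 <- x + at$y
  ln2 <- layernorm_fwd(x1, blk$ln2_g, blk$ln2_b)
  m1 <- linear_fwd(ln2$y, blk$Wmlp1, blk$bmlp1)
  act <- gelu(m1$y)
  m2 <- linear_fwd(act, blk$Wmlp2, blk$bmlp2)
  list(y = x1 + m2$y,
       cache = list(ln1 = ln1$cache, at = at$cache, ln2 = ln2$cache,
                    m1 = m1, act = act, m2cache = act, pre = m1$y))
}

block_bwd <- function(dy, cache, blk) {
  g <- list()
  m2b <- linear_bwd(dy, cache$act, blk$Wmlp2)
  dact <- m2b$dx * gelu_grad(cache$pre)
  m1b <- linear_bwd(dact, cache$m1$cache, blk$Wmlp1)
  ln2b <- layernorm_bwd(m1b$dx, cache$ln2)
  dx1 <- dy + ln2b$dx
  ab <- attn_bwd(dx1, cache$at, blk)
  ln1b <- layernorm_bwd(ab$dx, cache$ln1)
  dx <- dx1 + ln1b$dx
  g$ln1_g <- ln1b$dgamma; g$ln1_b <- ln1b$dbeta
  g$Wqkv <- ab$dWqkv; g$bqkv <- ab$dbqkv
  g$Wproj <- ab$dWproj; g$bproj <- ab$dbproj
  g$ln2_g <- ln2b$dgamma; g$ln2_b <- ln2b$dbeta
  g$Wmlp1 <- m1b$dW; g$bmlp1 <- m1b$db
  g$Wmlp2 <- m2b$dW; g$bmlp2 <- m2b$db
  list(dx = dx, grads = g)
}

# Forward pass of the encoder on a batch of images (list of (H,W,3) arrays).
# Returns the patch-token grid as a batched fmap plus caches for backward.
backbone_fwd <- function(model, images, keep_cache = FALSE) {
  cfg <- model$cfg$backbone
  b <- length(images)
  toks <- lapply(images, patchify, model = model)
  ns <- attr(toks[[1]], "n_special")
  grid <- attr(toks[[1]], "grid")
  n <- nrow(toks[[1]])
  x <- do.call(rbind, toks)
  caches <- if (keep_cache) vector("list", cfg$depth) else NULL
  acaches <- if (keep_cache) list() else NULL
  bp <- model$params$backbone
  for (i in seq_len(cfg$depth)) {
    bf <- block_fwd(x, bp[[paste0("block", i)]], n, b, cfg$num_heads)
    x <- bf$y
    if (!all(is.finite(x))) {
      stop(sprintf("non-finite encoder activations after block %d", i),
           call. = FALSE)
    }
    if (keep_cache) caches[[i]] <- bf$cache
    key <- paste0("layer", i)
    if (i %in% cfg$adapter_layers) {
      af <- adapter_fwd(x, model$params$adapters[[key]])
      x <- af$y
      if (keep_cache) acaches[[key]] <- af$cache
    }
  }
  lnf <- layernorm_fwd(x, bp$lnf_g, bp$lnf_b)
  x <- lnf$y
  # drop class/register tokens: keep rows ns+1..n of every sample
  keep <- as.vector(vapply(seq_len(b), function(s) {
    ((s - 1L) * n + ns + 1L):((s - 1L) * n + n)
  }, integer(n - ns)))
  gridmap <- fmap(x[keep, , drop = FALSE], b, grid[1], grid[2])
  list(grid = gridmap,
       cache = if (keep_cache) list(blocks = caches, adapters = acaches,
                                    lnf = lnf$cache, keep = keep, n = n,
                                    ns = ns, b = b, ntok = nrow(x),
                                    toks = toks, images = images) else NULL)
}

backbone_bwd <- function(dgrid, cache, model) {
  cfg <- model$cfg$backbone
  bp <- model$params$backbone
  D <- cfg$embed_dim
  dx <- matrix(0, cache$ntok, D)
  dx[cache$keep, ] <- dgrid
  lnb <- layernorm_bwd(dx, cache$lnf)
  dx <- lnb$dx
  g <- list(lnf_g = lnb$dgamma, lnf_b = lnb$dbeta)
  ga <- list()
  for (i in rev(seq_len(cfg$depth))) {
    key <- paste0("layer", i)
    if (i %in% cfg$adapter_layers) {
      ab <- adapter_bwd(dx, cache$adapters[[key]],
                        model$params$adapters[[key]])
      dx <- ab$dx
      ga[[key]] <- ab$grads
    }
    bb <- block_bwd(dx, cache$blocks[[i]], bp[[paste0("block", i)]])
    dx <- bb$dx
    g[[paste0("block", i)]] <- bb$grads
  }
  # token-level gradients back to embeddings
  b <- cache$b; n <- cache$n; ns <- cache$ns
  grid <- attr(cache$toks[[1]], "grid")
  g$cls <- matrix(0, 1L, D)
  if (cfg$num_register_tokens > 0L) {
    g$reg <- matrix(0, cfg$num_register_tokens, D)
  }
  g0 <- cfg$img_size %/% cfg$patch_size
  dpos_native <- matrix(0, grid[1] * grid[2], D)
  dW_patch <- matrix(0, nrow(bp$W_patch), D)
  db_patch <- numeric(D)
  for (s in seq_len(b)) {
    rows <- ((s - 1L) * n + 1L):(s * n)
    dtok <- dx[rows, , drop = FALSE]
    g$cls <- g$cls + dtok[1L, , drop = FALSE]
    if (cfg$num_register_tokens > 0L && ns > 1L) {
      g$reg <- g$reg + dtok[2:ns, , drop = FALSE]
    }
    dpatch <- dtok[(ns + 1L):n, , drop = FALSE]
    dpos_native <- dpos_native + dpatch
    X <- patch_pixels(cache$images[[s]], cfg$patch_size)
    dW_patch <- dW_patch + crossprod(X, dpatch)
    db_patch <- db_patch + colSums(dpatch)
  }
  if (grid[1] == g0 && grid[2] == g0) {
    g$pos_patch <- dpos_native
  } else {
    rp <- resize_bilinear_fwd(fmap(bp$pos_patch, 1L, g0, g0),
                              grid[1], grid[2])
    g$pos_patch <- resize_bilinear_bwd(dpos_native, rp$cache)
  }
  g$W_patch <- dW_patch
  g$b_patch <- db_patch
  list(backbone = g, adapters = ga)
}

# raw flattened patch-pixel matrix (np x 3*p*p), same layout as patchify
patch_pixels <- function(image, p) {
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  if (dim(image)[3] == 1L) image <- image[, , c(1L, 1L, 1L), drop = FALSE]
  H <- dim(image)[1]; W <- dim(image)[2]
  gh <- H %/% p; gw <- W %/% p
  X <- matrix(0, gh * gw, 3L * p * p)
  pi0 <- rep((seq_len(gh) - 1L) * p, each = gw)
  pj0 <- rep((seq_len(gw) - 1L) * p, times = gh)
  col <- 0L
  for (c in 1:3) {
    for (di in seq_len(p)) {
      for (dj in seq_len(p)) {
        col <- col + 1L
        X[, col] <- image[cbind(pi0 + di, pj0 + dj, c)]
      }
    }
  }
  X
}

#' Encode one slice into its spatial token grid
#'
#' Runs the full encoder (all transformer blocks, adapters after the
#' configured blocks, final layer norm), discards the class and register
#' tokens and reshapes the patch tokens row-major into a spatial grid.
#'
#' @param model a [strokevit_model()]
#' @param image array (H, W, 3) or (H, W); H and W must be divisible by
#'   the configured patch size
#' @return object of class `token_grid`: list with `grid` (array of dim
#'   (embed_dim, h, w)), and `input_size` c(H, W)
#' @export
encode <- function(model, image) {
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- backbone_fwd(model, list(image))
  f <- out$grid
  D <- ncol(f$x)
  grid <- array(0, c(D, f$h, f$w))
  for (d in seq_len(D)) grid[d, , ] <- matrix(f$x[, d], f$h, f$w, byrow = TRUE)
  structure(list(grid = grid, input_size = c(H, W)), class = "token_grid")
}

#' Flatten a token grid back to the row-major patch-token sequence
#' @param tg a `token_grid`
#' @return matrix (h*w x embed_dim)
#' @export
token_grid_tokens <- function(tg) {
  d <- dim(tg$grid)
  out <- matrix(0, d[2] * d[3], d[1])
  for (k in seq_len(d[1])) out[, k] <- as.vector(t(tg$grid[k, , ]))
  out
}

#' Optimizer parameter groups with hierarchical learning rates
#'
#' Partitions every trainable parameter into three disjoint groups --
#' encoder backbone, adapters, decoder -- each with its own learning rate.
#' Under the frozen-backbone regime the backbone group is dropped from
#' optimization entirely.
#'
#' @param model a [strokevit_model()]
#' @param lr_backbone,lr_adapters,lr_decoder group learning rates
#' @param freeze_backbone drop the backbone group (defaults to the model's
#'   backbone configuration flag)
#' @return named list of groups, each `list(name, paths, lr)` where `paths`
#'   are parameter paths into `model$params`
#' @export
parameter_groups <- function(model, lr_backbone = 1e-5, lr_adapters = 1e-4,
                             lr_decoder = 1e-4,
                             freeze_backbone =
                               model$cfg$backbone$freeze_backbone) {
  groups <- list()
  if (!freeze_backbone) {
    groups$backbone <- list(
      name = "backbone", lr = lr_backbone,
      paths = lapply(param_paths(model$params$backbone),
                     function(p) c("backbone", p)))
  }
  if (length(model$params$adapters)) {
    groups$adapters <- list(
      name = "adapters", lr = lr_adapters,
      paths = lapply(param_paths(model$params$adapters),
                     function(p) c("adapters", p)))
  }
  groups$decoder <- list(
    name = "decoder", lr = lr_decoder,
    paths = lapply(param_paths(model$params$decoder),
                   function(p) c("decoder", p)))
  all_paths <- unlist(lapply(groups, function(g) {
    vapply(g$paths, paste, character(1), collapse = "/")
  }), use.names = FALSE)
  if (anyDuplicated(all_paths)) {
    stop(sprintf("parameter assigned to two groups: %s",
                 all_paths[duplicated(all_paths)][1]), call. = FALSE)
  }
  trainable <- vapply(param_paths(model$params), paste, character(1),
                      collapse = "/")
  if (freeze_backbone) {
    trainable <- trainable[!startsWith(trainable, "backbone/")]
  }
  missing <- setdiff(trainable, all_paths)
  if (length(missing)) {
    stop(sprintf("parameter in no group: %s", missing[1]), call. = FALSE)
  }
  groups
}
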