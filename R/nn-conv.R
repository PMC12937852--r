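# ---------------------------------------------------------------------------
# Spatial primitives on batched feature maps.
#
# A feature map ("fmap") is list(x, b, h, w): x is a (b*h*w) x C matrix whose
# rows enumerate pixels row-major within each sample, samples stacked. This
# keeps every convolution an im2col gather followed by one BLAS matmul, which
# is the only way a pure-R network stays fast enough for desk-scale training.
# ---------------------------------------------------------------------------

fmap <- function(x, b, h, w) {
  stopifnot(nrow(x) == b * h * w)
  list(x = x, b = b, h = h, w = w)
}

#' Convert an h x w matrix (or h x w x C array) to a single-sample fmap
#' @keywords internal
as_fmap <- function(m) {
  if (is.matrix(m)) m <- array(m, c(dim(m), 1L))
  h <- dim(m)[1]; w <- dim(m)[2]; C <- dim(m)[3]
  x <- matrix(0, h * w, C)
  for (c in seq_len(C)) x[, c] <- as.vector(t(m[, , c]))
  fmap(x, 1L, h, w)
}

#' Convert a single-sample fmap back to an h x w x C array
#' @keywords internal
fmap_to_array <- function(f) {
  stopifnot(f$b == 1L)
  C <- ncol(f$x)
  a <- array(0, c(f$h, f$w, C))
  for (c in seq_len(C)) a[, , c] <- matrix(f$x[, c], f$h, f$w, byrow = TRUE)
  a
}

.idx_cache <- new.env(parent = emptyenv())

# Row indices (into the unbatched h*w map, NA = outside) gathered for each of
# the k*k taps of a dilated "same" convolution.
conv_taps <- function(h, w, k, dil) {
  key <- paste("c", h, w, k, dil, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- (k - 1L) %/% 2L
  ii <- rep(seq_len(h), each = w)
  jj <- rep(seq_len(w), times = h)
  idx <- matrix(NA_integer_, h * w, k * k)
  t <- 0L
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      t <- t + 1L
      si <- ii + (a - 1L - half) * dil
      sj <- jj + (b - 1L - half) * dil
      ok <- si >= 1L & si <= h & sj >= 1L & sj <= w
      v <- rep(NA_integer_, h * w)
      v[ok] <- (si[ok] - 1L) * w + sj[ok]
      idx[, t] <- v
    }
  }
  .idx_cache[[key]] <- idx
  idx
}

# Batched tap indices pointing into rbind(x, 0): out-of-image taps hit the
# appended zero row.
conv_taps_batched <- function(b, h, w, k, dil) {
  key <- paste("cb", b, h, w, k, dil, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- conv_taps(h, w, k, dil)
  n <- b * h * w
  zrow <- n + 1L
  out <- matrix(zrow, n, ncol(idx))
  hw <- h * w
  for (s in seq_len(b)) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    shifted <- idx + (s - 1L) * hw
    shifted[is.na(idx)] <- zrow
    out[rows, ] <- shifted
  }
  .idx_cache[[key]] <- out
  out
}

#' Same-padding 2D convolution (stride 1, square kernel, optional dilation)
#'
#' Weight layout: `W` is (k*k*Cin) x Cout with tap-major rows — tap t of the
#' row-major kernel occupies rows ((t-1)*Cin+1):(t*Cin).
#' @keywords internal
conv2d_fwd <- function(f, W, bias, k, dil = 1L) {
  C <- ncol(f$x)
  stopifnot(nrow(W) == k * k * C)
  if (k == 1L) {
    y <- f$x %*% W
    y <- sweep(y, 2L, bias, "+")
    return(list(y = fmap(y, f$b, f$h, f$w),
                cache = list(xcol = f$x, k = 1L, dil = dil, f = f)))
  }
  bidx <- conv_taps_batched(f$b, f$h, f$w, k, dil)
  xpad <- rbind(f$x, 0)
  taps <- vector("list", k * k)
  for (t in seq_len(k * k)) taps[[t]] <- xpad[bidx[, t], , drop = FALSE]
  xcol <- do.call(cbind, taps)
  y <- xcol %*% W
  y <- sweep(y, 2L, bias, "+")
  list(y = fmap(y, f$b, f$h, f$w),
       cache = list(xcol = xcol, bidx = bidx, k = k, dil = dil, f = f))
}

conv2d_bwd <- function(dy, cache, W) {
  k <- cache$k
  db <- colSums(dy)
  dW <- crossprod(cache$xcol, dy)
  if (k == 1L) {
    return(list(dx = dy %*% t(W), dW = dW, db = db))
  }
  f <- cache$f
  C <- ncol(f$x)
  n <- nrow(f$x)
  dxcol <- dy %*% t(W)
  # scatter adjoint of a stride-1 same-padding gather is a gather with the
  # mirrored tap offset, so the forward index table is reused directly
  dx <- matrix(0, n, C)
  zero <- matrix(0, 1L, C)
  for (t in seq_len(k * k)) {
    a <- (t - 1L) %/% k + 1L
    b <- (t - 1L) %% k + 1L
    tm <- (k - a) * k + (k + 1L - b)
    cols <- ((t - 1L) * C + 1L):(t * C)
    block <- rbind(dxcol[, cols, drop = FALSE], zero)
    dx <- dx + block[cache$bidx[, tm], , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# Output-row index per tap for the kernel-2 stride-2 transpose convolution:
# input pixel (i,j) of sample s writes output pixels (2i-1+a, 2j-1+b),
# a,b in {0,1}; the four taps partition the doubled-resolution grid.
tconv_taps <- function(b, h, w) {
  key <- paste("t", b, h, w, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hw <- h * w
  ii <- rep(seq_len(h), each = w)
  jj <- rep(seq_len(w), times = h)
  out <- vector("list", 4L)
  t <- 0L
  for (a in 0:1) {
    for (bb in 0:1) {
      t <- t + 1L
      base <- (2L * ii - 2L + a) * (2L * w) + (2L * jj - 1L + bb)
      idx <- integer(b * hw)
      for (s in seq_len(b)) {
        idx[((s - 1L) * hw + 1L):(s * hw)] <- base + (s - 1L) * 4L * hw
      }
      out[[t]] <- idx
    }
  }
  .idx_cache[[key]] <- out
  out
}

#' 2x upsampling transpose convolution (kernel 2, stride 2)
#'
#' `W` is Cin x (4*Cout): tap t = 2a+b+1 occupies columns
#' ((t-1)*Cout+1):(t*Cout).
#' @keywords internal
tconv2x_fwd <- function(f, W, bias) {
  Cout <- length(bias)
  stopifnot(ncol(W) == 4L * Cout)
  Yall <- f$x %*% W
  taps <- tconv_taps(f$b, f$h, f$w)
  y <- matrix(0, f$b * 4L * f$h * f$w, Cout)
  for (t in 1:4) {
    cols <- ((t - 1L) * Cout + 1L):(t * Cout)
    y[taps[[t]], ] <- Yall[, cols, drop = FALSE]
  }
  y <- sweep(y, 2L, bias, "+")
  list(y = fmap(y, f$b, 2L * f$h, 2L * f$w), cache = list(f = f, taps = taps))
}

tconv2x_bwd <- function(dy, cache, W) {
  f <- cache$f
  Cout <- ncol(dy)
  db <- colSums(dy)
  dYall <- matrix(0, nrow(f$x), 4L * Cout)
  for (t in 1:4) {
    cols <- ((t - 1L) * Cout + 1L):(t * Cout)
    dYall[, cols] <- dy[cache$taps[[t]], , drop = FALSE]
  }
  list(dx = dYall %*% t(W), dW = crossprod(f$x, dYall), db = db)
}

#' Batch normalization over all pixels of the batch, per channel
#' @keywords internal
batchnorm_fwd <- function(f, gamma, beta, state, training, momentum = 0.1,
                          eps = 1e-5) {
  x <- f$x
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu, "-")
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, inv, "*")
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
    cache <- list(xhat = xhat, inv = inv, gamma = gamma)
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- sweep(sweep(x, 2L, state$mean, "-"), 2L, inv, "*")
    cache <- NULL
  }
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = fmap(y, f$b, f$h, f$w), cache = cache, state = state)
}

batchnorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  N <- nrow(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat, 2L, s1 / N, "-") - sweep(xhat, 2L, s2 / N, "*")
  dx <- sweep(dx, 2L, cache$inv, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Half-pixel-center bilinear resampling plan: for each output pixel, four
# source row indices and weights.
resize_plan <- function(h, w, h2, w2) {
  key <- paste("r", h, w, h2, w2, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  src <- function(nout, nin) {
    s <- (seq_len(nout) - 0.5) * nin / nout + 0.5
    s <- pmin(pmax(s, 1), nin)
    i0 <- pmin(floor(s), nin - ifelse(nin > 1, 1, 0))
    list(i0 = as.integer(i0), t = s - i0)
  }
  sy <- src(h2, h); sx <- src(w2, w)
  i0 <- rep(sy$i0, each = w2); ty <- rep(sy$t, each = w2)
  j0 <- rep(sx$i0, times = h2); tx <- rep(sx$t, times = h2)
  i1 <- pmin(i0 + 1L, h); j1 <- pmin(j0 + 1L, w)
  plan <- list(
    idx = cbind((i0 - 1L) * w + j0, (i0 - 1L) * w + j1,
                (i1 - 1L) * w + j0, (i1 - 1L) * w + j1),
    wt = cbind((1 - ty) * (1 - tx), (1 - ty) * tx,
               ty * (1 - tx), ty * tx)
  )
  .idx_cache[[key]] <- plan
  plan
}

#' Differentiable bilinear resize of a batched feature map
#' @keywords internal
resize_bilinear_fwd <- function(f, h2, w2) {
  if (h2 == f$h && w2 == f$w) {
    return(list(y = f, cache = list(noop = TRUE, f = f)))
  }
  plan <- resize_plan(f$h, f$w, h2, w2)
  hw_in <- f$h * f$w
  hw_out <- h2 * w2
  C <- ncol(f$x)
  y <- matrix(0, f$b * hw_out, C)
  for (s in seq_len(f$b)) {
    xin <- f$x[((s - 1L) * hw_in + 1L):(s * hw_in), , drop = FALSE]
    acc <- plan$wt[, 1] * xin[plan$idx[, 1], , drop = FALSE]
    for (t in 2:4) {
      acc <- acc + plan$wt[, t] * xin[plan$idx[, t], , drop = FALSE]
    }
    y[((s - 1L) * hw_out + 1L):(s * hw_out), ] <- acc
  }
  list(y = fmap(y, f$b, h2, w2), cache = list(noop = FALSE, f = f, plan = plan,
                                              h2 = h2, w2 = w2))
}

resize_bilinear_bwd <- function(dy, cache) {
  if (isTRUE(cache$noop)) return(dy)
  f <- cache$f
  plan <- cache$plan
  hw_in <- f$h * f$w
  hw_out <- cache$h2 * cache$w2
  C <- ncol(f$x)
  dx <- matrix(0, f$b * hw_in, C)
  for (s in seq_len(f$b)) {
    dys <- dy[((s - 1L) * hw_out + 1L):(s * hw_out), , drop = FALSE]
    dxs <- matrix(0, hw_in, C)
    for (t in 1:4) {
      rs <- rowsum(plan$wt[, t] * dys, group = plan$idx[, t])
      rows <- as.integer(rownames(rs))
      dxs[rows, ] <- dxs[rows, ] + rs
    }
    dx[((s - 1L) * hw_in + 1L):(s * hw_in), ] <- dxs
  }
  dx
}

#' Resize a plain 2D matrix
#'
#' Bilinear for images, nearest-neighbour for label masks (half-pixel-center
#' convention in both cases). Masks are re-binarized by the caller.
#'
#' @param m numeric matrix
#' @param h2,w2 output size
#' @param method "bilinear" or "nearest"
#' @return h2 x w2 matrix
#' @export
image_resize <- function(m, h2, w2, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(m); w <- ncol(m)
  if (h == h2 && w == w2) return(m)
  if (method == "bilinear") {
    f <- resize_bilinear_fwd(as_fmap(m), h2, w2)$y
    return(matrix(f$x[, 1], h2, w2, byrow = TRUE))
  }
  si <- pmin(pmax(ceiling((seq_len(h2) - 0.5) * h / h2), 1L), h)
  sj <- pmin(pmax(ceiling((seq_len(w2) - 0.5) * w / w2), 1L), w)
  m[si, sj, drop = FALSE]
}
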