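# Independent brute-force oracles: plain-loop implementations of every
# numeric operation the package computes with vectorized/BLAS code paths.
# These share no code with the package internals.

# dense convolution by explicit sliding-window loops; W uses the package's
# tap-major layout ((a-1)*k+b, then input channel), x is an array (C,h,w)
oracle_conv2d <- function(x, W, bias, k, dil = 1) {
  C <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  Cout <- length(bias)
  half <- (k - 1) %/% 2
  out <- array(0, c(Cout, h, w))
  for (co in seq_len(Cout)) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        acc <- bias[co]
        for (a in seq_len(k)) {
          for (b in seq_len(k)) {
            si <- i + (a - 1 - half) * dil
            sj <- j + (b - 1 - half) * dil
            if (si < 1 || si > h || sj < 1 || sj > w) next
            t <- (a - 1) * k + b
            for (ci in seq_len(C)) {
              acc <- acc + x[ci, si, sj] * W[(t - 1) * C + ci, co]
            }
          }
        }
        out[co, i, j] <- acc
      }
    }
  }
  out
}

oracle_channel_attention <- function(x, p) {
  C <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(x[c, , ])
    mx[c] <- max(x[c, , ])
  }
  mlp <- function(v) {
    hid <- pmax(as.vector(v %*% p$W1) + p$b1, 0)
    as.vector(hid %*% p$W2) + p$b2
  }
  mc <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  out <- x
  for (c in seq_len(C)) out[c, , ] <- x[c, , ] * mc[c]
  out
}

oracle_spatial_attention <- function(x, p, k) {
  C <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  mu <- apply(x, c(2, 3), mean)
  mx <- apply(x, c(2, 3), max)
  stats <- array(0, c(2, h, w))
  stats[1, , ] <- mu
  stats[2, , ] <- mx
  z <- oracle_conv2d(stats, p$W, p$b, k)[1, , ]
  ms <- 1 / (1 + exp(-z))
  out <- x
  for (c in seq_len(C)) out[c, , ] <- x[c, , ] * ms
  out
}

oracle_dice <- function(probs, target, eps) {
  num <- 0; dp <- 0; dt <- 0
  for (i in seq_along(probs)) {
    num <- num + probs[i] * target[i]
    dp <- dp + probs[i]
    dt <- dt + target[i]
  }
  1 - (2 * num + eps) / (dp + dt + eps)
}

oracle_bce <- function(logits, target) {
  p <- 1 / (1 + exp(-logits))
  s <- 0
  for (i in seq_along(logits)) {
    s <- s - (target[i] * log(p[i]) + (1 - target[i]) * log(1 - p[i]))
  }
  s / length(logits)
}

# 95th percentile with linear interpolation over order statistics
oracle_p95 <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * 0.95 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# all metrics on two binary arrays by explicit set loops
oracle_metrics <- function(pred, gt, spacing = 1) {
  P <- which(pred != 0, arr.ind = TRUE)
  G <- which(gt != 0, arr.ind = TRUE)
  spacing <- rep_len(spacing, ncol(P))
  keyP <- apply(P, 1, paste, collapse = ",")
  keyG <- apply(G, 1, paste, collapse = ",")
  ninter <- sum(keyP %in% keyG)
  np <- nrow(P); ng <- nrow(G)
  dice <- if (np + ng == 0) 1 else 2 * ninter / (np + ng)
  iou <- if (np + ng == 0) 1 else ninter / (np + ng - ninter)
  vdp <- if (ng == 0) NA_real_ else (ng - ninter) / ng * 100
  if (np == 0 && ng == 0) {
    hd <- 0; hd95 <- 0
  } else if (np == 0 || ng == 0) {
    hd <- NA_real_; hd95 <- NA_real_
  } else {
    dmin <- function(A, B) {
      out <- numeric(nrow(A))
      for (i in seq_len(nrow(A))) {
        best <- Inf
        for (j in seq_len(nrow(B))) {
          d2 <- 0
          for (ax in seq_len(ncol(A))) {
            d2 <- d2 + ((A[i, ax] - B[j, ax]) * spacing[ax])^2
          }
          if (d2 < best) best <- d2
        }
        out[i] <- sqrt(best)
      }
      out
    }
    dpg <- dmin(P, G)
    dgp <- dmin(G, P)
    hd <- max(max(dpg), max(dgp))
    hd95 <- max(oracle_p95(dpg), oracle_p95(dgp))
  }
  c(dice = dice, iou = iou, hd = hd, hd95 = hd95, vdp = vdp,
    vol_pred = np, vol_gt = ng)
}

oracle_pearson <- function(vp, vg) {
  mp <- mean(vp); mg <- mean(vg)
  num <- sum((vp - mp) * (vg - mg))
  num / sqrt(sum((vp - mp)^2) * sum((vg - mg)^2))
}
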