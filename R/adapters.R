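# ---------------------------------------------------------------------------
# Residual bottleneck adapters.
#
# Each adapter is a token-wise residual update y = x + B(x) where B is a
# down-projection to a narrow latent space, an exact GELU, and an
# up-projection back to the token dimension. With the up-projection (and all
# biases) initialized to zero the adapter is an exact identity, so inserting
# adapters into a backbone changes nothing until training moves them -- the
# pretrained representation is preserved at step 0.
# ---------------------------------------------------------------------------

#' Create one bottleneck adapter
#'
#' @param embed_dim token dimensionality
#' @param bottleneck latent width (must be smaller than `embed_dim`)
#' @return parameter list with `W_down` (embed_dim x bottleneck), `b_down`,
#'   `W_up` (bottleneck x embed_dim), `b_up`. `W_down` is truncated-normal
#'   initialized; `W_up` and both biases start at zero (identity at init).
#' @export
adapter_init <- function(embed_dim, bottleneck) {
  if (bottleneck >= embed_dim) {
    stop("adapter bottleneck must be smaller than embed_dim", call. = FALSE)
  }
  list(
    W_down = mat_init(embed_dim, bottleneck),
    b_down = numeric(bottleneck),
    W_up = matrix(0, bottleneck, embed_dim),
    b_up = numeric(embed_dim)
  )
}

#' Apply a bottleneck adapter token-wise
#'
#' Computes `y = x + GELU(x W_down + b_down) W_up + b_up` for every token
#' (row) of `x`.
#'
#' @param x tokens, a matrix (n_tokens x embed_dim); a single token vector
#'   is accepted and returned as a vector
#' @param adapter parameter list from [adapter_init()]
#' @return matrix (or vector) of the same shape as `x`
#' @export
adapter_forward <- function(x, adapter) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(adapter$W_down)) {
    stop(sprintf("adapter expects %d-dim tokens, got %d",
                 nrow(adapter$W_down), ncol(x)), call. = FALSE)
  }
  y <- adapter_fwd(x, adapter)$y
  if (vec) drop(y) else y
}

adapter_fwd <- function(x, adapter) {
  pre <- sweep(x %*% adapter$W_down, 2L, adapter$b_down, "+")
  h <- gelu(pre)
  up <- sweep(h %*% adapter$W_up, 2L, adapter$b_up, "+")
  list(y = x + up, cache = list(x = x, pre = pre, h = h))
}

adapter_bwd <- function(dy, cache, adapter) {
  dh <- dy %*% t(adapter$W_up)
  dpre <- dh * gelu_grad(cache$pre)
  list(
    dx = dy + dpre %*% t(adapter$W_down),
    grads = list(
      W_down = crossprod(cache$x, dpre),
      b_down = colSums(dpre),
      W_up = crossprod(cache$h, dy),
      b_up = colSums(dy)
    )
  )
}

#' Closed-form adapter parameter count
#'
#' `n_adapters * (d*b + b + b*d + d)`: down-projection weights and bias plus
#' up-projection weights and bias. For the reference configuration
#' (embed_dim 768, bottleneck 48, 4 adapters) this is 298,176 parameters.
#'
#' @param embed_dim token dimensionality
#' @param bottleneck adapter latent width
#' @param n_adapters number of adapters
#' @return integer parameter count
#' @export
count_adapter_params <- function(embed_dim, bottleneck, n_adapters) {
  stopifnot(embed_dim > 0, bottleneck > 0, n_adapters >= 0)
  n_adapters * (embed_dim * bottleneck + bottleneck +
                  bottleneck * embed_dim + embed_dim)
}
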