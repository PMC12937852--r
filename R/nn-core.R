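# ---------------------------------------------------------------------------
# Core dense primitives: initializers, activations, linear, layer norm,
# softmax. Every forward returns list(y, cache); every backward takes the
# upstream gradient plus the cache and returns gradients for inputs and
# parameters. All tensors are plain double matrices so the whole network
# runs on BLAS.
# ---------------------------------------------------------------------------

#' Truncated-normal initializer
#'
#' Draws from N(0, sd^2) truncated to \[-2 sd, 2 sd\] by resampling, the
#' standard vision-transformer weight initialization.
#'
#' @param n number of values
#' @param sd standard deviation (default 0.02)
#' @return numeric vector of length `n`
#' @keywords internal
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), sd = sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

mat_init <- function(nrow, ncol, sd = 0.02) {
  matrix(trunc_normal(nrow * ncol, sd), nrow, ncol)
}

#' Exact Gaussian Error Linear Unit
#'
#' `gelu(x) = x * Phi(x)` with the erf-based cumulative normal, not the tanh
#' approximation, so independent oracles reproduce it to machine precision.
#'
#' @param x numeric vector/matrix
#' @return same shape as `x`
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

linear_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2L, b, "+")
  list(y = y, cache = x)
}

linear_bwd <- function(dy, cache, W) {
  list(
    dx = dy %*% t(W),
    dW = crossprod(cache, dy),
    db = colSums(dy)
  )
}

layernorm_fwd <- function(x, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * gamma[col(xhat)], 2L, beta, "+")
  # gamma[col(xhat)] broadcasts gamma across rows without an explicit sweep
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  inv <- cache$inv
  D <- ncol(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * cache$gamma[col(dy)]
  # standard layer-norm backward, vectorized across rows
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dx <- (dxhat - s1 / D - xhat * s2 / D) * inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_rows_bwd <- function(dy, y) {
  y * (dy - rowSums(dy * y))
}

# --- nested parameter-list utilities ---------------------------------------

#' Enumerate leaf paths of a nested parameter list
#' @param params nested list whose leaves are numeric arrays
#' @param prefix internal
#' @return list of character vectors, one path per leaf
#' @keywords internal
param_paths <- function(params, prefix = character()) {
  if (is.numeric(params)) return(list(prefix))
  out <- list()
  for (nm in names(params)) {
    out <- c(out, param_paths(params[[nm]], c(prefix, nm)))
  }
  out
}

pget <- function(params, path) {
  for (p in path) params <- params[[p]]
  params
}

pset <- function(params, path, value) {
  if (length(path) == 1L) {
    params[[path]] <- value
    return(params)
  }
  params[[path[1L]]] <- pset(params[[path[1L]]], path[-1L], value)
  params
}

#' Count the values held in a nested parameter list
#' @param params nested list of numeric arrays
#' @return integer total number of scalar parameters
#' @export
count_params <- function(params) {
  if (is.numeric(params)) return(length(params))
  sum(vapply(params, count_params, numeric(1)))
}
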