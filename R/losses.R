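# ---------------------------------------------------------------------------
# Hybrid Dice + BCE objective with weighted deep supervision:
#   L_total = L_Dice + L_BCE + aux_weight * sum_i L_aux,i
# where each auxiliary term mirrors the main term (Dice + BCE) on that
# head's logits bilinearly upsampled to full resolution. Dice is computed
# batch-globally (one ratio over all pixels of the batch), which keeps
# empty-slice batches stable.
# ---------------------------------------------------------------------------

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`, summed over every
#' pixel supplied (batch-global). Zero exactly when `probs` equals a binary
#' `target`; finite for empty prediction and target thanks to `eps`.
#'
#' @param probs predicted probabilities in (0,1) (any shape)
#' @param target binary ground truth, same shape
#' @param eps smoothing constant (> 0)
#' @return scalar in \[0, 1)
#' @export
dice_loss <- function(probs, target, eps = 1.0) {
  if (length(probs) != length(target)) {
    stop("dice_loss: probs and target differ in length", call. = FALSE)
  }
  1 - (2 * sum(probs * target) + eps) / (sum(probs) + sum(target) + eps)
}

dice_loss_grad <- function(probs, target, eps = 1.0) {
  num <- 2 * sum(probs * target) + eps
  den <- sum(probs) + sum(target) + eps
  list(loss = 1 - num / den,
       dprobs = -(2 * target * den - num) / den^2)
}

#' Binary cross-entropy from logits
#'
#' Mean over all pixels, computed in the standard numerically stable form
#' `max(z,0) - z*t + log(1 + exp(-|z|))`.
#'
#' @param logits raw scores (any shape)
#' @param target binary ground truth, same shape
#' @return scalar mean BCE
#' @export
bce_loss <- function(logits, target) {
  if (length(logits) != length(target)) {
    stop("bce_loss: logits and target differ in length", call. = FALSE)
  }
  mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
}

bce_loss_grad <- function(logits, target) {
  n <- length(logits)
  list(loss = bce_loss(logits, target),
       dlogits = (sigmoid(logits) - target) / n)
}

# Dice + BCE on one logits vector; returns loss terms and d(loss)/d(logits)
hybrid_term_grad <- function(logits, target, cfg) {
  d <- list(loss = 0, dprobs = 0)
  bce <- list(loss = 0, dlogits = 0)
  p <- sigmoid(logits)
  if (cfg$use_dice) d <- dice_loss_grad(p, target, cfg$dice_smooth)
  if (cfg$use_bce) bce <- bce_loss_grad(logits, target)
  dlogits <- bce$dlogits
  if (cfg$use_dice) dlogits <- dlogits + d$dprobs * p * (1 - p)
  list(dice = d$loss, bce = bce$loss, total = d$loss + bce$loss,
       dlogits = dlogits)
}

#' Total training loss with deep supervision
#'
#' Main term: Dice + BCE on the main logits. Each auxiliary head's logits
#' are bilinearly upsampled to the target resolution and scored against the
#' same full-resolution target; the summed auxiliary terms are weighted by
#' `cfg$aux_weight`.
#'
#' @param main_logits matrix (H x W) of raw scores
#' @param aux_logits list of lower-resolution logit matrices (may be empty)
#' @param target binary H x W matrix
#' @param cfg a [loss_config()]
#' @return list with `total` and a per-term `breakdown` data frame
#' @export
total_loss <- function(main_logits, aux_logits, target, cfg = loss_config()) {
  mf <- as_fmap(main_logits)
  tf <- as.vector(t(target))
  af <- lapply(aux_logits, as_fmap)
  if (length(af) && is.null(names(af))) {
    names(af) <- paste0("aux", seq_along(af))
  }
  out <- total_loss_fmap(mf, af, matrix(tf, ncol = 1L), cfg)
  list(total = out$total, breakdown = out$breakdown)
}

# fmap-level loss with gradients; target is a (b*H*W) x 1 matrix aligned
# with the main-logits fmap rows
total_loss_fmap <- function(main_f, aux_fs, target, cfg) {
  mt <- hybrid_term_grad(main_f$x[, 1], target[, 1], cfg)
  rows <- list(data.frame(term = "main", dice = mt$dice, bce = mt$bce,
                          weighted = mt$total))
  total <- mt$total
  daux <- list()
  for (nm in names(aux_fs)) {
    a <- aux_fs[[nm]]
    rs <- resize_bilinear_fwd(a, main_f$h, main_f$w)
    at <- hybrid_term_grad(rs$y$x[, 1], target[, 1], cfg)
    total <- total + cfg$aux_weight * at$total
    d <- resize_bilinear_bwd(matrix(cfg$aux_weight * at$dlogits, ncol = 1L),
                             rs$cache)
    daux[[nm]] <- d
    rows[[length(rows) + 1L]] <-
      data.frame(term = nm, dice = at$dice, bce = at$bce,
                 weighted = cfg$aux_weight * at$total)
  }
  list(total = total,
       breakdown = do.call(rbind, rows),
       dmain = matrix(mt$dlogits, ncol = 1L),
       daux = daux)
}
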