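# ---------------------------------------------------------------------------
# Training and inference orchestration: Adam with hierarchical learning
# rates over the backbone / adapters / decoder parameter groups,
# reduce-on-plateau scheduling of the validation loss, deep-supervised
# hybrid loss, best-checkpoint selection by validation Dice, and slice-wise
# volume prediction with restacking.
# ---------------------------------------------------------------------------

# quick overlap of two binary arrays (both-empty counts as perfect)
dice_binary <- function(p, g) {
  sp <- sum(p); sg <- sum(g)
  if (sp == 0 && sg == 0) return(1)
  2 * sum(p * g) / (sp + sg)
}

#' Prepare one slice pair for the network
#'
#' Normalizes to \[0,1\] (modality-specific clipping), resizes image
#' (bilinear) and mask (nearest, re-binarized) to the model input size,
#' optionally augments, then standardizes and replicates to 3 channels.
#'
#' @param pair slice pair from [slice_dataset()]
#' @param img_size model input edge
#' @param modality "dwi", "ncct" or "phantom"
#' @param policy an [augment_policy()] or NULL for evaluation
#' @return list with `image` ((s,s,3) standardized array) and `mask`
#' @export
prepare_slice <- function(pair, img_size, modality = "phantom",
                          policy = NULL) {
  img <- to_unit(pair$image, if (modality == "ncct") "ncct" else "dwi")
  img <- image_resize(img, img_size, img_size, "bilinear")
  msk <- (image_resize(pair$mask, img_size, img_size, "nearest") > 0.5) * 1
  if (!is.null(policy) && policy$enabled) {
    aug <- augment(list(image = img, mask = msk), policy)
    img <- aug$image
    msk <- aug$mask
  }
  std <- (img - 0.5) / 0.5
  list(image = array(std, c(img_size, img_size, 3L))[, , c(1, 1, 1)],
       mask = msk)
}

adam_init <- function(params, paths) {
  st <- list()
  for (p in paths) {
    key <- paste(p, collapse = "/")
    st[[key]] <- list(m = pget(params, p) * 0, v = pget(params, p) * 0)
  }
  st
}

adam_step <- function(params, grads, opt, groups, cfg, t) {
  for (g in groups) {
    lr <- g$lr
    for (p in g$paths) {
      key <- paste(p, collapse = "/")
      gr <- pget(grads, p)
      if (is.null(gr)) stop(sprintf("missing gradient for %s", key))
      th <- pget(params, p)
      gr <- gr + cfg$weight_decay * th
      s <- opt[[key]]
      s$m <- cfg$beta1 * s$m + (1 - cfg$beta1) * gr
      s$v <- cfg$beta2 * s$v + (1 - cfg$beta2) * gr^2
      opt[[key]] <- s
      mhat <- s$m / (1 - cfg$beta1^t)
      vhat <- s$v / (1 - cfg$beta2^t)
      params <- pset(params, p, th - lr * mhat / (sqrt(vhat) + 1e-8))
    }
  }
  list(params = params, opt = opt)
}

run_batch <- function(model, slices, losscfg, training) {
  imgs <- lapply(slices, `[[`, "image")
  s <- dim(imgs[[1]])[1]
  target <- matrix(unlist(lapply(slices, function(p) as.vector(t(p$mask)))),
                   ncol = 1L)
  out <- model_fwd(model, imgs, training = training)
  lo <- total_loss_fmap(out$main, out$aux, target, losscfg)
  list(out = out, loss = lo, target = target)
}

#' Train a segmentation model
#'
#' Runs the full protocol: shuffled mini-batches with augmentation,
#' Adam with per-group learning rates (the backbone group is dropped under
#' the frozen-backbone regime), deep-supervised Dice+BCE loss, per-epoch
#' validation loss and Dice, learning rates halved after
#' `plateau_patience` epochs without validation-loss improvement, and
#' best-checkpoint selection by validation Dice.
#'
#' @param model a [strokevit_model()]
#' @param data list with `train` and `val` slice lists (see
#'   [slice_dataset()])
#' @param cfg a [train_config()]
#' @param losscfg a [loss_config()]
#' @param modality slice normalization mode
#' @param policy training augmentation policy
#' @param verbose print per-epoch progress
#' @return list with `model` (best by validation Dice), `final_model`,
#'   `history` (data frame: epoch, train_loss, val_loss, val_dice, per-group
#'   learning rates), and `seed`
#' @export
train <- function(model, data, cfg = train_config(),
                  losscfg = loss_config(), modality = "phantom",
                  policy = augment_policy(), verbose = FALSE) {
  if (length(data$train) == 0L || length(data$val) == 0L) {
    stop("train and val splits must be nonempty", call. = FALSE)
  }
  freeze <- cfg$regime == "frozen_backbone"
  model$cfg$backbone$freeze_backbone <- freeze
  groups <- parameter_groups(model, cfg$lr_backbone, cfg$lr_adapters,
                             cfg$lr_decoder, freeze_backbone = freeze)
  all_paths <- do.call(c, lapply(groups, `[[`, "paths"))
  opt <- adam_init(model$params, all_paths)
  set.seed(cfg$seed)
  img_size <- model$cfg$backbone$img_size
  step <- 0L
  best_dice <- -Inf
  best_params <- model$params
  best_state <- model$state
  bad_epochs <- 0L
  best_val_loss <- Inf
  history <- list()
  lr_scale <- 1
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(data$train))
    train_losses <- c()
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      if (step >= cfg$max_steps) break
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      slices <- lapply(data$train[idx], prepare_slice, img_size = img_size,
                       modality = modality, policy = policy)
      rb <- run_batch(model, slices, losscfg, training = TRUE)
      if (!is.finite(rb$loss$total)) {
        stop(sprintf("non-finite loss at epoch %d step %d", epoch, step + 1L),
             call. = FALSE)
      }
      model$state$decoder <- rb$out$state
      grads <- model_bwd(model, rb$loss$dmain, rb$loss$daux, rb$out$cache)
      step <- step + 1L
      scaled <- groups
      for (nm in names(scaled)) scaled[[nm]]$lr <- scaled[[nm]]$lr * lr_scale
      upd <- adam_step(model$params, grads, opt, scaled, cfg, step)
      model$params <- upd$params
      opt <- upd$opt
      train_losses <- c(train_losses, rb$loss$total)
    }
    # validation pass (eval mode, no augmentation)
    val_losses <- c()
    inter <- 0; psum <- 0; gsum <- 0
    for (start in seq(1L, length(data$val), by = cfg$batch_size)) {
      idx <- start:min(start + cfg$batch_size - 1L, length(data$val))
      slices <- lapply(data$val[idx], prepare_slice, img_size = img_size,
                       modality = modality, policy = NULL)
      rb <- run_batch(model, slices, losscfg, training = FALSE)
      val_losses <- c(val_losses, rb$loss$total)
      pred <- (sigmoid(rb$out$main$x[, 1]) > cfg$threshold) * 1
      inter <- inter + sum(pred * rb$target[, 1])
      psum <- psum + sum(pred)
      gsum <- gsum + sum(rb$target[, 1])
    }
    val_loss <- mean(val_losses)
    val_dice <- if (psum + gsum == 0) 1 else 2 * inter / (psum + gsum)
    if (val_dice > best_dice) {
      best_dice <- val_dice
      best_params <- model$params
      best_state <- model$state
    }
    if (val_loss < best_val_loss - 1e-8) {
      best_val_loss <- val_loss
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$plateau_patience) {
        lr_scale <- lr_scale * cfg$plateau_factor
        bad_epochs <- 0L
      }
    }
    history[[epoch]] <- data.frame(
      epoch = epoch,
      train_loss = mean(train_losses),
      val_loss = val_loss, val_dice = val_dice,
      lr_backbone = if (freeze) NA_real_ else cfg$lr_backbone * lr_scale,
      lr_adapters = cfg$lr_adapters * lr_scale,
      lr_decoder = cfg$lr_decoder * lr_scale)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                      epoch, mean(train_losses), val_loss, val_dice))
    }
    if (step >= cfg$max_steps) break
  }
  best <- model
  best$params <- best_params
  best$state <- best_state
  list(model = best, final_model = model,
       history = do.call(rbind, history), seed = cfg$seed)
}

#' Predict the lesion mask of a whole volume
#'
#' Every axial slice is normalized, resized to the model input size, passed
#' through the network, and the sigmoid probabilities are bilinearly
#' resized back to the native slice shape before thresholding; the slice
#' masks are stacked into a 3D volume aligned with the input.
#'
#' @param model a [strokevit_model()]
#' @param volume list with `image` (3D array) and optionally `spacing`, `id`
#' @param modality normalization mode
#' @param threshold probability cut (default 0.5)
#' @param batch_size slices per forward pass
#' @return list with `mask` (binary 3D array), `prob` (probability array),
#'   `spacing`, `id`
#' @export
predict_volume <- function(model, volume, modality = "phantom",
                           threshold = 0.5, batch_size = 8L) {
  img_size <- model$cfg$backbone$img_size
  dims <- dim(volume$image)
  S <- dims[3]
  prob <- array(0, dims)
  for (start in seq(1L, S, by = batch_size)) {
    ks <- start:min(start + batch_size - 1L, S)
    imgs <- lapply(ks, function(k) {
      x <- to_unit(volume$image[, , k],
                   if (modality == "ncct") "ncct" else "dwi")
      x <- image_resize(x, img_size, img_size, "bilinear")
      std <- (x - 0.5) / 0.5
      array(std, c(img_size, img_size, 3L))[, , c(1, 1, 1)]
    })
    probs <- predict_slices(model, imgs)
    for (t in seq_along(ks)) {
      prob[, , ks[t]] <- image_resize(probs[[t]], dims[1], dims[2],
                                      "bilinear")
    }
  }
  list(mask = (prob > threshold) * 1, prob = prob,
       spacing = volume$spacing, id = volume$id)
}
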