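# ---------------------------------------------------------------------------
# Full segmentation model: encoder + adapters + decoder, assembled from one
# configuration schema so that the reference-scale model (224x224, ViT-B/16)
# and tiny test-scale models are the same code path.
# ---------------------------------------------------------------------------

#' Assemble a segmentation model
#'
#' @param backbone a [backbone_config()]
#' @param decoder a [decoder_config()]
#' @param seed optional RNG seed for weight initialization
#' @return object of class `strokevit_model`: `cfg`, `params` (nested list
#'   with `backbone`, `adapters`, `decoder`), and `state` (batch-norm
#'   running statistics)
#' @export
strokevit_model <- function(backbone = backbone_config(),
                            decoder = decoder_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- list(
    backbone = build_backbone_params(backbone),
    adapters = build_adapter_params(backbone),
    decoder = build_decoder_params(decoder, backbone$embed_dim)
  )
  structure(list(
    cfg = list(backbone = backbone, decoder = decoder),
    params = params,
    state = list(decoder = build_decoder_state(decoder, backbone$embed_dim))
  ), class = "strokevit_model")
}

#' @export
print.strokevit_model <- function(x, ...) {
  cb <- x$cfg$backbone
  cat(sprintf(
    "<strokevit_model> patch %d, dim %d, depth %d, heads %d\n",
    cb$patch_size, cb$embed_dim, cb$depth, cb$num_heads))
  cat(sprintf("  adapters: %s (bottleneck %d), %s parameters\n",
              if (length(cb$adapter_layers))
                paste(cb$adapter_layers, collapse = "/") else "none",
              cb$adapter_bottleneck,
              format(count_params(x$params$adapters), big.mark = ",")))
  cat(sprintf("  decoder stages: %s; total parameters: %s\n",
              paste(x$cfg$decoder$stage_channels, collapse = "/"),
              format(count_params(x$params), big.mark = ",")))
  invisible(x)
}

#' Forward pass on a batch of slices
#'
#' @param model a [strokevit_model()]
#' @param images list of (H, W, 3) arrays (or (H, W) matrices), all the
#'   same size, H and W divisible by the patch size
#' @param training batch-norm mode; training mode also retains the caches
#'   needed for the backward pass
#' @return list with `main` (logits fmap at input resolution), `aux`
#'   (named list of auxiliary logit fmaps), `state` (updated batch-norm
#'   state), and `cache` when `training`
#' @keywords internal
model_fwd <- function(model, images, training = FALSE) {
  images <- lapply(images, function(im) {
    if (length(dim(im)) == 2L) im <- array(im, c(dim(im), 1L))
    im
  })
  H <- dim(images[[1]])[1]; W <- dim(images[[1]])[2]
  bf <- backbone_fwd(model, images, keep_cache = training)
  df <- decoder_fwd(model, bf$grid, H, W, training = training)
  list(main = df$main, aux = df$aux, state = df$state,
       cache = if (training) list(backbone = bf$cache, decoder = df$cache)
               else NULL)
}

# Backward pass: upstream gradients on main/aux logits -> parameter grads
model_bwd <- function(model, dmain, daux, cache) {
  db <- decoder_bwd(dmain, daux, cache$decoder, model)
  bb <- backbone_bwd(db$dgrid, cache$backbone, model)
  list(backbone = bb$backbone, adapters = bb$adapters, decoder = db$grads)
}

#' Segment a batch of normalized slices
#'
#' @param model a [strokevit_model()]
#' @param images list of normalized (H, W, 3) arrays
#' @return list of H x W probability matrices
#' @export
predict_slices <- function(model, images) {
  out <- model_fwd(model, images, training = FALSE)
  f <- out$main
  hw <- f$h * f$w
  lapply(seq_len(f$b), function(s) {
    rows <- ((s - 1L) * hw + 1L):(s * hw)
    matrix(sigmoid(f$x[rows, 1]), f$h, f$w, byrow = TRUE)
  })
}

#' Save a model checkpoint
#'
#' Stores configuration, parameters and batch-norm state in one RDS file;
#' [load_checkpoint()] restores an identical model.
#'
#' @param model a [strokevit_model()]
#' @param path output file
#' @param extra optional list stored alongside (e.g. training history)
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(cfg = model$cfg, params = model$params, state = model$state,
               extra = extra), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()]
#' @return a `strokevit_model` (the stored `extra` list is attached as
#'   attribute "extra")
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  m <- structure(list(cfg = obj$cfg, params = obj$params, state = obj$state),
                 class = "strokevit_model")
  attr(m, "extra") <- obj$extra
  m
}

#' Import backbone weights from an external state dictionary
#'
#' Optional hook for loading pretrained encoder weights: `mapping` names
#' entries of `state` (a named list of arrays) keyed by the internal
#' backbone parameter paths ("block3/Wqkv", "W_patch", ...). Shapes must
#' match exactly; unmapped parameters keep their current values.
#'
#' @param model a [strokevit_model()]
#' @param state named list of numeric arrays
#' @param mapping named character vector: internal path -> name in `state`
#' @return the model with imported weights
#' @export
import_backbone_weights <- function(model, state, mapping) {
  for (path in names(mapping)) {
    src <- state[[mapping[[path]]]]
    if (is.null(src)) {
      stop(sprintf("state entry '%s' not found", mapping[[path]]),
           call. = FALSE)
    }
    parts <- strsplit(path, "/", fixed = TRUE)[[1]]
    cur <- pget(model$params$backbone, parts)
    if (!identical(dim(cur), dim(src)) || length(cur) != length(src)) {
      stop(sprintf("shape mismatch importing '%s'", path), call. = FALSE)
    }
    model$params$backbone <- pset(model$params$backbone, parts, src)
  }
  model
}
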