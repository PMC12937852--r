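# ---------------------------------------------------------------------------
# Configuration objects. One schema covers the reference-scale model (224x224
# slices, ViT-B/16 encoder) and the tiny configurations used in tests; all
# constructors validate their invariants eagerly so misconfiguration fails
# at build time, not mid-training.
# ---------------------------------------------------------------------------

#' Backbone (encoder) configuration
#'
#' Defaults describe a ViT-B/16 encoder: 16x16 patches, 768-dim tokens,
#' 12 transformer blocks with 12 heads, bottleneck adapters of width 48
#' applied after blocks 3, 6, 9 and 12.
#'
#' @param patch_size patch edge in pixels; must divide the input height/width
#' @param embed_dim token dimensionality
#' @param depth number of transformer blocks
#' @param num_heads attention heads; must divide `embed_dim`
#' @param mlp_ratio feed-forward expansion ratio
#' @param adapter_layers 1-based block indices after which an adapter is
#'   applied; empty vector disables adapters
#' @param adapter_bottleneck adapter latent width (must be < `embed_dim`)
#' @param freeze_backbone exclude backbone parameters from optimization
#' @param num_register_tokens auxiliary non-spatial tokens carried through
#'   the encoder and discarded before decoding (a class token is always
#'   present in addition)
#' @param img_size training slice edge; with `patch_size` fixes the learned
#'   positional-embedding grid
#' @return object of class `backbone_config`
#' @export
backbone_config <- function(patch_size = 16L, embed_dim = 768L, depth = 12L,
                            num_heads = 12L, mlp_ratio = 4,
                            adapter_layers = c(3L, 6L, 9L, 12L),
                            adapter_bottleneck = 48L,
                            freeze_backbone = FALSE,
                            num_register_tokens = 4L,
                            img_size = 224L) {
  patch_size <- as.integer(patch_size)
  embed_dim <- as.integer(embed_dim)
  depth <- as.integer(depth)
  num_heads <- as.integer(num_heads)
  adapter_layers <- sort(unique(as.integer(adapter_layers)))
  adapter_bottleneck <- as.integer(adapter_bottleneck)
  num_register_tokens <- as.integer(num_register_tokens)
  img_size <- as.integer(img_size)
  if (embed_dim %% num_heads != 0L) {
    stop("embed_dim must be divisible by num_heads", call. = FALSE)
  }
  if (length(adapter_layers) &&
      (min(adapter_layers) < 1L || max(adapter_layers) > depth)) {
    stop("adapter_layers indices must lie in [1, depth]", call. = FALSE)
  }
  if (length(adapter_layers) && adapter_bottleneck >= embed_dim) {
    stop("adapter_bottleneck must be smaller than embed_dim", call. = FALSE)
  }
  if (img_size %% patch_size != 0L) {
    stop(sprintf("img_size %d is not divisible by patch_size %d",
                 img_size, patch_size), call. = FALSE)
  }
  structure(list(
    patch_size = patch_size, embed_dim = embed_dim, depth = depth,
    num_heads = num_heads, mlp_ratio = mlp_ratio,
    adapter_layers = adapter_layers, adapter_bottleneck = adapter_bottleneck,
    freeze_backbone = isTRUE(freeze_backbone),
    num_register_tokens = num_register_tokens, img_size = img_size
  ), class = "backbone_config")
}

#' Decoder configuration
#'
#' Four upsampling stages double the resolution each; the fused token grid
#' therefore ends at 16x the grid resolution before the final bilinear
#' resize back to the input size.
#'
#' @param branch_channels channels per multi-scale aggregation branch
#' @param stage_channels integer vector of 4 stage widths
#' @param attention_reduction channel-attention MLP reduction ratio
#' @param spatial_kernel spatial-attention kernel size (odd)
#' @param aux_stages stages (subset of 1:4) carrying auxiliary heads
#' @param use_attention enable the serial channel/spatial attention pair
#'   (the decoder-attention ablation toggle)
#' @return object of class `decoder_config`
#' @export
decoder_config <- function(branch_channels = 192L,
                           stage_channels = c(256L, 128L, 64L, 32L),
                           attention_reduction = 16L,
                           spatial_kernel = 7L,
                           aux_stages = c(1L, 2L),
                           use_attention = TRUE) {
  stage_channels <- as.integer(stage_channels)
  aux_stages <- sort(unique(as.integer(aux_stages)))
  spatial_kernel <- as.integer(spatial_kernel)
  if (length(stage_channels) != 4L) {
    stop("stage_channels must have exactly 4 entries", call. = FALSE)
  }
  if (spatial_kernel %% 2L != 1L) {
    stop("spatial_kernel must be odd", call. = FALSE)
  }
  if (length(aux_stages) && !all(aux_stages %in% 1:4)) {
    stop("aux_stages must be a subset of {1,2,3,4}", call. = FALSE)
  }
  structure(list(
    branch_channels = as.integer(branch_channels),
    stage_channels = stage_channels,
    attention_reduction = as.integer(attention_reduction),
    spatial_kernel = spatial_kernel,
    aux_stages = aux_stages,
    use_attention = isTRUE(use_attention)
  ), class = "decoder_config")
}

#' Loss configuration
#'
#' @param aux_weight deep-supervision weight relative to the main loss
#' @param dice_smooth additive smoothing constant of the Dice ratio
#' @param use_dice,use_bce loss-term toggles (at least one must be on)
#' @return object of class `loss_config`
#' @export
loss_config <- function(aux_weight = 0.3, dice_smooth = 1.0,
                        use_dice = TRUE, use_bce = TRUE) {
  if (!use_dice && !use_bce) {
    stop("at least one of use_dice/use_bce must be TRUE", call. = FALSE)
  }
  if (aux_weight < 0) stop("aux_weight must be >= 0", call. = FALSE)
  if (dice_smooth <= 0) stop("dice_smooth must be > 0", call. = FALSE)
  structure(list(aux_weight = aux_weight, dice_smooth = dice_smooth,
                 use_dice = isTRUE(use_dice), use_bce = isTRUE(use_bce)),
            class = "loss_config")
}

#' Training configuration
#'
#' Defaults are the reference protocol: Adam (beta1 0.9, beta2 0.999,
#' weight decay 1e-5), batch size 8, 100 epochs, hierarchical learning
#' rates (1e-5 backbone when unfrozen, 1e-4 adapters, 1e-4 decoder),
#' learning rates halved when the validation loss plateaus for 10 epochs.
#'
#' @param epochs training epochs
#' @param batch_size slices per optimization step
#' @param lr_backbone,lr_adapters,lr_decoder per-group learning rates
#' @param weight_decay L2 coefficient added to gradients
#' @param beta1,beta2 Adam moment decays
#' @param plateau_factor,plateau_patience ReduceLROnPlateau settings
#'   monitoring validation loss
#' @param regime "frozen_backbone" (adapters + decoder only) or "unfrozen"
#' @param seed RNG seed controlling shuffling and augmentation
#' @param threshold probability cut for binary masks
#' @param max_steps optional cap on total optimization steps (smoke tests)
#' @return object of class `train_config`
#' @export
train_config <- function(epochs = 100L, batch_size = 8L,
                         lr_backbone = 1e-5, lr_adapters = 1e-4,
                         lr_decoder = 1e-4, weight_decay = 1e-5,
                         beta1 = 0.9, beta2 = 0.999,
                         plateau_factor = 0.5, plateau_patience = 10L,
                         regime = c("unfrozen", "frozen_backbone"),
                         seed = 1L, threshold = 0.5, max_steps = Inf) {
  regime <- match.arg(regime)
  if (any(c(lr_backbone, lr_adapters, lr_decoder) <= 0)) {
    stop("learning rates must be positive", call. = FALSE)
  }
  if (plateau_patience < 1L) stop("plateau_patience must be >= 1",
                                  call. = FALSE)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr_backbone = lr_backbone, lr_adapters = lr_adapters,
    lr_decoder = lr_decoder, weight_decay = weight_decay,
    beta1 = beta1, beta2 = beta2,
    plateau_factor = plateau_factor,
    plateau_patience = as.integer(plateau_patience),
    regime = regime, seed = as.integer(seed), threshold = threshold,
    max_steps = max_steps
  ), class = "train_config")
}

#' Augmentation policy
#'
#' The training-time policy: rotations within +/-10 degrees, horizontal
#' flip with probability 0.5, multiplicative intensity scaling and additive
#' Gaussian noise (sd 0.01 on the normalized intensity scale).
#'
#' @param rotate_deg maximum absolute rotation in degrees
#' @param hflip_prob horizontal flip probability
#' @param intensity_range multiplicative scale range (uniform)
#' @param noise_sd Gaussian noise standard deviation
#' @param enabled master switch; disabled policies are identity maps
#' @return object of class `augment_policy`
#' @export
augment_policy <- function(rotate_deg = 10, hflip_prob = 0.5,
                           intensity_range = c(0.9, 1.1), noise_sd = 0.01,
                           enabled = TRUE) {
  structure(list(rotate_deg = rotate_deg, hflip_prob = hflip_prob,
                 intensity_range = intensity_range, noise_sd = noise_sd,
                 enabled = isTRUE(enabled)),
            class = "augment_policy")
}

#' Read a model/training configuration from a YAML file
#'
#' Recognized top-level sections: `backbone:`, `decoder:`, `loss:`,
#' `train:`, `augment:`, `phantom:`; each maps 1:1 onto the corresponding
#' constructor's arguments. Missing sections fall back to defaults.
#'
#' @param path YAML file
#' @return named list of configuration objects
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    do.call(ctor, args)
  }
  list(
    backbone = build("backbone", backbone_config),
    decoder = build("decoder", decoder_config),
    loss = build("loss", loss_config),
    train = build("train", train_config),
    augment = build("augment", augment_policy),
    phantom = if (!is.null(raw$phantom)) do.call(phantom_spec, raw$phantom)
              else NULL
  )
}
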