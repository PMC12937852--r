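# Shared tiny fixtures: models small enough for exhaustive numeric checks.

tiny_backbone <- function(adapter_layers = c(1L, 2L), img_size = 16L,
                          patch_size = 4L, depth = 2L, embed_dim = 8L,
                          num_register_tokens = 0L) {
  backbone_config(
    patch_size = patch_size, embed_dim = embed_dim, depth = depth,
    num_heads = 2L, adapter_layers = adapter_layers,
    adapter_bottleneck = 4L, num_register_tokens = num_register_tokens,
    img_size = img_size)
}

tiny_decoder <- function(...) {
  decoder_config(branch_channels = 4L, stage_channels = c(8L, 8L, 4L, 4L),
                 attention_reduction = 2L, spatial_kernel = 3L, ...)
}

tiny_model <- function(seed = 1, ...) {
  strokevit_model(tiny_backbone(...), tiny_decoder(), seed = seed)
}

rand_image <- function(size = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(size * size * 3), c(size, size, 3L))
}

# random CHW array
rand_chw <- function(C, h, w) array(stats::rnorm(C * h * w), c(C, h, w))

# the functional-training backbone: depth 4, dim 64, patch 8
overfit_model <- function(img_size = 32L, seed = 2) {
  strokevit_model(
    backbone_config(patch_size = 8L, embed_dim = 64L, depth = 4L,
                    num_heads = 4L, adapter_layers = c(2L, 4L),
                    adapter_bottleneck = 16L, num_register_tokens = 0L,
                    img_size = img_size),
    decoder_config(branch_channels = 16L, stage_channels = c(32L, 16L, 8L, 8L),
                   attention_reduction = 4L, spatial_kernel = 7L),
    seed = seed)
}
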