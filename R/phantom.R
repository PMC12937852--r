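# ---------------------------------------------------------------------------
# Deterministic brain-phantom generator. Each slice carries an elliptical
# brain region (smooth plateau near 0.5 with a soft rim), low-frequency
# texture, and 0-3 blob lesions (unions of overlapping discs) whose
# intensity is shifted by a modality-dependent contrast: faint for
# NCCT-like volumes, bright for DWI-like ones. The mask is the exact
# lesion support. Every volume is fully determined by (seed, volume
# index), independent of generation order.
# ---------------------------------------------------------------------------

#' Phantom dataset specification
#'
#' Defaults describe the desk-scale study conditions: 64x64 slices, 6
#' slices per volume, up to 3 lesions of radius 3-7 voxels, additive
#' Gaussian noise of sd 0.02, and lesion contrast +0.05 for NCCT-like
#' volumes (subtle, near the noise floor) versus +0.40 for DWI-like
#' volumes (bright, sharply delineated).
#'
#' @param n_volumes number of volumes
#' @param slices_per_volume axial slices per volume
#' @param image_size slice edge in voxels
#' @param modality "dwi_like" or "ncct_like"
#' @param lesions_range inclusive range of lesion count per volume
#' @param lesion_radius inclusive disc radius range in voxels
#' @param lesion_contrast intensity shift inside lesions; default depends
#'   on modality
#' @param noise_sd additive Gaussian noise sd
#' @param texture_amp amplitude of the low-frequency background texture
#' @param spacing per-axis voxel spacing written to NIfTI headers
#' @param seed base RNG seed; volume i is a pure function of (seed, i)
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(n_volumes = 10L, slices_per_volume = 6L,
                         image_size = 64L,
                         modality = c("dwi_like", "ncct_like"),
                         lesions_range = c(0L, 3L),
                         lesion_radius = c(3, 7),
                         lesion_contrast = NULL,
                         noise_sd = 0.02, texture_amp = 0.03,
                         spacing = c(1, 1, 5), seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(lesion_contrast)) {
    lesion_contrast <- if (modality == "dwi_like") 0.40 else 0.05
  }
  if (lesion_contrast <= 0) stop("lesion_contrast must be > 0", call. = FALSE)
  image_size <- as.integer(image_size)
  # the smaller brain semi-axis is ~0.36 of the edge; a lesion disc larger
  # than that cannot fit inside the brain ellipse at all
  if (max(lesion_radius) >= 0.36 * 0.95 * image_size) {
    stop("lesion radius range does not fit inside the brain ellipse",
         call. = FALSE)
  }
  structure(list(
    n_volumes = as.integer(n_volumes),
    slices_per_volume = as.integer(slices_per_volume),
    image_size = image_size, modality = modality,
    lesions_range = as.integer(lesions_range),
    lesion_radius = lesion_radius, lesion_contrast = lesion_contrast,
    noise_sd = noise_sd, texture_amp = texture_amp,
    spacing = spacing, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Generate one phantom volume
#'
#' @param spec a [phantom_spec()]
#' @param volume_index 1-based volume index; with `spec$seed` it fully
#'   determines the output
#' @return list with `image` (H x W x S array), `mask` (exact lesion
#'   support, same shape), `clean` (image before noise), `base` (image
#'   before lesions and noise), `spacing`, `id`
#' @export
generate_volume <- function(spec, volume_index) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed((spec$seed %% 65536L) * 32749L + volume_index * 7919L)
  n <- spec$image_size
  S <- spec$slices_per_volume
  ci <- (n + 1) / 2; cj <- (n + 1) / 2
  a <- 0.42 * n * stats::runif(1, 0.95, 1.05)  # semi-axis, rows
  b <- 0.36 * n * stats::runif(1, 0.95, 1.05)  # semi-axis, cols
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  r2 <- ((ii - ci) / a)^2 + ((jj - cj) / b)^2
  brain <- r2 <= 1
  # smooth rim: cosine roll-off over the outer 15% of the radial coordinate
  prof <- ifelse(r2 <= 0.85, 1, 0.5 * (1 + cos(pi * pmin((r2 - 0.85) / 0.15, 1))))
  prof[!brain] <- 0
  base_slice <- function() {
    tex <- matrix(0, n, n)
    for (k in 1:3) {
      fr <- stats::runif(2, 0.5, 2) * 2 * pi / n
      ph <- stats::runif(2, 0, 2 * pi)
      tex <- tex + cos(fr[1] * ii + ph[1]) * cos(fr[2] * jj + ph[2])
    }
    (0.5 + spec$texture_amp * tex / 3) * prof
  }
  safe_sample <- function(x, k) if (length(x) == 1L) rep(x, k) else sample(x, k)
  # lesion blueprints: centers well inside the ellipse, a contiguous slice
  # interval, and 1-4 overlapping discs each
  n_les <- safe_sample(seq(spec$lesions_range[1], spec$lesions_range[2]), 1L)
  lesions <- list()
  if (n_les > 0) {
    for (l in seq_len(n_les)) {
      repeat {
        li <- ci + stats::runif(1, -0.6, 0.6) * a
        lj <- cj + stats::runif(1, -0.6, 0.6) * b
        if (((li - ci) / a)^2 + ((lj - cj) / b)^2 < 0.36) break
      }
      ndisc <- safe_sample(1:4, 1L)
      discs <- lapply(seq_len(ndisc), function(d) {
        r <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
        list(i = li + stats::runif(1, -r / 2, r / 2),
             j = lj + stats::runif(1, -r / 2, r / 2), r = r)
      })
      s0 <- safe_sample(seq_len(S), 1L)
      s1 <- min(S, s0 + safe_sample(0:(S - 1L), 1L))
      lesions[[l]] <- list(discs = discs, slices = s0:s1)
    }
  }
  image <- array(0, c(n, n, S))
  clean <- array(0, c(n, n, S))
  base <- array(0, c(n, n, S))
  mask <- array(0, c(n, n, S))
  for (s in seq_len(S)) {
    bs <- base_slice()
    ms <- matrix(FALSE, n, n)
    for (l in lesions) {
      if (!(s %in% l$slices)) next
      for (d in l$discs) {
        ms <- ms | (((ii - d$i)^2 + (jj - d$j)^2) <= d$r^2)
      }
    }
    ms <- ms & brain  # lesions never extend outside the brain
    cs <- bs + spec$lesion_contrast * ms
    base[, , s] <- bs
    clean[, , s] <- cs
    mask[, , s] <- ms * 1
    image[, , s] <- cs + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
  }
  list(image = image, mask = mask, clean = clean, base = base,
       spacing = spec$spacing,
       id = sprintf("phantom_%03d", volume_index))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a phantom dataset in memory
#'
#' @param spec a [phantom_spec()]
#' @return list of volumes from [generate_volume()]
#' @export
generate_dataset <- function(spec) {
  lapply(seq_len(spec$n_volumes), function(i) generate_volume(spec, i))
}

#' Write a phantom dataset as NIfTI pairs with a manifest
#'
#' Writes `<id>_image.nii.gz` / `<id>_label.nii.gz` per volume plus
#' `manifest.csv` with columns volume_id, image, label, split. The
#' 70/15/15 train/val/test split is assigned by volume (never by slice)
#' deterministically from `spec$seed`.
#'
#' @param spec a [phantom_spec()]
#' @param out_dir output directory (created if needed)
#' @return the manifest data frame (invisibly also written to CSV)
#' @export
write_dataset <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", spec$n_volumes)
  for (i in seq_len(spec$n_volumes)) {
    v <- generate_volume(spec, i)
    ip <- file.path(out_dir, sprintf("%s_image.nii.gz", v$id))
    lp <- file.path(out_dir, sprintf("%s_label.nii.gz", v$id))
    img_n <- RNifti::asNifti(v$image)
    RNifti::pixdim(img_n) <- spec$spacing
    lab_n <- RNifti::asNifti(v$mask)
    RNifti::pixdim(lab_n) <- spec$spacing
    RNifti::writeNifti(img_n, ip)
    RNifti::writeNifti(lab_n, lp)
    rows[[i]] <- data.frame(volume_id = v$id, image = ip, label = lp)
  }
  manifest <- do.call(rbind, rows)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  ord <- sample(spec$n_volumes)
  n_train <- max(1L, floor(0.7 * spec$n_volumes))
  n_val <- max(1L, floor(0.15 * spec$n_volumes))
  split <- rep("test", spec$n_volumes)
  split[ord[seq_len(n_train)]] <- "train"
  if (n_train + n_val <= spec$n_volumes) {
    split[ord[(n_train + 1L):(n_train + n_val)]] <- "val"
  }
  manifest$split <- split
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
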