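# ---------------------------------------------------------------------------
# Data pipeline: NIfTI ingestion, label mapping, per-slice normalization,
# resizing, and the training augmentation policy. Axial slices are indexed
# along the last NIfTI axis; image resampling is bilinear, mask resampling
# nearest-neighbour with re-binarization, and image and mask always receive
# the same geometric transform.
# ---------------------------------------------------------------------------

#' Load an image volume and its label volume
#'
#' @param image_path NIfTI file (.nii or .nii.gz)
#' @param label_path matching integer label volume
#' @param id optional volume identifier (defaults to the file name)
#' @return list with `image` (3D array), `labels` (3D array), `spacing`
#'   (per-axis mm/voxel from the header), `id`
#' @export
load_volume <- function(image_path, label_path, id = NULL) {
  if (!file.exists(image_path)) {
    stop(sprintf("image file not found: %s", image_path), call. = FALSE)
  }
  if (!file.exists(label_path)) {
    stop(sprintf("label file not found: %s", label_path), call. = FALSE)
  }
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(label_path)
  if (!identical(dim(img), dim(lab))) {
    stop(sprintf("image %s and labels %s have different shapes",
                 image_path, label_path), call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  list(image = unclass(img)[, , , drop = FALSE],
       labels = unclass(lab)[, , , drop = FALSE],
       spacing = as.numeric(spacing),
       id = if (is.null(id)) basename(image_path) else id)
}

#' Map integer labels to a binary lesion mask
#'
#' Scheme `"aisd"` marks the multi-class infarct labels 1, 2, 3 and 5 as
#' positive and everything else (including label 4) as background; scheme
#' `"binary"` marks any nonzero label positive.
#'
#' @param labels integer array
#' @param scheme "aisd" or "binary"
#' @return array of 0/1 with the shape of `labels`
#' @export
map_labels <- function(labels, scheme = c("aisd", "binary")) {
  scheme <- match.arg(scheme)
  out <- labels
  out[] <- if (scheme == "aisd") as.numeric(labels %in% c(1, 2, 3, 5))
           else as.numeric(labels != 0)
  out
}

# clip + min-max to [0,1]; constant slices map to zeros
to_unit <- function(slice, modality) {
  x <- slice
  if (modality == "ncct") {
    x <- pmin(pmax(x, 0), 80)
  } else {
    lo <- stats::quantile(x, 0.005, names = FALSE)
    hi <- stats::quantile(x, 0.995, names = FALSE)
    x <- pmin(pmax(x, lo), hi)
  }
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    x[] <- 0
  } else {
    x <- (x - rng[1]) / (rng[2] - rng[1])
  }
  x
}

#' Normalize a 2D slice for the network
#'
#' NCCT slices are clipped to the 0--80 HU brain window; DWI and phantom
#' slices to their 0.5/99.5 intensity percentiles. The clipped slice is
#' min-max scaled to \[0,1\] (a constant slice maps to zeros), replicated
#' to 3 channels, and standardized with the given per-channel mean/sd.
#'
#' @param slice 2D numeric matrix
#' @param modality "ncct", "dwi" or "phantom"
#' @param mean,sd standardization constants
#' @return array of dim (H, W, 3)
#' @export
normalize_slice <- function(slice, modality = c("dwi", "ncct", "phantom"),
                            mean = 0.5, sd = 0.5) {
  modality <- match.arg(modality)
  x <- to_unit(slice, modality)
  x <- (x - mean) / sd
  array(x, c(dim(x), 3L))[, , c(1L, 1L, 1L)]
}

# bilinear sampling at fractional coordinates; outside-image reads are 0
sample_bilinear <- function(m, si, sj) {
  h <- nrow(m); w <- ncol(m)
  i0 <- floor(si); j0 <- floor(sj)
  ti <- si - i0; tj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    v <- numeric(length(ii))
    v[ok] <- m[cbind(ii[ok], jj[ok])]
    v
  }
  (1 - ti) * (1 - tj) * val(i0, j0) + (1 - ti) * tj * val(i0, j0 + 1) +
    ti * (1 - tj) * val(i0 + 1, j0) + ti * tj * val(i0 + 1, j0 + 1)
}

sample_nearest <- function(m, si, sj) {
  h <- nrow(m); w <- ncol(m)
  ii <- round(si); jj <- round(sj)
  ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
  v <- numeric(length(ii))
  v[ok] <- m[cbind(ii[ok], jj[ok])]
  v
}

#' Rotate a 2D slice about its center
#'
#' @param m numeric matrix
#' @param degrees rotation angle
#' @param method "bilinear" (images) or "nearest" (masks); out-of-image
#'   samples are 0
#' @return rotated matrix, same shape
#' @export
rotate_slice <- function(m, degrees, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (degrees == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  th <- degrees * pi / 180
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  io <- rep(seq_len(h), times = w) - ci
  jo <- rep(seq_len(w), each = h) - cj
  si <- ci + cos(th) * io - sin(th) * jo
  sj <- cj + sin(th) * io + cos(th) * jo
  v <- if (method == "bilinear") sample_bilinear(m, si, sj)
       else sample_nearest(m, si, sj)
  matrix(v, h, w)
}

#' Apply the training augmentation policy to one slice pair
#'
#' One rotation angle drawn uniformly from the configured range is applied
#' identically to image (bilinear) and mask (nearest, re-binarized); a
#' horizontal flip with the configured probability is applied to both; the
#' multiplicative intensity scale and additive Gaussian noise touch the
#' image only. Operates on the \[0,1\] normalized intensity scale and is
#' deterministic given the R RNG state.
#'
#' @param pair list with `image` (2D matrix, \[0,1\] scale) and `mask`
#'   (binary matrix); other fields pass through
#' @param policy an [augment_policy()]
#' @return augmented pair
#' @export
augment <- function(pair, policy = augment_policy()) {
  if (!policy$enabled) return(pair)
  img <- pair$image
  msk <- pair$mask
  ang <- stats::runif(1, -policy$rotate_deg, policy$rotate_deg)
  img <- rotate_slice(img, ang, "bilinear")
  msk <- (rotate_slice(msk, ang, "nearest") > 0.5) * 1
  if (stats::runif(1) < policy$hflip_prob) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  scale <- stats::runif(1, policy$intensity_range[1], policy$intensity_range[2])
  img <- img * scale +
    matrix(stats::rnorm(length(img), sd = policy$noise_sd),
           nrow(img), ncol(img))
  pair$image <- img
  pair$mask <- msk
  pair
}

#' Extract axial slice pairs from loaded volumes
#'
#' Training mode keeps slices whose nonzero (brain) area exceeds
#' `brain_threshold` of the slice; evaluation mode keeps every slice so
#' stacked predictions align with the ground-truth volume.
#'
#' @param volumes list of volumes as returned by [load_volume()], each with
#'   a binary `mask` field (see [map_labels()]); a `labels` field is mapped
#'   with `scheme` when `mask` is absent
#' @param mode "train" or "eval"
#' @param brain_threshold minimum nonzero-area fraction in training mode
#' @param scheme label-mapping scheme used when needed
#' @return list of slice pairs: `image` (2D), `mask` (binary 2D),
#'   `volume_id`, `slice_index`, `spacing`
#' @export
slice_dataset <- function(volumes, mode = c("train", "eval"),
                          brain_threshold = 0.01, scheme = "binary") {
  mode <- match.arg(mode)
  out <- list()
  for (v in volumes) {
    msk <- if (!is.null(v$mask)) v$mask else map_labels(v$labels, scheme)
    nz <- dim(v$image)[3]
    for (k in seq_len(nz)) {
      img <- v$image[, , k]
      if (mode == "train" &&
          mean(abs(img) > 1e-8) <= brain_threshold) next
      out[[length(out) + 1L]] <- list(
        image = img, mask = msk[, , k] * 1,
        volume_id = v$id, slice_index = k,
        spacing = v$spacing)
    }
  }
  out
}
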