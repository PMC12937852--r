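# ---------------------------------------------------------------------------
# Evaluation suite: Dice similarity coefficient, intersection over union,
# Hausdorff distance and its 95th percentile, volumetric difference
# percentage, and dataset-level volumetric correlation. Distances are
# computed literally over foreground voxel sets (interior voxels contribute
# zero when covered), scaled by the per-axis voxel spacing, with the 95th
# percentile taken by linear interpolation over the sorted directed
# distances.
# ---------------------------------------------------------------------------

#' Pair of foreground voxel sets
#'
#' @param pred,gt binary arrays (2D or 3D) of identical shape, or -- with
#'   `coords = TRUE` -- integer coordinate matrices (one voxel per row)
#' @param spacing per-axis physical voxel size (recycled to the number of
#'   axes; default 1)
#' @param coords interpret `pred`/`gt` as coordinate matrices
#' @return object of class `mask_pair` holding coordinate matrices `P`, `G`
#'   and `spacing`
#' @export
mask_pair <- function(pred, gt, spacing = 1, coords = FALSE) {
  to_coords <- function(x) {
    if (coords) {
      x <- as.matrix(x)
      storage.mode(x) <- "double"
      return(x)
    }
    which(x != 0, arr.ind = TRUE)
  }
  P <- to_coords(pred); G <- to_coords(gt)
  nd <- max(ncol(P), ncol(G), 2L)
  if (nrow(P) && nrow(G) && ncol(P) != ncol(G)) {
    stop("pred and gt have different dimensionality", call. = FALSE)
  }
  spacing <- rep_len(spacing, nd)
  structure(list(P = P, G = G, spacing = spacing), class = "mask_pair")
}

voxel_keys <- function(M) {
  if (!nrow(M)) return(character(0))
  apply(M, 1L, paste, collapse = ",")
}

#' Dice similarity coefficient and intersection over union
#'
#' `DSC = 2|P∩G| / (|P|+|G|)`, `IoU = |P∩G| / |P∪G|`. Both return 1 when
#' prediction and ground truth are both empty.
#'
#' @param pair a [mask_pair()]
#' @return named numeric `c(dice, iou)`
#' @export
dsc_iou <- function(pair) {
  np <- nrow(pair$P); ng <- nrow(pair$G)
  if (np == 0L && ng == 0L) return(c(dice = 1, iou = 1))
  ninter <- length(intersect(voxel_keys(pair$P), voxel_keys(pair$G)))
  nunion <- np + ng - ninter
  c(dice = 2 * ninter / (np + ng), iou = ninter / nunion)
}

# all directed distances from rows of A to the set B, spacing-scaled
directed_dists <- function(A, B, spacing) {
  As <- sweep(A, 2L, spacing, "*")
  Bs <- sweep(B, 2L, spacing, "*")
  nB <- nrow(Bs)
  b2 <- rowSums(Bs^2)
  out <- numeric(nrow(As))
  chunk <- max(1L, floor(2e7 / nB))
  for (start in seq(1L, nrow(As), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(As))
    cross <- As[idx, , drop = FALSE] %*% t(Bs)
    d2 <- rowSums(As[idx, , drop = FALSE]^2) - 2 * cross +
      matrix(b2, length(idx), nB, byrow = TRUE)
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Hausdorff distance and its 95th-percentile variant
#'
#' `HD = max(max_p d(p,G), max_g d(g,P))` and `HD95` is the larger of the
#' two directed 95th percentiles (linear interpolation over the sorted
#' directed distances), with `d` the spacing-scaled Euclidean
#' nearest-neighbour distance. Both are 0 when both sets are empty, and
#' undefined (NA) when exactly one set is empty.
#'
#' @param pair a [mask_pair()]
#' @return named numeric `c(hd, hd95)` in physical units
#' @export
hd_hd95 <- function(pair) {
  np <- nrow(pair$P); ng <- nrow(pair$G)
  if (np == 0L && ng == 0L) return(c(hd = 0, hd95 = 0))
  if (np == 0L || ng == 0L) return(c(hd = NA_real_, hd95 = NA_real_))
  dpg <- directed_dists(pair$P, pair$G, pair$spacing)
  dgp <- directed_dists(pair$G, pair$P, pair$spacing)
  c(hd = max(max(dpg), max(dgp)),
    hd95 = max(stats::quantile(dpg, 0.95, names = FALSE, type = 7),
               stats::quantile(dgp, 0.95, names = FALSE, type = 7)))
}

#' Volumetric difference percentage
#'
#' The share of ground-truth lesion volume not covered by the prediction:
#' `(|G| - |P∩G|) / |G| * 100`. Undefined (NA) for empty ground truth.
#' False-positive voxels outside G do not change VDP.
#'
#' @param pair a [mask_pair()]
#' @return percentage in \[0, 100\], or NA
#' @export
vdp <- function(pair) {
  ng <- nrow(pair$G)
  if (ng == 0L) return(NA_real_)
  ninter <- length(intersect(voxel_keys(pair$P), voxel_keys(pair$G)))
  (ng - ninter) / ng * 100
}

#' Volumetric correlation
#'
#' Pearson correlation of predicted vs ground-truth foreground voxel counts
#' across the dataset. Undefined (NA) with fewer than two volumes or zero
#' variance in either list.
#'
#' @param volumes_pred,volumes_gt numeric vectors of voxel counts
#' @return correlation in \[-1, 1\], or NA
#' @export
vc <- function(volumes_pred, volumes_gt) {
  if (length(volumes_pred) != length(volumes_gt)) {
    stop("volume lists differ in length", call. = FALSE)
  }
  if (length(volumes_pred) < 2L) return(NA_real_)
  if (stats::sd(volumes_pred) == 0 || stats::sd(volumes_gt) == 0) {
    return(NA_real_)
  }
  stats::cor(volumes_pred, volumes_gt)
}

#' Evaluate a dataset of predicted vs ground-truth volumes
#'
#' Computes per-volume DSC, IoU, HD, HD95 and VDP on the 3D masks, plus the
#' dataset-level volumetric correlation. Volumes whose HD or VDP is
#' undefined (one-sided empty masks) keep NA in that cell and are excluded
#' from the corresponding mean. Mismatched volumes are skipped with a
#' recorded error.
#'
#' @param pred_volumes,gt_volumes lists of binary arrays
#' @param spacings list of per-axis spacings (recycled; default unit)
#' @param ids optional volume identifiers
#' @return object of class `metric_report`: `per_volume` data frame,
#'   `summary` named vector of means plus `vc`, and `errors`
#' @export
evaluate_dataset <- function(pred_volumes, gt_volumes, spacings = NULL,
                             ids = NULL) {
  n <- length(pred_volumes)
  if (length(gt_volumes) != n) {
    stop("prediction and ground-truth lists differ in length", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("vol", seq_len(n))
  rows <- vector("list", n)
  errors <- character(0)
  for (i in seq_len(n)) {
    sp <- if (is.null(spacings)) 1 else spacings[[i]]
    res <- tryCatch({
      if (!identical(dim(pred_volumes[[i]]), dim(gt_volumes[[i]]))) {
        stop("shape mismatch between prediction and ground truth")
      }
      pair <- mask_pair(pred_volumes[[i]], gt_volumes[[i]], spacing = sp)
      ov <- dsc_iou(pair)
      hd <- hd_hd95(pair)
      data.frame(id = ids[i], dice = ov[["dice"]], iou = ov[["iou"]],
                 hd = hd[["hd"]], hd95 = hd[["hd95"]], vdp = vdp(pair),
                 vol_pred = nrow(pair$P), vol_gt = nrow(pair$G))
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", ids[i], conditionMessage(e)))
      NULL
    })
    rows[[i]] <- res
  }
  per <- do.call(rbind, rows)
  summ <- c(
    dice = mean(per$dice, na.rm = TRUE),
    iou = mean(per$iou, na.rm = TRUE),
    hd = mean(per$hd, na.rm = TRUE),
    hd95 = mean(per$hd95, na.rm = TRUE),
    vdp = mean(per$vdp, na.rm = TRUE),
    vc = vc(per$vol_pred, per$vol_gt)
  )
  structure(list(per_volume = per, summary = summ, errors = errors),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d volumes", nrow(x$per_volume)))
  if (length(x$errors)) cat(sprintf(" (%d skipped)", length(x$errors)))
  cat("\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Write a metric report to CSV
#'
#' One row per volume plus a `summary` row holding the dataset means and
#' the volumetric correlation.
#'
#' @param report a `metric_report`
#' @param path output CSV path
#' @export
write_metric_report <- function(report, path) {
  per <- report$per_volume
  per$vc <- NA_real_
  summary_row <- data.frame(
    id = "summary", dice = report$summary[["dice"]],
    iou = report$summary[["iou"]], hd = report$summary[["hd"]],
    hd95 = report$summary[["hd95"]], vdp = report$summary[["vdp"]],
    vol_pred = NA_real_, vol_gt = NA_real_,
    vc = report$summary[["vc"]])
  utils::write.csv(rbind(per, summary_row), path, row.names = FALSE)
  invisible(path)
}
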