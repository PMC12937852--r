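test_that("overlap metrics reproduce set-counting examples", {
  m <- matrix(0, 3, 3)
  a <- m; a[1, 1] <- 1; a[1, 2] <- 1
  b <- m; b[1, 2] <- 1; b[2, 2] <- 1
  pair <- mask_pair(a, b)
  ov <- dsc_iou(pair)
  expect_equal(ov[["dice"]], 0.5)
  expect_equal(ov[["iou"]], 1 / 3)
  expect_equal(dsc_iou(mask_pair(a, a)), c(dice = 1, iou = 1))
  expect_equal(dsc_iou(mask_pair(m, m)), c(dice = 1, iou = 1))  # both empty
  d <- m; d[3, 3] <- 1
  expect_equal(dsc_iou(mask_pair(a, d)), c(dice = 0, iou = 0))
})

test_that("hausdorff distances handle degenerate and single-point sets", {
  m <- matrix(0, 5, 6)
  a <- m; a[1, 1] <- 1
  b <- m; b[4, 5] <- 1  # offset (3, 4): distance 5
  expect_equal(hd_hd95(mask_pair(a, b)), c(hd = 5, hd95 = 5))
  expect_equal(hd_hd95(mask_pair(a, a)), c(hd = 0, hd95 = 0))
  expect_equal(hd_hd95(mask_pair(m, m)), c(hd = 0, hd95 = 0))
  one_sided <- hd_hd95(mask_pair(a, m))
  expect_true(all(is.na(one_sided)))
})

test_that("voxel spacing scales distances anisotropically", {
  m <- matrix(0, 4, 4)
  a <- m; a[1, 1] <- 1
  b <- m; b[1, 2] <- 1  # one step along the second axis
  expect_equal(hd_hd95(mask_pair(a, b, spacing = c(1, 2.5)))[["hd"]], 2.5)
})

test_that("metric suite matches the brute-force oracle on random masks", {
  set.seed(9)
  for (rep in 1:50) {
    dims <- c(sample(3:6, 1), sample(3:6, 1))
    p <- matrix(rbinom(prod(dims), 1, runif(1, 0.1, 0.6)), dims[1])
    g <- matrix(rbinom(prod(dims), 1, runif(1, 0.1, 0.6)), dims[1])
    sp <- sample(c(1, 1, 2), 2, replace = TRUE)
    ref <- oracle_metrics(p, g, sp)
    pair <- mask_pair(p, g, spacing = sp)
    ov <- dsc_iou(pair)
    hd <- hd_hd95(pair)
    expect_equal(ov[["dice"]], ref[["dice"]], tolerance = 1e-9)
    expect_equal(ov[["iou"]], ref[["iou"]], tolerance = 1e-9)
    if (!is.na(ref[["hd"]])) {
      expect_equal(hd[["hd"]], ref[["hd"]], tolerance = 1e-9)
      expect_equal(hd[["hd95"]], ref[["hd95"]], tolerance = 1e-9)
    }
    if (!is.na(ref[["vdp"]])) {
      expect_equal(vdp(pair), ref[["vdp"]], tolerance = 1e-9)
    }
  }
})

test_that("dice dominates iou and hd95 never exceeds hd", {
  set.seed(10)
  for (rep in 1:30) {
    p <- array(rbinom(4 * 4 * 3, 1, 0.3), c(4, 4, 3))
    g <- array(rbinom(4 * 4 * 3, 1, 0.3), c(4, 4, 3))
    pair <- mask_pair(p, g)
    ov <- dsc_iou(pair)
    expect_gte(ov[["dice"]], ov[["iou"]])
    if (!(ov[["dice"]] %in% c(0, 1))) expect_gt(ov[["dice"]], ov[["iou"]])
    hd <- hd_hd95(pair)
    if (!is.na(hd[["hd"]])) expect_lte(hd[["hd95"]], hd[["hd"]])
    # symmetry in (P, G)
    rev <- hd_hd95(mask_pair(g, p))
    if (!is.na(hd[["hd"]])) expect_equal(hd, rev)
  }
})

test_that("vdp ignores false positives and counts missed volume", {
  g <- matrix(0, 4, 4); g[1:2, 1:2] <- 1            # |G| = 4
  p_sup <- matrix(1, 4, 4)                          # P superset of G
  expect_equal(vdp(mask_pair(p_sup, g)), 0)
  p_part <- matrix(0, 4, 4); p_part[1, 1] <- 1      # covers 1 of 4
  expect_equal(vdp(mask_pair(p_part, g)), 75)
  expect_equal(vdp(mask_pair(matrix(0, 4, 4), g)), 100)
  expect_true(is.na(vdp(mask_pair(g, matrix(0, 4, 4)))))
  # adding false positives leaves vdp unchanged
  set.seed(11)
  for (rep in 1:20) {
    g <- matrix(rbinom(25, 1, 0.4), 5)
    if (sum(g) == 0) next
    p <- matrix(rbinom(25, 1, 0.3), 5)
    p2 <- p
    p2[g == 0] <- pmin(p2[g == 0] + rbinom(sum(g == 0), 1, 0.5), 1)
    expect_equal(vdp(mask_pair(p2, g)), vdp(mask_pair(p, g)))
  }
})

test_that("volumetric correlation follows the pearson definition", {
  expect_equal(vc(c(3, 5, 9), c(3, 5, 9)), 1)
  expect_equal(vc(2 * c(3, 5, 9) + 5, c(3, 5, 9)), 1)
  expect_equal(vc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(vc(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(vc(1, 2)))
  set.seed(12)
  vp <- rpois(8, 40); vg <- rpois(8, 40)
  expect_equal(vc(vp, vg), oracle_pearson(vp, vg), tolerance = 1e-9)
})

test_that("axis permutation with isotropic spacing leaves metrics unchanged", {
  set.seed(13)
  p <- array(rbinom(60, 1, 0.3), c(3, 4, 5))
  g <- array(rbinom(60, 1, 0.3), c(3, 4, 5))
  a1 <- c(dsc_iou(mask_pair(p, g)), hd_hd95(mask_pair(p, g)))
  pp <- aperm(p, c(3, 1, 2)); gp <- aperm(g, c(3, 1, 2))
  a2 <- c(dsc_iou(mask_pair(pp, gp)), hd_hd95(mask_pair(pp, gp)))
  expect_equal(a1, a2)
})

test_that("dataset evaluation aggregates per-volume metrics and vc", {
  set.seed(14)
  gts <- lapply(1:4, function(i) array(rbinom(4 * 4 * 2, 1, 0.3), c(4, 4, 2)))
  rep1 <- evaluate_dataset(gts, gts)
  expect_equal(rep1$summary[["dice"]], 1)
  expect_equal(rep1$summary[["hd95"]], 0)
  expect_equal(rep1$summary[["vdp"]], 0)
  expect_equal(rep1$summary[["vc"]], 1)
  # single volume: vc undefined
  rep2 <- evaluate_dataset(gts[1], gts[1])
  expect_true(is.na(rep2$summary[["vc"]]))
  # mismatched shapes are skipped and recorded
  bad <- list(array(0, c(3, 3, 2)))
  rep3 <- evaluate_dataset(c(gts[1], bad), list(gts[[1]], gts[[2]]))
  expect_length(rep3$errors, 1)
  expect_equal(nrow(rep3$per_volume), 1)
})

test_that("metric report round-trips through CSV", {
  set.seed(15)
  gts <- lapply(1:3, function(i) array(rbinom(32, 1, 0.4), c(4, 4, 2)))
  preds <- lapply(gts, function(g) {
    p <- g; p[1, 1, 1] <- 1 - p[1, 1, 1]; p
  })
  rep <- evaluate_dataset(preds, gts)
  path <- tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 4)  # 3 volumes + summary row
  expect_equal(back$dice[1:3], rep$per_volume$dice)
  expect_equal(back$vc[4], rep$summary[["vc"]])
})
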