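solid_rgb <- function(h, w, rgb) {
  a <- array(0, c(h, w, 3))
  a[, , 1] <- rgb[1]; a[, , 2] <- rgb[2]; a[, , 3] <- rgb[3]
  a
}

test_that("HSV tissue detection finds stained blocks and ignores glass", {
  glass <- solid_rgb(64, 64, c(250, 250, 250))         # saturation ~0
  expect_false(any(tissue_mask_hsv(glass, min_hole = 4, min_object = 4)$pixels))
  tile <- solid_rgb(150, 150, c(250, 250, 250))
  tile[26:125, 26:125, 1] <- 230; tile[26:125, 26:125, 2] <- 120
  tile[26:125, 26:125, 3] <- 170                        # pink, high saturation
  tm <- tissue_mask_hsv(tile, min_hole = 4, min_object = 4)
  want <- matrix(FALSE, 150, 150); want[26:125, 26:125] <- TRUE
  expect_identical(tm$pixels, want)                     # exact block, +-0 px
  pink <- solid_rgb(32, 32, c(230, 120, 170))
  expect_true(all(tissue_mask_hsv(pink, min_hole = 0, min_object = 0)$pixels))
  expect_warning(tissue_mask_hsv(pink, lo = c(0, 0.5, 0), hi = c(0, 0.5, 0)),
                 "degenerate")
})

test_that("hole filling and clump removal respect their size cut-offs", {
  tile <- solid_rgb(60, 60, c(250, 250, 250))
  tile[11:50, 11:50, 2] <- 120                          # big tissue block
  tile[30:31, 30:31, 2] <- 250                          # 4-px hole
  tile[2:3, 2:3, 2] <- 120                              # 4-px clump
  tm <- tissue_mask_hsv(tile, min_hole = 10, min_object = 10)
  expect_true(all(tm$pixels[30:31, 30:31]))             # hole filled
  expect_false(any(tm$pixels[2:3, 2:3]))                # clump removed
})

test_that("Otsu picks the darker class and matches a naive variance search", {
  bi <- matrix(rep(c(0, 255), each = 200), 20, 20)
  tm <- tissue_mask_otsu(bi)
  expect_identical(tm$pixels, bi == 0)
  expect_identical(tissue_mask_otsu(255 - bi)$pixels, bi == 255)
  set.seed(2)
  g <- matrix(pmin(pmax(c(rnorm(400, 60, 10), rnorm(400, 200, 10)), 0), 255),
              20, 40)
  # independent oracle: minimise weighted within-class variance directly
  v <- as.vector(round(g))
  wcv <- vapply(1:254, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(Inf)
    (length(lo) * stats::var(lo) * (length(lo) - 1) / length(lo) +
     length(hi) * stats::var(hi) * (length(hi) - 1) / length(hi))
  }, numeric(1))
  t_oracle <- which.min(wcv)
  tm2 <- tissue_mask_otsu(g)
  t_pkg <- max(g[tm2$pixels])                            # implied threshold
  expect_gt(t_pkg, 60); expect_lt(t_pkg, 200)
  expect_lt(abs(t_pkg - t_oracle), 3)
  expect_error(tissue_mask_otsu(matrix(7, 5, 5)),
               class = "histofuse_degenerate_image")
})

test_that("bounding boxes are exact, half-open and scale-aware", {
  m <- matrix(FALSE, 20, 20)
  m[3:6, 4:9] <- TRUE
  m[12:15, 14:17] <- TRUE
  tm <- structure(list(pixels = m, scale = 1L), class = "tissue_mask")
  bb <- tissue_bounding_boxes(tm)
  expect_equal(nrow(bb), 2)
  expect_equal(unlist(bb[1, c("r0", "r1", "c0", "c1")]),
               c(r0 = 2, r1 = 6, c0 = 3, c1 = 9))
  tm2 <- structure(list(pixels = m, scale = 4L), class = "tissue_mask")
  expect_equal(tissue_bounding_boxes(tm2)$r1[1], 24)
  empty <- structure(list(pixels = matrix(FALSE, 4, 4), scale = 1L),
                     class = "tissue_mask")
  expect_equal(nrow(tissue_bounding_boxes(empty)), 0)
  full <- structure(list(pixels = matrix(TRUE, 6, 8), scale = 1L),
                    class = "tissue_mask")
  expect_equal(unlist(tissue_bounding_boxes(full)[1, c("r0", "r1", "c0", "c1")]),
               c(r0 = 0, r1 = 6, c0 = 0, c1 = 8))
})

test_that("grid extraction yields floor(box/stride)^2 patches, crops bit-exact", {
  set.seed(3)
  img <- array(runif(480 * 480 * 3, 0, 255), c(480, 480, 3))
  boxes <- tibble::tibble(r0 = 16, r1 = 16 + 448, c0 = 16, c1 = 16 + 448)
  g <- extract_patches_grid(img, boxes, size = 224, stride = 224)
  expect_equal(nrow(g), 4)                               # floor(448/224)^2
  for (i in seq_len(nrow(g))) {
    expect_identical(g$pixels[[i]],
                     img[(g$row[i] + 1):(g$row[i] + 224),
                         (g$col[i] + 1):(g$col[i] + 224), , drop = FALSE])
  }
  small <- tibble::tibble(r0 = 0, r1 = 100, c0 = 0, c1 = 100)
  expect_equal(nrow(extract_patches_grid(img, small, size = 224)), 0)
})

test_that("random extraction is seeded, uniform over valid origins", {
  img <- array(200, c(64, 64, 3))
  tm <- structure(list(pixels = matrix(TRUE, 64, 64), scale = 1L),
                  class = "tissue_mask")
  p <- extract_patches_random(img, tm, size = 16, n = 20, seed = 9)
  expect_equal(nrow(p), 20)
  p2 <- extract_patches_random(img, tm, size = 16, n = 20, seed = 9)
  expect_identical(p[, c("row", "col")], p2[, c("row", "col")])
  # a single size-sized tissue square leaves exactly one valid origin
  one <- matrix(FALSE, 64, 64); one[11:26, 21:36] <- TRUE
  tm1 <- structure(list(pixels = one, scale = 1L), class = "tissue_mask")
  expect_warning(
    q <- extract_patches_random(img, tm1, size = 16, n = 5,
                                min_tissue_frac = 1, seed = 1),
    "valid origins")
  expect_equal(nrow(q), 1)
  expect_equal(unlist(q[1, c("row", "col")]), c(row = 10, col = 20))
})

test_that("reinhard normalisation maps channel stats onto the target", {
  set.seed(8)
  ref <- array(runif(32 * 32 * 3, 80, 220), c(32, 32, 3))
  target <- reinhard_stats(ref)
  patch <- array(runif(24 * 24 * 3, 60, 250), c(24, 24, 3))
  out <- color_normalize(patch, "reinhard", target)
  got <- reinhard_stats(out)
  expect_true(all(abs(got$mean - target$mean) < 1))
  # a patch already at the target stats is (nearly) unchanged
  again <- color_normalize(out, "reinhard", target)
  expect_lt(max(abs(again - out)), 2)
  expect_warning(color_normalize(solid_rgb(8, 8, c(100, 100, 100)),
                                 "reinhard", target),
                 class = "histofuse_constant_patch")
  expect_error(color_normalize(patch, "reinhard"), "target_stats")
})

test_that("histogram equalisation spreads a two-level image to the extremes", {
  a <- solid_rgb(10, 10, c(100, 100, 100))
  a[1:5, , ] <- 60                      # levels 60 and 100, half and half
  out <- color_normalize(a, "hist_eq")
  expect_setequal(unique(as.vector(out)), c(0, 255))
  expect_true(all(out[1:5, , ] == 0) && all(out[6:10, , ] == 255))
  expect_true(all(out >= 0 & out <= 255))
})

test_that("isolation-forest filtering removes planted far outliers", {
  set.seed(13)
  X <- rbind(matrix(rnorm(95 * 4), 95), matrix(rnorm(5 * 4) + 10, 5))
  kept <- filter_patches_iforest(X, contamination = 0.05, seed = 1)
  expect_setequal(setdiff(seq_len(100), kept), 96:100)
  expect_equal(length(kept), ceiling(0.95 * 100))
  expect_identical(filter_patches_iforest(X, contamination = 0, seed = 1),
                   seq_len(100))
  expect_identical(kept, filter_patches_iforest(X, contamination = 0.05, seed = 1))
  expect_error(filter_patches_iforest(X, contamination = 0.6), "contamination")
  # keeps ceiling((1-c) n) across contamination levels
  for (cont in c(0.1, 0.25, 0.4)) {
    expect_equal(length(filter_patches_iforest(X, cont, seed = 2)),
                 ceiling((1 - cont) * 100))
  }
})

test_that("rotation balancing equalises classes without touching originals", {
  set.seed(21)
  px <- lapply(1:40, function(i) array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3)))
  patches <- tibble::tibble(row = 0L, col = 0L, size = 8L, pixels = px,
                            label = rep(c("oligodendroglioma", "astrocytoma"),
                                        c(10, 30)),
                            augmented = FALSE)
  bal <- balance_by_rotation(patches, seed = 4)
  expect_equal(unname(table(bal$label)["oligodendroglioma"]), 30)
  expect_equal(unname(table(bal$label)["astrocytoma"]), 30)
  expect_equal(sum(bal$augmented), 20)
  # all originals still present, untouched
  expect_identical(bal[!bal$augmented, ], patches)
  # already balanced input passes through
  even <- patches[c(1:10, 11:20), ]
  expect_identical(balance_by_rotation(even, seed = 4), even)
  # augmented pixels are transforms of originals: same multiset of values
  aug1 <- bal$pixels[[which(bal$augmented)[1]]]
  expect_true(any(vapply(px[1:10], function(o) {
    isTRUE(all.equal(sort(as.vector(o)), sort(as.vector(aug1))))
  }, logical(1))))
})

test_that("effective-patch selection applies the 0.99 threshold and fallback", {
  p <- tibble::tibble(row = 0L, col = 0L, size = 4L,
                      pixels = replicate(3, array(0, c(4, 4, 3)),
                                         simplify = FALSE),
                      label = NA_character_, augmented = FALSE,
                      p_oligo = c(0.995, 0.8, 0.009),
                      p_astro = c(0.005, 0.2, 0.991))
  expect_equal(nrow(select_effective_patches(p, 0.99)), 2)
  expect_equal(nrow(select_effective_patches(p, 0)), 3)
  low <- p; low$p_oligo <- c(0.6, 0.7, 0.55); low$p_astro <- 1 - low$p_oligo
  expect_warning(kept <- select_effective_patches(low, 0.99),
                 class = "histofuse_fallback")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$p_oligo, 0.7)
})

test_that("patch-vote aggregation returns a proper distribution", {
  mk <- function(po) tibble::tibble(p_oligo = po, p_astro = 1 - po)
  all1 <- aggregate_patch_votes(mk(c(1, 1, 1)), "mean_prob")
  expect_equal(all1$p_oligo, 1)
  split <- mk(c(1, 0))
  for (mode in c("mean_prob", "majority_frac")) {
    r <- aggregate_patch_votes(split, mode)
    expect_equal(r$p_oligo, 0.5)
    expect_equal(r$p_oligo + r$p_astro, 1)
  }
  # argmax ties split equally in majority mode
  tied <- mk(c(0.5, 1))
  expect_equal(aggregate_patch_votes(tied, "majority_frac")$p_oligo, 0.75)
})
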