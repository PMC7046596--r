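# Tissue detection and patch machinery shared by the three case-
# classification methods. Images are plain RGB arrays (height x width x 3,
# values 0..255); whole-slide pyramids are out of scope — the challenge
# operated on extracted tiles.

new_tissue_mask <- function(pixels, scale = 1L) {
  stopifnot(is.matrix(pixels), is.logical(pixels), scale >= 1)
  structure(list(pixels = pixels, scale = as.integer(scale)),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %dx%d at scale %d, %.1f%% tissue\n",
              nrow(x$pixels), ncol(x$pixels), x$scale,
              100 * mean(x$pixels)))
  invisible(x)
}

#' Plot a tissue mask
#' @param object A tissue mask from [tissue_mask_hsv()] or
#'   [tissue_mask_otsu()].
#' @param ... Unused.
#' @method autoplot tissue_mask
#' @export
autoplot.tissue_mask <- function(object, ...) {
  m <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$tissue <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$tissue)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey90", "TRUE" = "palevioletred3")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

fill_small_holes <- function(m, min_hole) {
  if (min_hole <= 0) return(m)
  lab <- cc_label(!m, connectivity = 4L)
  if (max(lab) == 0L) return(m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- tabulate(lab)
  fill_ids <- setdiff(which(areas < min_hole), border)
  m | (lab %in% fill_ids & lab > 0L)
}

remove_small_objects <- function(m, min_object) {
  if (min_object <= 0 || !any(m)) return(m)
  lab <- cc_label(m)
  areas <- tabulate(lab)
  m & !(matrix(lab %in% which(areas < min_object), nrow(m), ncol(m)) & lab > 0L)
}

#' HSV-threshold tissue detection
#'
#' Converts an RGB tile to HSV, keeps pixels inside the channelwise
#' `[lo, hi]` box, fills holes smaller than `min_hole` pixels and removes
#' foreground clumps smaller than `min_object` pixels. The default bounds
#' (saturation >= 0.05, hue and value wide open) separate stained tissue
#' from near-achromatic glass background.
#'
#' @param rgb RGB array (h x w x 3, values 0..255).
#' @param lo,hi HSV lower/upper bounds, each length 3 in `[0, 1]`
#'   (hue, saturation, value).
#' @param min_hole,min_object Area cut-offs in pixels at the working scale.
#' @param scale Downsample factor this tile stands at relative to its
#'   source (recorded, not applied).
#' @return A `tissue_mask`.
#' @export
tissue_mask_hsv <- function(rgb, lo = c(0, 0.05, 0), hi = c(1, 1, 1),
                            min_hole = 64, min_object = 64, scale = 1L) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L,
            length(lo) == 3L, length(hi) == 3L, all(lo <= hi))
  if (all(lo == hi)) {
    rlang::warn("degenerate HSV thresholds (lo == hi); mask may be empty")
  }
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  hsv <- grDevices::rgb2hsv(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                            as.vector(rgb[, , 3]), maxColorValue = 255)
  keep <- hsv[1, ] >= lo[1] & hsv[1, ] <= hi[1] &
          hsv[2, ] >= lo[2] & hsv[2, ] <= hi[2] &
          hsv[3, ] >= lo[3] & hsv[3, ] <= hi[3]
  m <- matrix(keep, h, w)
  m <- fill_small_holes(m, min_hole)
  m <- remove_small_objects(m, min_object)
  new_tissue_mask(m, scale)
}

otsu_threshold <- function(v) {
  # exhaustive search of the between-class variance over 256 bins
  breaks <- seq(-0.5, 255.5, by = 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = 256L)
  p <- h / sum(h)
  levels_ <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels_)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  levels_[which.max(sigma_b)]
}

#' Otsu-threshold tissue detection
#'
#' Foreground is the darker class of the Otsu split (tissue absorbs light;
#' glass background is bright).
#'
#' @param gray Grayscale matrix (values 0..255) or an RGB array, which is
#'   averaged across channels first.
#' @param scale As in [tissue_mask_hsv()].
#' @return A `tissue_mask`.
#' @export
tissue_mask_otsu <- function(gray, scale = 1L) {
  if (length(dim(gray)) == 3L) {
    gray <- (gray[, , 1] + gray[, , 2] + gray[, , 3]) / 3
  }
  stopifnot(is.matrix(gray))
  if (length(unique(as.vector(gray))) < 2L) {
    rlang::abort("constant image has no Otsu split",
                 class = "histofuse_degenerate_image")
  }
  t <- otsu_threshold(as.vector(gray))
  new_tissue_mask(gray <= t, scale)
}

#' Bounding boxes of tissue components
#'
#' One half-open box `[r0, r1) x [c0, c1)` per 8-connected component, in
#' source-pixel coordinates (the mask's `scale` is applied), 0-based.
#'
#' @param tm A `tissue_mask`.
#' @return Tibble: `component`, `r0`, `r1`, `c0`, `c1`, `area_px` (component
#'   area at the working scale).
#' @export
tissue_bounding_boxes <- function(tm) {
  stopifnot(inherits(tm, "tissue_mask"))
  lab <- cc_label(tm$pixels)
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(component = integer(), r0 = integer(), r1 = integer(),
                          c0 = integer(), c1 = integer(), area_px = integer()))
  }
  s <- tm$scale
  purrr::map_dfr(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    tibble::tibble(component = k,
                   r0 = (min(idx[, 1]) - 1L) * s, r1 = max(idx[, 1]) * s,
                   c0 = (min(idx[, 2]) - 1L) * s, c1 = max(idx[, 2]) * s,
                   area_px = nrow(idx))
  })
}

crop_patch <- function(rgb, r0, c0, size) {
  rgb[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), , drop = FALSE]
}

new_patch_tbl <- function(row, col, size, pixels, label = NA_character_,
                          augmented = FALSE) {
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 size = as.integer(size), pixels = pixels,
                 label = label, augmented = augmented)
}

#' Grid patch extraction within tissue bounding boxes
#'
#' Row-major grid of `size`-pixel patches with the given stride inside each
#' box; patches that would cross a box edge are dropped, not padded. Origins
#' are 0-based source-pixel coordinates.
#'
#' @param rgb RGB array (h x w x 3).
#' @param boxes Tibble from [tissue_bounding_boxes()] (or any tibble with
#'   `r0`, `r1`, `c0`, `c1`).
#' @param size Patch side length in pixels.
#' @param stride Grid stride in pixels.
#' @return Patch tibble: `row`, `col`, `size`, `pixels` (list of RGB
#'   arrays), `label`, `augmented`.
#' @export
extract_patches_grid <- function(rgb, boxes, size = 224L, stride = size) {
  stopifnot(size >= 1, stride >= 1)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  out <- purrr::pmap_dfr(boxes[, c("r0", "r1", "c0", "c1")],
    function(r0, r1, c0, c1) {
      r1 <- min(r1, h); c1 <- min(c1, w)
      if (r1 - r0 < size || c1 - c0 < size) return(NULL)
      rows <- seq(r0, r1 - size, by = stride)
      cols <- seq(c0, c1 - size, by = stride)
      og <- expand.grid(col = cols, row = rows)[, c("row", "col")]
      new_patch_tbl(og$row, og$col, size,
                    purrr::map2(og$row, og$col, crop_patch, rgb = rgb, size = size))
    })
  if (nrow(out) == 0L) return(new_patch_tbl(integer(), integer(), integer(), list()))
  out
}

#' Uniform-random patch extraction over tissue
#'
#' Samples `n` patch origins uniformly (without replacement) from all
#' positions whose patch lies inside the tile and covers at least
#' `min_tissue_frac` tissue; deterministic for a fixed seed. If fewer valid
#' origins exist than requested, all of them are returned with a warning.
#'
#' @param rgb RGB array.
#' @param tm A `tissue_mask` for the same tile (any scale).
#' @param size Patch side length in source pixels.
#' @param n Number of patches.
#' @param min_tissue_frac Minimum tissue fraction per patch.
#' @param seed Integer seed.
#' @return Patch tibble as in [extract_patches_grid()].
#' @export
extract_patches_random <- function(rgb, tm, size = 448L, n = 20L,
                                   min_tissue_frac = 0.5, seed = 1L) {
  stopifnot(n >= 1, inherits(tm, "tissue_mask"))
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  mask <- tm$pixels
  if (tm$scale > 1L) {
    mask <- mask[rep(seq_len(nrow(mask)), each = tm$scale),
                 rep(seq_len(ncol(mask)), each = tm$scale), drop = FALSE]
  }
  mask <- mask[seq_len(min(h, nrow(mask))), seq_len(min(w, ncol(mask))), drop = FALSE]
  full <- matrix(FALSE, h, w)
  full[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  # summed-area table for O(1) per-origin tissue fractions
  sat <- rbind(0, cbind(0, apply(apply(full, 2, cumsum), 1, cumsum) |> t()))
  if (h < size || w < size) {
    rlang::warn("tile smaller than patch size; no valid origins")
    return(new_patch_tbl(integer(), integer(), integer(), list()))
  }
  r0 <- 0:(h - size); c0 <- 0:(w - size)
  area <- sat[r0 + size + 1, c0 + size + 1, drop = FALSE] -
          sat[r0 + 1, c0 + size + 1, drop = FALSE] -
          sat[r0 + size + 1, c0 + 1, drop = FALSE] +
          sat[r0 + 1, c0 + 1, drop = FALSE]
  valid <- which(area / size^2 >= min_tissue_frac, arr.ind = TRUE)
  if (nrow(valid) == 0L) {
    rlang::warn("no origins satisfy min_tissue_frac")
    return(new_patch_tbl(integer(), integer(), integer(), list()))
  }
  if (nrow(valid) < n) {
    rlang::warn(sprintf("only %d valid origins for %d requested patches",
                        nrow(valid), n))
    pick <- seq_len(nrow(valid))
  } else {
    pick <- withr::with_seed(as.integer(seed), sample.int(nrow(valid), n))
  }
  og_r <- r0[valid[pick, 1]]
  og_c <- c0[valid[pick, 2]]
  new_patch_tbl(og_r, og_c, size,
                purrr::map2(og_r, og_c, crop_patch, rgb = rgb, size = size))
}

# ---- Colour normalisation ---------------------------------------------------

# Ruderman log-LMS opponent space used by Reinhard-style stain normalisation.
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

rgb_to_lab_ruderman <- function(rgb) {
  v <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]), as.vector(rgb[, , 3])) / 255
  lms <- pmax(.rgb2lms %*% v, 1e-6)
  .lms2lab %*% log10(lms)
}

lab_ruderman_to_rgb <- function(lab, dims) {
  lms <- 10^(.lab2lms %*% lab)
  v <- pmin(pmax(.lms2rgb %*% lms, 0), 1) * 255
  out <- array(0, dims)
  out[, , 1] <- v[1, ]; out[, , 2] <- v[2, ]; out[, , 3] <- v[3, ]
  out
}

#' Channel statistics of a tile in Ruderman log-LMS space
#'
#' Use on a reference tile to build the `target_stats` consumed by
#' [color_normalize()] with `method = "reinhard"`.
#'
#' @param rgb RGB array.
#' @return List with `mean` and `sd`, each length 3.
#' @export
reinhard_stats <- function(rgb) {
  lab <- rgb_to_lab_ruderman(rgb)
  list(mean = rowMeans(lab), sd = apply(lab, 1, stats::sd))
}

#' Colour-normalise a patch
#'
#' `"reinhard"` matches the per-channel mean and standard deviation in the
#' Ruderman log-LMS opponent space to `target_stats` (the stain-
#' normalisation recipe used before patch classification); `"hist_eq"`
#' applies an independent cumulative-histogram equalisation per RGB channel.
#' Output is clipped to 0..255. A constant-colour patch cannot be Reinhard-
#' normalised (zero channel spread) and passes through with a warning.
#'
#' @param p An RGB array, or a patch tibble from the extractors (each
#'   `pixels` entry is normalised).
#' @param method `"reinhard"` or `"hist_eq"`.
#' @param target_stats For `"reinhard"`: list with `mean` and `sd` in
#'   Ruderman log-LMS space, e.g. from [reinhard_stats()].
#' @return Same shape as `p`.
#' @export
color_normalize <- function(p, method = c("reinhard", "hist_eq"),
                            target_stats = NULL) {
  method <- match.arg(method)
  if (is.data.frame(p)) {
    p$pixels <- purrr::map(p$pixels, color_normalize, method = method,
                           target_stats = target_stats)
    return(p)
  }
  stopifnot(length(dim(p)) == 3L)
  if (method == "reinhard") {
    if (is.null(target_stats)) {
      rlang::abort("reinhard normalisation requires target_stats")
    }
    lab <- rgb_to_lab_ruderman(p)
    mu <- rowMeans(lab)
    sdv <- apply(lab, 1, stats::sd)
    if (any(sdv < 1e-8)) {
      rlang::warn("constant-colour patch; reinhard pass-through",
                  class = "histofuse_constant_patch")
      return(p)
    }
    lab <- (lab - mu) / sdv * target_stats$sd + target_stats$mean
    lab_ruderman_to_rgb(lab, dim(p))
  } else {
    out <- p
    for (ch in 1:3) {
      v <- pmin(pmax(round(as.vector(p[, , ch])), 0L), 255L)
      counts <- tabulate(v + 1L, nbins = 256L)
      cdf <- cumsum(counts)
      cdf_min <- min(cdf[cdf > 0])
      n <- length(v)
      map <- if (n > cdf_min) {
        round((cdf - cdf_min) / (n - cdf_min) * 255)
      } else {
        rep(0L, 256L)  # constant channel
      }
      out[, , ch] <- matrix(map[v + 1L], dim(p)[1], dim(p)[2])
    }
    out
  }
}

# ---- Class balancing and vote aggregation -----------------------------------

rot_mat_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_per_channel <- function(a, f) {
  ch <- lapply(1:3, function(k) f(a[, , k]))
  array(c(ch[[1]], ch[[2]], ch[[3]]), c(dim(ch[[1]]), 3L))
}

dihedral_transforms <- list(
  rot90  = function(a) apply_per_channel(a, rot_mat_cw),
  rot180 = function(a) apply_per_channel(a, function(m) rot_mat_cw(rot_mat_cw(m))),
  rot270 = function(a) apply_per_channel(a, function(m) rot_mat_cw(rot_mat_cw(rot_mat_cw(m)))),
  flip_h = function(a) apply_per_channel(a, function(m) m[, ncol(m):1, drop = FALSE]),
  flip_v = function(a) apply_per_channel(a, function(m) m[nrow(m):1, , drop = FALSE]),
  transpose = function(a) apply_per_channel(a, t),
  anti_transpose = function(a) apply_per_channel(a, function(m)
    t(m)[ncol(m):1, nrow(m):1, drop = FALSE])
)

rotate_small_angle <- function(a, angle_deg) {
  h <- dim(a)[1]; w <- dim(a)[2]
  th <- angle_deg * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  sr <- cr + cos(th) * (g$r - cr) - sin(th) * (g$c - cc)
  sc <- cc + sin(th) * (g$r - cr) + cos(th) * (g$c - cc)
  sr <- pmin(pmax(round(sr), 1L), h)
  sc <- pmin(pmax(round(sc), 1L), w)
  out <- a
  for (ch in 1:3) {
    m <- a[, , ch]
    out[, , ch] <- matrix(m[cbind(sr, sc)], h, w)
  }
  out
}

#' Equalise class counts by rotation augmentation
#'
#' Minority classes grow by appending transformed copies of their own
#' patches — the 7 symmetric dihedral transforms (90/180/270 rotations,
#' flips, transposes) first, then random small-angle rotations (within
#' +/-15 degrees, nearest-neighbour resampled) — until every class matches
#' the majority count. Originals are always retained; augmented rows carry
#' `augmented = TRUE`.
#'
#' @param patches Patch tibble with a non-missing `label` column.
#' @param seed Integer seed for source-patch and angle draws.
#' @return Patch tibble with equal per-class counts.
#' @export
balance_by_rotation <- function(patches, seed = 1L) {
  stopifnot(is.data.frame(patches), "label" %in% names(patches))
  if (any(is.na(patches$label))) rlang::abort("all patches need a class label")
  counts <- table(patches$label)
  if (any(counts == 0L)) rlang::abort("a class has zero patches",
                                      class = "histofuse_degenerate_labels")
  target <- max(counts)
  if (all(counts == target)) return(patches)
  extra <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(names(counts)[counts < target], function(cls) {
      pool <- patches[patches$label == cls, , drop = FALSE]
      need <- target - nrow(pool)
      src <- rep_len(sample.int(nrow(pool)), need)
      tfi <- seq_len(need)
      aug <- purrr::map(seq_len(need), function(i) {
        px <- pool$pixels[[src[i]]]
        if (tfi[i] <= length(dihedral_transforms) * nrow(pool)) {
          k <- ((tfi[i] - 1L) %% length(dihedral_transforms)) + 1L
          dihedral_transforms[[k]](px)
        } else {
          rotate_small_angle(px, stats::runif(1, -15, 15))
        }
      })
      out <- pool[src, , drop = FALSE]
      out$pixels <- aug
      out$augmented <- TRUE
      out
    })
  })
  dplyr::bind_rows(patches, extra)
}

#' Keep only high-confidence ("effective") patches
#'
#' Retains patches whose maximum class probability reaches `threshold`
#' (0.99 in the weighted-average method). If none qualifies, the single
#' most confident patch is kept with a warning so a case never loses all
#' its evidence.
#'
#' @param patches Patch tibble with `p_oligo` and `p_astro` columns.
#' @param threshold Confidence cut-off in `[0, 1]`.
#' @return Filtered patch tibble.
#' @export
select_effective_patches <- function(patches, threshold = 0.99) {
  stopifnot(is.data.frame(patches),
            all(c("p_oligo", "p_astro") %in% names(patches)))
  if (any(is.na(patches$p_oligo) | is.na(patches$p_astro))) {
    rlang::abort("all patches need class probabilities")
  }
  maxp <- pmax(patches$p_oligo, patches$p_astro)
  keep <- maxp >= threshold
  if (!any(keep)) {
    rlang::warn("no patch reaches the confidence threshold; keeping the top 1",
                class = "histofuse_fallback")
    keep <- seq_along(maxp) == which.max(maxp)
  }
  patches[keep, , drop = FALSE]
}

#' Aggregate patch-level probabilities into a case-level prediction
#'
#' `mean_prob` averages the per-class probabilities over patches;
#' `majority_frac` reports the fraction of patches voting (argmax) for each
#' class, with exact argmax ties split equally. Either way the result is a
#' probability distribution.
#'
#' @param patches Patch tibble with `p_oligo` and `p_astro`.
#' @param mode `"mean_prob"` or `"majority_frac"`.
#' @return A [case_probs()] with `modality = "pathology"`.
#' @export
aggregate_patch_votes <- function(patches, mode = c("mean_prob", "majority_frac")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(patches), nrow(patches) >= 1L,
            all(c("p_oligo", "p_astro") %in% names(patches)))
  if (mode == "mean_prob") {
    po <- mean(patches$p_oligo)
    pa <- mean(patches$p_astro)
  } else {
    votes_o <- ifelse(patches$p_oligo > patches$p_astro, 1,
                      ifelse(patches$p_oligo == patches$p_astro, 0.5, 0))
    po <- mean(votes_o)
    pa <- 1 - po
  }
  s <- po + pa
  case_probs(po / s, pa / s, modality = "pathology")
}
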