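#' Scored instance mask
#'
#' A single binary instance mask with a confidence score, the unit of
#' candidate segmentation consumed by [mask_nms()]. Scores are typically the
#' classification probability emitted by an upstream instance-segmentation
#' model; the synthetic generator ([perturb_truth()]) produces them from the
#' overlap with the source truth.
#'
#' @param pixels Logical matrix, `TRUE` = foreground. Must contain at least
#'   one foreground pixel.
#' @param score Confidence in `[0, 1]`.
#' @param source_id Integer identifier of the producing model or fold.
#' @return A `scored_mask` object (list with `pixels`, `score`, `source_id`).
#' @examples
#' m <- matrix(FALSE, 4, 4); m[2:3, 2:3] <- TRUE
#' scored_mask(m, 0.9)
#' @export
scored_mask <- function(pixels, score, source_id = NA_integer_) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  if (!any(pixels)) {
    rlang::abort("scored_mask must have at least one foreground pixel",
                 class = "histofuse_empty_mask")
  }
  if (!is.finite(score) || score < 0 || score > 1) {
    rlang::abort("score must be finite and in [0, 1]",
                 class = "histofuse_bad_score")
  }
  structure(
    list(pixels = pixels, score = as.numeric(score),
         source_id = as.integer(source_id)),
    class = "scored_mask"
  )
}

#' @export
print.scored_mask <- function(x, ...) {
  cat(sprintf("<scored_mask> %dx%d, %d px, score %.3f, source %s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$score,
              ifelse(is.na(x$source_id), "NA", x$source_id)))
  invisible(x)
}

#' Ordered collection of scored masks on one grid
#'
#' @param masks List of [scored_mask()] objects sharing one grid geometry
#'   (may overlap each other).
#' @param dim Grid dimension `c(height, width)`; required when `masks` is
#'   empty, inferred otherwise.
#' @return A `mask_set` object.
#' @export
mask_set <- function(masks = list(), dim = NULL) {
  stopifnot(is.list(masks))
  masks <- lapply(masks, function(m) {
    if (inherits(m, "scored_mask")) m else scored_mask(m, score = 1)
  })
  if (length(masks) > 0L) {
    dims <- vapply(masks, function(m) dim(m$pixels), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      rlang::abort("all masks in a mask_set must share one grid geometry",
                   class = "histofuse_geometry")
    }
    dim <- dims[, 1]
  } else if (is.null(dim)) {
    rlang::abort("an empty mask_set needs an explicit grid `dim`")
  }
  structure(masks, class = "mask_set", grid_dim = as.integer(dim))
}

#' @export
print.mask_set <- function(x, ...) {
  d <- attr(x, "grid_dim")
  cat(sprintf("<mask_set> %d masks on a %dx%d grid\n", length(x), d[1], d[2]))
  invisible(x)
}

#' Instance label map
#'
#' A 2D grid of non-negative integer labels: 0 is background, each positive
#' integer one instance. This is the container for ground-truth nucleus
#' segmentations and for the fused output of [mask_nms()].
#'
#' @param labels Integer matrix of non-negative labels.
#' @return An `instance_map` object (an integer matrix with a class).
#' @export
instance_map <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) rlang::abort("labels must be non-negative")
  structure(labels, class = c("instance_map", "matrix", "array"))
}

#' @export
print.instance_map <- function(x, ...) {
  cat(sprintf("<instance_map> %dx%d, %d instances, %d fg px\n",
              nrow(x), ncol(x), length(instance_labels(x)), sum(x > 0L)))
  invisible(x)
}

#' Distinct positive labels present in an instance map
#' @param lm An [instance_map()].
#' @return Sorted integer vector of instance labels.
#' @export
instance_labels <- function(lm) {
  u <- sort(unique(as.integer(lm)))
  u[u > 0L]
}

as_pixels <- function(x) {
  if (inherits(x, "scored_mask")) return(x$pixels)
  if (inherits(x, "instance_map")) return(unclass(x) > 0L)
  if (is.matrix(x) && is.logical(x)) return(x)
  if (is.matrix(x) && is.numeric(x)) return(x > 0)
  rlang::abort("expected a logical matrix, scored_mask or instance_map")
}

check_geometry <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    rlang::abort("mask geometries differ", class = "histofuse_geometry")
  }
}

#' Intersection over union of two binary masks
#'
#' @param a,b Logical matrices (or [scored_mask()]s) on the same grid.
#' @return `|a & b| / |a | b|` in `[0, 1]`. Two empty masks are an error —
#'   a degenerate comparison should surface, not silently score 0 or 1.
#' @examples
#' a <- matrix(FALSE, 3, 3); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 3, 3); b[2:3, 1:2] <- TRUE
#' iou(a, b)  # 2 shared / 6 union
#' @export
iou <- function(a, b) {
  a <- as_pixels(a); b <- as_pixels(b)
  check_geometry(a, b)
  u <- sum(a | b)
  if (u == 0L) {
    rlang::abort("iou of two empty masks is undefined",
                 class = "histofuse_empty_mask")
  }
  sum(a & b) / u
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|a & b| / (|a| + |b|)`; the monotone transform `2*iou/(1 + iou)`.
#'
#' @inheritParams iou
#' @return Ratio in `[0, 1]`; both-empty input is an error.
#' @export
dice_binary <- function(a, b) {
  a <- as_pixels(a); b <- as_pixels(b)
  check_geometry(a, b)
  s <- sum(a) + sum(b)
  if (s == 0L) {
    rlang::abort("dice of two empty masks is undefined",
                 class = "histofuse_empty_mask")
  }
  2 * sum(a & b) / s
}

#' Pixelwise union of two binary masks
#' @inheritParams iou
#' @return Logical matrix `a | b`.
#' @export
mask_union <- function(a, b) {
  a <- as_pixels(a); b <- as_pixels(b)
  check_geometry(a, b)
  a | b
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected to the grid border become foreground
#' (the hole-filling morphology step applied to candidate nucleus masks
#' before fusion). Foreground connectivity is 8; the background dual uses 4.
#'
#' @param m Logical matrix (or [scored_mask()]).
#' @return Logical matrix, a superset of the input foreground.
#' @export
fill_holes <- function(m) {
  m <- as_pixels(m)
  if (!any(m)) rlang::abort("fill_holes expects a non-empty mask",
                            class = "histofuse_empty_mask")
  fill_holes_mat(m)
}

#' Split touching nuclei by erosion and seeded re-growth
#'
#' Erodes the mask with a disk of `erosion_radius`, relabels the surviving
#' components (8-connectivity), and grows each seed back over the original
#' foreground. Contested pixels — and pixels farther than the radius from any
#' seed, e.g. on a thin bridge — go to the nearest eroded seed in Euclidean
#' distance, ties to the lower label id. The output partitions the input
#' foreground exactly: no pixel is invented and none is dropped.
#'
#' If erosion removes all foreground the input is returned as a single
#' instance with a `histofuse_over_eroded` warning.
#'
#' @param m Logical matrix (or [scored_mask()]).
#' @param erosion_radius Disk radius in pixels, `>= 1`.
#' @return An [instance_map()] covering exactly the input foreground.
#' @export
split_touching <- function(m, erosion_radius = 2) {
  m <- as_pixels(m)
  stopifnot(erosion_radius >= 1)
  if (!any(m)) rlang::abort("split_touching expects a non-empty mask",
                            class = "histofuse_empty_mask")
  seeds_bin <- binary_erode(m, erosion_radius)
  if (!any(seeds_bin)) {
    rlang::warn("erosion removed all foreground; returning input as one instance",
                class = "histofuse_over_eroded")
    lab <- matrix(0L, nrow(m), ncol(m))
    lab[m] <- 1L
    return(instance_map(lab))
  }
  seeds <- cc_label(seeds_bin)
  instance_map(nearest_seed_assign(m, seeds))
}

#' Explode an instance map into a mask set
#'
#' @param lm An [instance_map()].
#' @param default_score Score assigned to every emitted mask.
#' @return A [mask_set()] with one mask per instance, in ascending label
#'   order; `source_id` carries the original label.
#' @export
label_map_to_masks <- function(lm, default_score = 1) {
  stopifnot(inherits(lm, "instance_map"))
  labs <- instance_labels(lm)
  mask_set(lapply(labs, function(l) {
    scored_mask(unclass(lm) == l, default_score, source_id = l)
  }), dim = dim(lm))
}

#' Rasterise a mask set into an instance label map
#'
#' Overlapping pixels are resolved by a fixed tie rule: higher score wins,
#' then larger area, then lower `source_id`, then input position. Output
#' label `k` is the position of the winning mask in the input set, so a
#' round trip through [label_map_to_masks()] is lossless up to relabelling
#' for non-overlapping masks.
#'
#' @param ms A [mask_set()]; masks may overlap.
#' @return An [instance_map()].
#' @export
masks_to_label_map <- function(ms) {
  stopifnot(inherits(ms, "mask_set"))
  d <- attr(ms, "grid_dim")
  lab <- matrix(0L, d[1], d[2])
  if (length(ms) == 0L) return(instance_map(lab))
  score <- vapply(ms, `[[`, numeric(1), "score")
  area <- vapply(ms, function(m) sum(m$pixels), integer(1))
  src <- vapply(ms, function(m) {
    if (is.na(m$source_id)) .Machine$integer.max else m$source_id
  }, integer(1))
  # paint from lowest priority to highest so the winner paints last
  ord <- order(score, area, -src, -seq_along(ms))  # ascending priority
  for (i in ord) lab[ms[[i]]$pixels] <- i
  instance_map(lab)
}

# ---- Run-length encoding (COCO-style, column-major, uncompressed) ----------

# counts start with the length of the leading background run (possibly 0).
rle_encode_mask <- function(pixels) {
  v <- as.integer(pixels)  # column-major flatten
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  as.integer(counts)
}

rle_decode_mask <- function(counts, size) {
  v <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  if (length(v) != prod(size)) {
    rlang::abort("RLE counts do not match the stated size")
  }
  matrix(as.logical(v), nrow = size[1], ncol = size[2])
}

#' Read / write a mask set as COCO-style RLE JSON
#'
#' Each mask is stored as `{"size": [h, w], "counts": [...], "score": s,
#' "source_id": id}` with uncompressed column-major run-length counts
#' (leading background run first).
#'
#' @param ms A [mask_set()].
#' @param path File path.
#' @return `write_mask_set()` returns `path` invisibly; `read_mask_set()`
#'   returns a [mask_set()].
#' @export
write_mask_set <- function(ms, path) {
  stopifnot(inherits(ms, "mask_set"))
  d <- attr(ms, "grid_dim")
  recs <- lapply(ms, function(m) {
    list(size = as.integer(d), counts = rle_encode_mask(m$pixels),
         score = m$score, source_id = m$source_id)
  })
  jsonlite::write_json(list(grid = as.integer(d), masks = recs), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_mask_set
#' @export
read_mask_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  d <- as.integer(obj$grid)
  masks <- lapply(obj$masks, function(r) {
    scored_mask(rle_decode_mask(as.integer(unlist(r$counts)), as.integer(unlist(r$size))),
                score = r$score,
                source_id = if (is.null(r$source_id)) NA_integer_ else r$source_id)
  })
  mask_set(masks, dim = d)
}

# ---- Label-map I/O: 16-bit ASCII PGM (P2) ----------------------------------

#' Read / write an instance label map as 16-bit ASCII PGM
#'
#' Plain-text P2 PGM with maxval 65535: a portable, codec-free container for
#' integer label images (labels above 65535 are rejected).
#'
#' @param lm An [instance_map()].
#' @param path File path.
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "instance_map"))
  if (max(lm) > 65535L) rlang::abort("labels exceed 16-bit range")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(lm), nrow(lm)), "65535"), con)
  # row-major pixel order per PGM
  write(t(unclass(lm)), con, ncolumns = min(ncol(lm), 64L))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") rlang::abort("not an ASCII PGM (P2) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) rlang::abort("PGM pixel count mismatch")
  instance_map(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
}
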