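#' Configuration for mask-level non-maximum suppression
#'
#' @param suppress_iou Suppression threshold `N` in (0, 1): after a winner is
#'   selected, remaining candidates with IOU strictly greater than `N` are
#'   removed.
#' @param merge_mode `"merge_union"` (default) additionally unions
#'   high-overlap candidates into the winner before suppression;
#'   `"suppress_only"` never modifies the winner.
#' @param merge_iou Merge threshold in (0, 1), `>= suppress_iou`; candidates
#'   with IOU `>=` this value are unioned into the winner (merge uses `>=`,
#'   suppression uses strict `>`).
#' @return An `nms_config` list.
#' @export
nms_config <- function(suppress_iou = 0.5, merge_mode = c("merge_union", "suppress_only"),
                       merge_iou = 0.8) {
  merge_mode <- match.arg(merge_mode)
  stopifnot(suppress_iou > 0, suppress_iou < 1, merge_iou > 0, merge_iou < 1)
  if (merge_mode == "merge_union" && merge_iou < suppress_iou) {
    rlang::abort("merge_iou must be >= suppress_iou in merge_union mode")
  }
  structure(list(suppress_iou = suppress_iou, merge_mode = merge_mode,
                 merge_iou = merge_iou), class = "nms_config")
}

iou_px <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# Deterministic candidate priority: score desc, area desc, source_id asc,
# position asc.
nms_order <- function(ms) {
  score <- vapply(ms, `[[`, numeric(1), "score")
  if (any(!is.finite(score))) {
    rlang::abort("candidate scores must be finite", class = "histofuse_bad_score")
  }
  area <- vapply(ms, function(m) sum(m$pixels), integer(1))
  src <- vapply(ms, function(m) {
    if (is.na(m$source_id)) .Machine$integer.max else m$source_id
  }, integer(1))
  order(-score, -area, src, seq_along(ms))
}

#' Greedy mask-level non-maximum suppression (MASK-NMS)
#'
#' Fuses a set of scored candidate masks into a single instance map. The
#' loop repeatedly selects the maximum-score candidate `M` (ties: larger
#' area, then lower `source_id`), moves it to the output set, and removes
#' every remaining candidate whose IOU with `M` exceeds `suppress_iou`. In
#' `merge_union` mode, candidates with IOU `>= merge_iou` (measured against
#' the round's original winner) are first unioned into `M` — `M` keeps its
#' score — and suppression IOUs are then measured against the merged mask.
#' The surviving output set is rasterised with the [masks_to_label_map()]
#' tie rule.
#'
#' @param candidates A [mask_set()]; an empty set yields an empty map.
#' @param cfg An [nms_config()].
#' @return An [instance_map()]; attribute `masks` carries the fused
#'   [mask_set()] (winner masks with their inherited scores).
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:5, 2:5] <- TRUE
#' ms <- mask_set(list(scored_mask(m, 0.9), scored_mask(m, 0.8)))
#' mask_nms(ms, nms_config(merge_mode = "suppress_only"))
#' @export
mask_nms <- function(candidates, cfg = nms_config()) {
  stopifnot(inherits(candidates, "mask_set"), inherits(cfg, "nms_config"))
  d <- attr(candidates, "grid_dim")
  if (length(candidates) == 0L) {
    out <- masks_to_label_map(candidates)
    attr(out, "masks") <- candidates
    return(out)
  }
  pool <- unclass(candidates)[nms_order(candidates)]  # plain list, priority order
  kept <- list()
  while (length(pool) > 0L) {
    m <- pool[[1L]]
    pool <- pool[-1L]
    if (length(pool) > 0L) {
      ious <- vapply(pool, function(x) iou_px(m$pixels, x$pixels), numeric(1))
      if (cfg$merge_mode == "merge_union") {
        mg <- ious >= cfg$merge_iou
        if (any(mg)) {
          for (x in pool[mg]) m$pixels <- m$pixels | x$pixels
          pool <- pool[!mg]
          ious <- vapply(pool, function(x) iou_px(m$pixels, x$pixels), numeric(1))
        }
      }
      if (length(pool) > 0L) pool <- pool[!(ious > cfg$suppress_iou)]
    }
    kept <- c(kept, list(m))
  }
  fused <- mask_set(kept, dim = d)
  out <- masks_to_label_map(fused)
  attr(out, "masks") <- fused
  out
}

#' Fuse per-fold candidate sets with MASK-NMS
#'
#' Concatenates the candidate masks of several cross-validation folds (or
#' models) — stamping each candidate's `source_id` with its fold index —
#' and runs [mask_nms()] on the pooled set. This is the post-processing
#' ensemble step that combines fivefold cross-training predictions.
#'
#' @param per_fold List of [mask_set()]s sharing one grid geometry.
#' @param cfg An [nms_config()].
#' @return An [instance_map()] as from [mask_nms()].
#' @export
fuse_folds <- function(per_fold, cfg = nms_config()) {
  stopifnot(is.list(per_fold), length(per_fold) >= 1L,
            all(vapply(per_fold, inherits, logical(1), "mask_set")))
  dims <- vapply(per_fold, attr, integer(2), "grid_dim")
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    rlang::abort("folds must share one grid geometry",
                 class = "histofuse_geometry")
  }
  all_masks <- list()
  for (f in seq_along(per_fold)) {
    fold <- per_fold[[f]]
    all_masks <- c(all_masks, lapply(unclass(fold), function(m) {
      m$source_id <- f
      m
    }))
  }
  mask_nms(mask_set(all_masks, dim = dims[, 1]), cfg)
}
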