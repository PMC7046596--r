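# Deterministic synthetic stand-ins for the challenge data and the deep
# predictors: H&E-like tiles with elliptical nuclei, fold-wise perturbed
# prediction sets for the NMS fusion, and two-modality case cohorts with
# controllable class-informativeness. Everything is a pure function of its
# seed.

draw_ellipse_mask <- function(h, w, cr, cc, a, b, theta) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  dr <- g$r - cr; dc <- g$c - cc
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  matrix(u^2 + v^2 <= 1, h, w)
}

#' Generate an H&E-like tile with elliptical nuclei
#'
#' Places `n` non-overlapping textured ellipses (hematoxylin-blue nuclei) on
#' an eosin-pink background by rejection sampling. The ground-truth label
#' map has exactly `n` instances. Deterministic per seed.
#'
#' @param n Number of nuclei.
#' @param height,width Tile size in pixels.
#' @param radius_range Semi-axis range in pixels, `c(min, max)`.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget per nucleus.
#' @return A `nuclei_scene`: list with `image` (RGB array 0..255), `truth`
#'   ([instance_map()]), `n_nuclei`, `seed`.
#' @export
gen_nuclei_scene <- function(n, height = 128L, width = 128L,
                             radius_range = c(6, 12), seed = 1L,
                             max_attempts = 200L) {
  stopifnot(n >= 0, height > 2 * radius_range[2], width > 2 * radius_range[2])
  out <- withr::with_seed(as.integer(seed), {
    truth <- matrix(0L, height, width)
    occupied <- matrix(FALSE, height, width)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        a <- stats::runif(1, radius_range[1], radius_range[2])
        b <- stats::runif(1, radius_range[1], radius_range[2])
        cr <- stats::runif(1, radius_range[2] + 1, height - radius_range[2])
        cc <- stats::runif(1, radius_range[2] + 1, width - radius_range[2])
        m <- draw_ellipse_mask(height, width, cr, cc, a, b,
                               stats::runif(1, 0, pi))
        # keep a 1-px moat so instances stay separable
        if (!any(binary_dilate(m, 1) & occupied)) {
          truth[m] <- k
          occupied <- occupied | m
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rlang::abort(sprintf("could not place nucleus %d within %d attempts",
                             k, max_attempts),
                     class = "histofuse_placement_failure")
      }
    }
    # eosin-pink background, hematoxylin-blue nuclei, mild texture
    img <- array(0, c(height, width, 3))
    npix <- height * width
    img[, , 1] <- 232 + stats::rnorm(npix, 0, 5)
    img[, , 2] <- 205 + stats::rnorm(npix, 0, 5)
    img[, , 3] <- 224 + stats::rnorm(npix, 0, 5)
    fg <- truth > 0L
    tex <- stats::rnorm(sum(fg), 0, 10)
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
    r[fg] <- 95 + tex; g[fg] <- 70 + tex; b[fg] <- 150 + tex
    img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
    img <- pmin(pmax(img, 0), 255)
    list(image = img, truth = instance_map(truth))
  })
  structure(list(image = out$image, truth = out$truth, n_nuclei = as.integer(n),
                 seed = as.integer(seed)),
            class = "nuclei_scene")
}

#' @export
print.nuclei_scene <- function(x, ...) {
  cat(sprintf("<nuclei_scene> %dx%d, %d nuclei, seed %d\n",
              nrow(x$truth), ncol(x$truth), x$n_nuclei, x$seed))
  invisible(x)
}

#' Plot a synthetic nuclei scene
#' @param object A `nuclei_scene`.
#' @param ... Unused.
#' @method autoplot nuclei_scene
#' @export
autoplot.nuclei_scene <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(row = seq_len(dim(img)[1]), col = seq_len(dim(img)[2]))
  df$fill <- grDevices::rgb(img[, , 1][cbind(df$row, df$col)],
                            img[, , 2][cbind(df$row, df$col)],
                            img[, , 3][cbind(df$row, df$col)],
                            maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill), show.legend = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Perturbation settings for synthetic fold predictions
#'
#' Emulates inter-fold model disagreement: spatial jitter, morphological
#' dither, dropped instances (false negatives), spurious blobs (false
#' positives), split and merged instances, and score noise.
#'
#' @param jitter_px Max translation per instance (pixels, >= 0).
#' @param fp_rate,fn_rate,split_rate,merge_rate Rates in `[0, 1]`; applied
#'   as deterministic counts `round(rate * n)` so metadata reconciles
#'   exactly.
#' @param score_noise_sd Gaussian noise added to scores before clamping.
#' @param seed Integer seed.
#' @export
perturb_spec <- function(jitter_px = 1, fp_rate = 0.2, fn_rate = 0.1,
                         split_rate = 0, merge_rate = 0,
                         score_noise_sd = 0.05, seed = 1L) {
  rates <- c(fp_rate, fn_rate, split_rate, merge_rate)
  stopifnot(jitter_px >= 0, all(rates >= 0 & rates <= 1), score_noise_sd >= 0)
  structure(list(jitter_px = jitter_px, fp_rate = fp_rate, fn_rate = fn_rate,
                 split_rate = split_rate, merge_rate = merge_rate,
                 score_noise_sd = score_noise_sd, seed = as.integer(seed)),
            class = "perturb_spec")
}

split_mask_in_two <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
  theta <- stats::runif(1, 0, pi)
  side <- (idx[, 1] - cr) * cos(theta) + (idx[, 2] - cc) * sin(theta) >= 0
  if (all(side) || !any(side)) side <- idx[, 1] >= cr  # degenerate cut
  a <- px; a[] <- FALSE; a[idx[side, , drop = FALSE]] <- TRUE
  b <- px; b[] <- FALSE; b[idx[!side, , drop = FALSE]] <- TRUE
  if (!any(a) || !any(b)) return(list(px))  # 1-px masks cannot split
  list(a, b)
}

jitter_dither <- function(px, jitter_px) {
  if (jitter_px <= 0) return(px)
  dr <- sample(-jitter_px:jitter_px, 1L)
  dc <- sample(-jitter_px:jitter_px, 1L)
  out <- shift_mask(px, dr, dc)
  if (!any(out)) out <- px
  op <- sample(c("none", "dilate", "erode"), 1L)
  if (op == "dilate") out <- binary_dilate(out, 1)
  if (op == "erode") {
    er <- binary_erode(out, 1)
    if (any(er)) out <- er
  }
  out
}

# Distractor sites for false-positive blobs, a pure function of the truth
# map (seeded by a content checksum) so that every fold of the same scene
# sees the same sites.
fp_distractor_sites <- function(truth, n_sites) {
  h <- nrow(truth); w <- ncol(truth)
  checksum <- (sum(as.double(truth) * seq_along(truth)) %% 2147483647)
  withr::with_seed(as.integer(checksum), {
    data.frame(r = stats::runif(n_sites, 7, h - 6),
               c = stats::runif(n_sites, 7, w - 6),
               a = stats::runif(n_sites, 3, 6),
               b = stats::runif(n_sites, 3, 6),
               theta = stats::runif(n_sites, 0, pi))
  })
}

#' Perturb a ground-truth map into a synthetic fold prediction
#'
#' Applies the [perturb_spec()] to each instance: `round(fn_rate * n)`
#' instances are dropped, `round(split_rate * n)` of the kept ones are cut
#' in two at a random angle through the centroid, `round(merge_rate * n)`
#' nearest-centroid pairs of the remaining kept ones are unioned, every
#' emitted mask is jittered/dithered, and `round(fp_rate * n)` spurious
#' elliptical blobs are added at distractor sites derived from the truth
#' content — shared across folds of one scene, because cross-trained models
#' hallucinate at the same confusing structures (the blobs themselves are
#' site-deterministic; only their scores vary by fold). Scores are
#' `clamp(0.5 + 0.5 * IOU(mask, its source truth) + noise, 0.01, 1)`, so
#' faithful masks score near 1 and false positives near 0.5.
#'
#' @param truth An [instance_map()].
#' @param spec A [perturb_spec()].
#' @return A [mask_set()]; attribute `perturb_meta` lists `kept`, `dropped`,
#'   `split`, `merged` (list of label pairs) and `n_added`, which reconcile
#'   exactly with the emitted mask count.
#' @export
perturb_truth <- function(truth, spec = perturb_spec()) {
  stopifnot(inherits(truth, "instance_map"), inherits(spec, "perturb_spec"))
  labs <- instance_labels(truth)
  n <- length(labs)
  h <- nrow(truth); w <- ncol(truth)
  withr::with_seed(spec$seed, {
    n_drop <- round(spec$fn_rate * n)
    dropped <- if (n_drop > 0) sort(sample(labs, n_drop)) else integer(0)
    kept <- setdiff(labs, dropped)
    n_split <- min(round(spec$split_rate * n), length(kept))
    split_ids <- if (n_split > 0) sort(sample(kept, n_split)) else integer(0)
    mergeable <- setdiff(kept, split_ids)
    n_merge <- min(round(spec$merge_rate * n), floor(length(mergeable) / 2))
    merged_pairs <- list()
    if (n_merge > 0) {
      cent <- t(vapply(mergeable, function(l) {
        idx <- which(unclass(truth) == l, arr.ind = TRUE)
        c(mean(idx[, 1]), mean(idx[, 2]))
      }, numeric(2)))
      avail <- mergeable
      for (i in seq_len(n_merge)) {
        if (length(avail) < 2L) break
        a <- avail[1L]
        ca <- cent[match(a, mergeable), ]
        rest <- avail[-1L]
        d <- vapply(rest, function(l) {
          sum((cent[match(l, mergeable), ] - ca)^2)
        }, numeric(1))
        b <- rest[which.min(d)]
        merged_pairs <- c(merged_pairs, list(c(a, b)))
        avail <- setdiff(avail, c(a, b))
      }
    }
    merged_flat <- unlist(merged_pairs)
    plain <- setdiff(kept, c(split_ids, merged_flat))

    masks <- list()
    sources <- list()  # truth pixels each mask derives from, for scoring
    for (l in plain) {
      masks <- c(masks, list(unclass(truth) == l))
      sources <- c(sources, list(unclass(truth) == l))
    }
    n_split_masks <- 0L
    for (l in split_ids) {
      px <- unclass(truth) == l
      halves <- split_mask_in_two(px)
      n_split_masks <- n_split_masks + length(halves)
      for (hm in halves) {
        masks <- c(masks, list(hm))
        sources <- c(sources, list(px))
      }
    }
    for (pr in merged_pairs) {
      px <- unclass(truth) == pr[1] | unclass(truth) == pr[2]
      masks <- c(masks, list(px))
      sources <- c(sources, list(px))
    }
    masks <- lapply(masks, jitter_dither, jitter_px = spec$jitter_px)
    # False positives sit at distractor sites derived from the truth content
    # (not from spec$seed): models cross-trained on folds of the same data
    # hallucinate nuclei at the same confusing structures, so FP blobs of
    # different folds co-locate and NMS can collapse them.
    n_fp <- round(spec$fp_rate * n)
    if (n_fp > 0) {
      sites <- fp_distractor_sites(truth, n_fp)
      for (i in seq_len(n_fp)) {
        s <- sites[i, ]
        fp <- draw_ellipse_mask(h, w, s[["r"]], s[["c"]], s[["a"]], s[["b"]],
                                s[["theta"]])
        masks <- c(masks, list(fp))
        sources <- c(sources, list(NULL))
      }
    }
    scored <- vector("list", length(masks))
    for (i in seq_along(masks)) {
      src <- sources[[i]]
      ov <- if (is.null(src)) 0 else {
        u <- sum(masks[[i]] | src)
        if (u == 0) 0 else sum(masks[[i]] & src) / u
      }
      s <- 0.5 + 0.5 * ov +
        if (spec$score_noise_sd > 0) stats::rnorm(1, 0, spec$score_noise_sd) else 0
      scored[[i]] <- scored_mask(masks[[i]], min(1, max(0.01, s)))
    }
    out <- mask_set(scored, dim = c(h, w))
    attr(out, "perturb_meta") <- list(
      kept = kept, dropped = dropped, split = split_ids,
      merged = merged_pairs, n_added = n_fp,
      n_masks = length(plain) + n_split_masks + length(merged_pairs) + n_fp)
    out
  })
}

#' Generate fold-wise perturbed prediction sets
#'
#' Calls [perturb_truth()] once per fold with seeds `spec$seed + fold - 1`,
#' emulating the disagreeing predictions of fivefold cross-trained models.
#'
#' @param truth An [instance_map()].
#' @param spec A [perturb_spec()]; its seed anchors the per-fold seeds.
#' @param n_folds Number of folds (default 5).
#' @return List of [mask_set()]s, one per fold.
#' @export
gen_perturbed_folds <- function(truth, spec = perturb_spec(), n_folds = 5L) {
  stopifnot(n_folds >= 1)
  lapply(seq_len(n_folds), function(f) {
    fs <- spec
    fs$seed <- spec$seed + f - 1L
    perturb_truth(truth, fs)
  })
}

#' Cohort settings for the two-modality classification stand-in
#'
#' Mirrors the scale of the original training cohort (32 cases, 16 per
#' class) by default. `informativeness_*` is the class-mean separation of
#' the modality's features in units of their (unit) standard deviation; 0
#' means the modality carries no label signal.
#'
#' @param n_cases Number of cases, split evenly across the two classes.
#' @param informativeness_path,informativeness_rad Effect sizes (sd units).
#' @param feature_len_path,feature_len_rad Extractor output lengths.
#' @param dropout_rate Bernoulli drop probability of the test-time-dropout
#'   feature masks, in `[0, 1)`.
#' @param seed Integer seed.
#' @export
cohort_spec <- function(n_cases = 32L, informativeness_path = 3,
                        informativeness_rad = 0.5, feature_len_path = 50L,
                        feature_len_rad = 50L, dropout_rate = 0.5, seed = 1L) {
  stopifnot(n_cases >= 2L, n_cases %% 2L == 0L,
            informativeness_path >= 0, informativeness_rad >= 0,
            feature_len_path >= 1L, feature_len_rad >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_cases = as.integer(n_cases),
                 informativeness_path = informativeness_path,
                 informativeness_rad = informativeness_rad,
                 feature_len_path = as.integer(feature_len_path),
                 feature_len_rad = as.integer(feature_len_rad),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

make_extractor <- function(base, dropout_rate, salt) {
  force(base); force(dropout_rate); force(salt)
  stochastic_extractor(
    sample = function(case_id, seed) {
      v <- base[case_id, ]
      if (dropout_rate == 0) return(v)
      sub <- (as.numeric(seed) * 7919 + as.numeric(case_id) * 104729 + salt) %%
        2147483647
      keep <- withr::with_seed(as.integer(sub),
                               stats::rbinom(length(v), 1L, 1 - dropout_rate))
      v * keep
    },
    length = ncol(base),
    stochastic = dropout_rate > 0
  )
}

#' Generate a two-modality synthetic case cohort
#'
#' Features are class-conditional Gaussians: the first coordinate of each
#' modality carries the class signal (means +/- informativeness/2, unit sd;
#' oligodendroglioma on the positive side), all other coordinates are
#' N(0, 1) noise. The returned extractors wrap the per-case feature vectors
#' with multiplicative Bernoulli(1 - dropout_rate) masks drawn per call —
#' the test-time-dropout stand-in. Modality probabilities are a logistic
#' map of the class-discriminant (first) coordinate.
#'
#' @param spec A [cohort_spec()].
#' @return List: `cases` (tibble: `case_id`, `label`, `p_oligo_path`,
#'   `p_astro_path`, `p_oligo_rad`, `p_astro_rad`), `ex_path`, `ex_rad`
#'   ([stochastic_extractor()]s keyed by integer `case_id`),
#'   `features_path`, `features_rad` (the underlying matrices), `spec`.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases
  labels <- factor(rep(GLIOMA_CLASSES, each = n / 2), levels = GLIOMA_CLASSES)
  sign_ <- ifelse(labels == GLIOMA_CLASSES[1], 1, -1)
  out <- withr::with_seed(spec$seed, {
    fpath <- matrix(stats::rnorm(n * spec$feature_len_path), n)
    frad <- matrix(stats::rnorm(n * spec$feature_len_rad), n)
    fpath[, 1] <- fpath[, 1] + sign_ * spec$informativeness_path / 2
    frad[, 1] <- frad[, 1] + sign_ * spec$informativeness_rad / 2
    list(fpath = fpath, frad = frad)
  })
  p_oligo_path <- stats::plogis(1.5 * out$fpath[, 1])
  p_oligo_rad <- stats::plogis(1.5 * out$frad[, 1])
  cases <- tibble::tibble(
    case_id = seq_len(n),
    label = as.character(labels),
    p_oligo_path = p_oligo_path, p_astro_path = 1 - p_oligo_path,
    p_oligo_rad = p_oligo_rad, p_astro_rad = 1 - p_oligo_rad)
  list(cases = cases,
       ex_path = make_extractor(out$fpath, spec$dropout_rate, 17L),
       ex_rad = make_extractor(out$frad, spec$dropout_rate, 23L),
       features_path = out$fpath, features_rad = out$frad, spec = spec)
}

#' Case probabilities of one modality as a list of [case_probs()]
#'
#' @param cases The `cases` tibble from [gen_cohort()] (or any tibble with
#'   the matching probability columns).
#' @param modality `"pathology"` or `"radiology"`.
#' @return List of [case_probs()], one per row.
#' @export
cohort_case_probs <- function(cases, modality = c("pathology", "radiology")) {
  modality <- match.arg(modality)
  if (modality == "pathology") {
    purrr::map2(cases$p_oligo_path, cases$p_astro_path, case_probs,
                modality = "pathology")
  } else {
    purrr::map2(cases$p_oligo_rad, cases$p_astro_rad, case_probs,
                modality = "radiology")
  }
}
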