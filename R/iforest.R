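# Isolation forest, implemented here because no R anomaly-detection package
# is available in the target environment. Standard construction: iTrees grown
# on subsamples of size psi with random axis-aligned splits, height limit
# ceiling(log2(psi)); anomaly score s(x) = 2^(-E[h(x)]/c(psi)) where c(n) is
# the average unsuccessful-search path length of a BST.

avg_path_length <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

grow_itree <- function(x, height, height_limit) {
  n <- nrow(x)
  if (height >= height_limit || n <= 1L) {
    return(list(leaf = TRUE, size = n))
  }
  ranges <- apply(x, 2, range)
  splittable <- which(ranges[2, ] > ranges[1, ])
  if (length(splittable) == 0L) return(list(leaf = TRUE, size = n))
  q <- if (length(splittable) == 1L) splittable else sample(splittable, 1L)
  p <- stats::runif(1, ranges[1, q], ranges[2, q])
  left <- x[, q] < p
  list(leaf = FALSE, q = q, p = p,
       left = grow_itree(x[left, , drop = FALSE], height + 1L, height_limit),
       right = grow_itree(x[!left, , drop = FALSE], height + 1L, height_limit))
}

itree_path_length <- function(tree, x, height = 0) {
  if (tree$leaf) return(height + avg_path_length(tree$size))
  if (x[tree$q] < tree$p) {
    itree_path_length(tree$left, x, height + 1)
  } else {
    itree_path_length(tree$right, x, height + 1)
  }
}

#' Isolation-forest anomaly scores
#'
#' @param x Numeric matrix, one row per observation.
#' @param n_trees Number of isolation trees.
#' @param subsample Subsample size `psi` per tree (capped at `nrow(x)`).
#' @param seed Integer seed; scores are deterministic given it.
#' @return Numeric vector of anomaly scores in (0, 1); larger = more
#'   anomalous (~0.5 for unremarkable points).
#' @export
iforest_scores <- function(x, n_trees = 100L, subsample = 256L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  psi <- min(as.integer(subsample), nrow(x))
  hl <- ceiling(log2(psi))
  trees <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_trees), function(i) {
      rows <- sample.int(nrow(x), psi)
      grow_itree(x[rows, , drop = FALSE], 0L, hl)
    })
  })
  eh <- vapply(seq_len(nrow(x)), function(i) {
    mean(vapply(trees, itree_path_length, numeric(1), x = x[i, ]))
  }, numeric(1))
  2^(-eh / avg_path_length(psi))
}

#' Filter patch feature vectors with an isolation forest
#'
#' The outlier-removal step of the patch pipeline: patches whose feature
#' vectors are anomalous under an isolation forest are dropped before
#' classification. Exactly `ceiling((1 - contamination) * n)` inliers are
#' kept — the lowest-scoring points, ties broken by input position.
#'
#' @param features Numeric matrix (one row per patch) or list of equal-length
#'   numeric vectors.
#' @param contamination Expected outlier fraction in `[0, 0.5)`; 0 keeps all.
#' @param seed Integer seed for the forest.
#' @param n_trees,subsample Forest size parameters, see [iforest_scores()].
#' @return Sorted integer vector of kept (inlier) row indices.
#' @export
filter_patches_iforest <- function(features, contamination = 0.05, seed = 1L,
                                   n_trees = 100L, subsample = 256L) {
  if (is.list(features) && !is.matrix(features)) {
    len <- unique(lengths(features))
    if (length(len) != 1L) rlang::abort("feature vectors must share one length")
    features <- do.call(rbind, features)
  }
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  if (contamination < 0 || contamination >= 0.5) {
    rlang::abort("contamination must be in [0, 0.5)")
  }
  n <- nrow(features)
  if (contamination == 0) return(seq_len(n))
  sc <- iforest_scores(features, n_trees = n_trees, subsample = subsample,
                       seed = seed)
  n_keep <- ceiling((1 - contamination) * n)
  sort(order(sc, seq_len(n))[seq_len(n_keep)])
}
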