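# Case-level classification heads and the three radiology-pathology fusion
# strategies. Class order is fixed as (oligodendroglioma, astrocytoma)
# everywhere; every tie rule resolves toward the earlier class.

GLIOMA_CLASSES <- c("oligodendroglioma", "astrocytoma")

#' Per-case class-probability pair
#'
#' The probability that a case is oligodendroglioma vs astrocytoma, as
#' emitted by one modality's classifier (softmax output of a pathology or
#' radiology model, or a fused result).
#'
#' @param p_oligo,p_astro Non-negative, summing to 1 (within 1e-9).
#' @param modality `"pathology"`, `"radiology"` or `"fused"`.
#' @return A `case_probs` object.
#' @export
case_probs <- function(p_oligo, p_astro,
                       modality = c("pathology", "radiology", "fused")) {
  modality <- match.arg(modality)
  if (p_oligo < 0 || p_astro < 0 || abs(p_oligo + p_astro - 1) > 1e-9) {
    rlang::abort("class probabilities must be non-negative and sum to 1",
                 class = "histofuse_bad_distribution")
  }
  structure(list(p_oligo = p_oligo, p_astro = p_astro, modality = modality),
            class = "case_probs")
}

#' @export
print.case_probs <- function(x, ...) {
  cat(sprintf("<case_probs %s> oligo %.3f / astro %.3f\n",
              x$modality, x$p_oligo, x$p_astro))
  invisible(x)
}

argmax_class <- function(p) {
  # tie resolves to the earlier class
  if (p$p_oligo >= p$p_astro) GLIOMA_CLASSES[1] else GLIOMA_CLASSES[2]
}

#' Confidence-based voting between modalities
#'
#' The winning-method fusion rule: the case label comes from whichever
#' modality is more confident, i.e. has the larger maximum class
#' probability. An exact tie of the maxima goes to pathology; an argmax tie
#' within the chosen modality goes to the earlier class
#' (oligodendroglioma).
#'
#' @param path,rad [case_probs()] for the pathology and radiology models.
#' @return List with `label` (character) and `probs` (the chosen modality's
#'   [case_probs()] re-flagged as `"fused"`).
#' @examples
#' confidence_vote(case_probs(0.9, 0.1), case_probs(0.4, 0.6, "radiology"))
#' @export
confidence_vote <- function(path, rad) {
  stopifnot(inherits(path, "case_probs"), inherits(rad, "case_probs"))
  conf_path <- max(path$p_oligo, path$p_astro)
  conf_rad <- max(rad$p_oligo, rad$p_astro)
  chosen <- if (conf_path >= conf_rad) path else rad
  list(label = argmax_class(chosen),
       probs = case_probs(chosen$p_oligo, chosen$p_astro, "fused"))
}

#' Fusion weight container
#' @param alpha Pathology weight in `[0, 1]`.
#' @export
fusion_weights <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha), class = "fusion_weights")
}

#' Weighted-average fusion of modality probabilities
#'
#' `y_hat = alpha * f(X_pathology) + (1 - alpha) * g(X_radiology)`,
#' componentwise; the result is again a probability distribution.
#'
#' @param path,rad [case_probs()] inputs.
#' @param w A [fusion_weights()] (or bare alpha in `[0, 1]`).
#' @return A fused [case_probs()].
#' @export
weighted_average <- function(path, rad, w) {
  stopifnot(inherits(path, "case_probs"), inherits(rad, "case_probs"))
  if (is.numeric(w)) w <- fusion_weights(w)
  a <- w$alpha
  case_probs(a * path$p_oligo + (1 - a) * rad$p_oligo,
             a * path$p_astro + (1 - a) * rad$p_astro, "fused")
}

#' Estimate the fusion weight alpha on training cases
#'
#' Grid search over `alpha in {0, grid_step, ..., 1}` maximising the
#' training accuracy of `argmax(weighted_average(path, rad, alpha))`; the
#' smallest maximising alpha is returned so ties are deterministic.
#'
#' @param train_path,train_rad Lists of [case_probs()], one per case.
#' @param labels Character/factor vector of true labels
#'   (`"oligodendroglioma"` / `"astrocytoma"`).
#' @param grid_step Grid resolution (default 0.01).
#' @return A [fusion_weights()]; attribute `accuracy` holds the achieved
#'   training accuracy and attribute `profile` the full grid as a tibble.
#' @export
estimate_alpha <- function(train_path, train_rad, labels, grid_step = 0.01) {
  stopifnot(length(train_path) == length(train_rad),
            length(labels) == length(train_path), length(labels) >= 2L)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    rlang::abort("alpha estimation needs both classes present",
                 class = "histofuse_degenerate_labels")
  }
  grid <- seq(0, 1, by = grid_step)
  acc <- vapply(grid, function(a) {
    pred <- vapply(seq_along(labels), function(i) {
      argmax_class(weighted_average(train_path[[i]], train_rad[[i]], a))
    }, character(1))
    mean(pred == labels)
  }, numeric(1))
  best <- which.max(acc)  # first (= smallest alpha) among maximisers
  w <- fusion_weights(grid[best])
  attr(w, "accuracy") <- acc[best]
  attr(w, "profile") <- tibble::tibble(alpha = grid, accuracy = acc)
  w
}

#' Plot an alpha-estimation accuracy profile
#' @param w A [fusion_weights()] from [estimate_alpha()].
#' @return A ggplot of training accuracy over the alpha grid with the
#'   selected alpha marked.
#' @export
plot_alpha_profile <- function(w) {
  prof <- attr(w, "profile")
  if (is.null(prof)) rlang::abort("no profile attached; use estimate_alpha()")
  ggplot2::ggplot(prof, ggplot2::aes(.data$alpha, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = w$alpha, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = expression(alpha), y = "training accuracy")
}

# ---- Dropout-sampled feature ensemble --------------------------------------

#' Build a stochastic feature extractor
#'
#' The pluggable-predictor contract standing in for a trained network with
#' test-time dropout enabled: `sample(case_id, seed)` returns a fixed-length
#' feature vector, identical across calls when `stochastic` is off and
#' varying when on.
#'
#' @param sample Function `(case_id, seed) -> numeric vector` of fixed
#'   length.
#' @param length Output vector length.
#' @param stochastic Logical flag.
#' @return A `stochastic_extractor`.
#' @export
stochastic_extractor <- function(sample, length, stochastic = TRUE) {
  stopifnot(is.function(sample), length >= 1)
  structure(list(sample = sample, length = as.integer(length),
                 stochastic = isTRUE(stochastic)),
            class = "stochastic_extractor")
}

#' Draw concatenated dropout feature samples per case
#'
#' For each case, draws `k` feature vectors from the pathology extractor and
#' `k` from the radiology extractor and concatenates them pairwise — the
#' test-time-dropout trick that turns 2 networks x n cases into `k * n`
#' training vectors for the ensemble SVM. Deterministic for a fixed seed.
#'
#' @param ex_path,ex_rad [stochastic_extractor()]s.
#' @param case_ids Vector of case identifiers.
#' @param k Samples per case (the original approach uses thousands).
#' @param seed Integer seed.
#' @return Tibble: `case_id`, `draw`, `features` (list of concatenated
#'   numeric vectors of length `ex_path$length + ex_rad$length`).
#' @export
dropout_sample <- function(ex_path, ex_rad, case_ids, k = 100L, seed = 1L) {
  stopifnot(inherits(ex_path, "stochastic_extractor"),
            inherits(ex_rad, "stochastic_extractor"), k >= 1)
  rows <- purrr::map_dfr(seq_along(case_ids), function(ci) {
    feats <- purrr::map(seq_len(k), function(d) {
      sub_seed <- (as.numeric(seed) + 97 * ci + 131071 * d) %% 2147483647
      fp <- ex_path$sample(case_ids[[ci]], sub_seed)
      fr <- ex_rad$sample(case_ids[[ci]], sub_seed + 1L)
      if (length(fp) != ex_path$length || length(fr) != ex_rad$length) {
        rlang::abort("extractor returned a vector of unexpected length",
                     class = "histofuse_length_mismatch")
      }
      c(fp, fr)
    })
    tibble::tibble(case_id = case_ids[[ci]], draw = seq_len(k), features = feats)
  })
  rows
}

#' Train the ensemble SVM on dropout samples
#'
#' Every sampled concatenated vector inherits its case's label; a linear
#' max-margin classifier ([linear_svm()]) is fit on the pooled samples.
#'
#' @param samples Tibble from [dropout_sample()].
#' @param labels Named vector/list mapping `case_id` to class label, or a
#'   vector aligned with `unique(samples$case_id)`.
#' @param lambda L2 penalty passed to [linear_svm()].
#' @return An `ensemble_svm` object wrapping the fitted [linear_svm()].
#' @export
train_ensemble_svm <- function(samples, labels, lambda = 1e-2) {
  stopifnot(is.data.frame(samples), all(c("case_id", "features") %in% names(samples)))
  ids <- unique(samples$case_id)
  lab_by_case <- if (!is.null(names(labels))) {
    unlist(labels)[as.character(ids)]
  } else {
    stats::setNames(as.character(unlist(labels)), as.character(ids))[as.character(ids)]
  }
  if (any(is.na(lab_by_case))) rlang::abort("missing label for some case")
  if (length(unique(lab_by_case)) < 2L ||
      min(table(lab_by_case)) < 2L) {
    rlang::abort("need at least two cases per class",
                 class = "histofuse_degenerate_labels")
  }
  x <- do.call(rbind, samples$features)
  y <- factor(lab_by_case[as.character(samples$case_id)], levels = GLIOMA_CLASSES)
  fit <- linear_svm(x, y, lambda = lambda)
  structure(list(svm = fit, n_cases = length(ids), k = max(samples$draw),
                 dim = ncol(x)),
            class = "ensemble_svm")
}

#' @export
print.ensemble_svm <- function(x, ...) {
  cat(sprintf("<ensemble_svm> %d cases, %d draws/case, %d-dim samples\n",
              x$n_cases, x$k, x$dim))
  invisible(x)
}

#' Predict a case with the dropout-sampled ensemble
#'
#' Draws `k` fresh concatenated feature samples for the case, classifies
#' each with the trained SVM, and aggregates: `"majority"` reports the
#' fraction of per-sample votes per class, `"mean_margin"` the logistic
#' transform of the mean signed margin.
#'
#' @param clf An `ensemble_svm` from [train_ensemble_svm()].
#' @param ex_path,ex_rad [stochastic_extractor()]s.
#' @param case_id Case identifier.
#' @param k Samples to draw.
#' @param seed Integer seed.
#' @param aggregate `"majority"` or `"mean_margin"`.
#' @return A fused [case_probs()].
#' @export
predict_ensemble <- function(clf, ex_path, ex_rad, case_id, k = 100L, seed = 1L,
                             aggregate = c("majority", "mean_margin")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(clf, "ensemble_svm"), k >= 1)
  samples <- dropout_sample(ex_path, ex_rad, list(case_id), k = k, seed = seed)
  x <- do.call(rbind, samples$features)
  m <- svm_margin(clf$svm, x)
  if (aggregate == "majority") {
    po <- mean(m >= 0)
  } else {
    po <- stats::plogis(mean(m))
  }
  case_probs(po, 1 - po, "fused")
}

# ---- Radiomics head: PCA + cross-validated logistic regression --------------

#' PCA + logistic-regression radiomics classification head
#'
#' The radiology head of the winning method: radiomic feature vectors
#' (105-dimensional in the original) are reduced by principal component
#' analysis to `n_components` (16) dimensions and classified with logistic
#' regression, evaluated by k-fold cross-validation. To avoid leakage the
#' PCA is re-fit on the training folds inside each CV split; the deployed
#' model (PCA then logistic regression) is fit on all data, and the
#' reported accuracy is the mean held-out accuracy over folds.
#'
#' @param features Numeric matrix, one row per case (e.g. n x 105).
#' @param labels Two-class label vector aligned with rows.
#' @param n_components PCA dimension (default 16).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A `pca_logreg` object: `rotation`, `center`, `scale`, the glm
#'   `coefficients`, `cv_accuracy`, `cv_fold_accuracy`, `levels`.
#' @export
pca_logreg_head <- function(features, labels, n_components = 16L, folds = 5L,
                            seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            nrow(features) >= folds, ncol(features) >= n_components)
  y <- factor(labels, levels = intersect(GLIOMA_CLASSES, unique(as.character(labels))))
  if (nlevels(y) != 2L) {
    y <- factor(labels)
    if (nlevels(y) != 2L) rlang::abort("need exactly two classes",
                                       class = "histofuse_degenerate_labels")
  }
  n <- nrow(features)
  max_comp <- min(n - ceiling(n / folds), ncol(features))
  if (n_components > max_comp) {
    rlang::abort(sprintf("n_components = %d exceeds what %d training cases support (max %d)",
                         n_components, n, max_comp))
  }
  fold_id <- withr::with_seed(as.integer(seed),
                              sample(rep_len(seq_len(folds), n)))
  # liblinear-style logistic regression is L2-regularised (C = 1 by
  # default), which also keeps the fit stable when the reduced features
  # separate the classes perfectly; ridge-penalised binomial glmnet with
  # lambda = 1/n is the equivalent estimator.
  fit_one <- function(xtr, ytr) {
    pc <- stats::prcomp(xtr, center = TRUE, scale. = FALSE, rank. = n_components)
    z <- pc$x[, seq_len(n_components), drop = FALSE]
    g <- glmnet::glmnet(z, ytr, family = "binomial", alpha = 0,
                        lambda = 1 / nrow(z), standardize = FALSE)
    list(pc = pc, glm = g)
  }
  predict_one <- function(model, xte) {
    z <- predict(model$pc, xte)[, seq_len(n_components), drop = FALSE]
    # glmnet models P(second level); flip to first-level probability
    p2 <- as.numeric(stats::predict(model$glm, newx = z, type = "response"))
    1 - p2
  }
  fold_acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    model <- fit_one(features[tr, , drop = FALSE], y[tr])
    p1 <- predict_one(model, features[!tr, , drop = FALSE])
    pred <- ifelse(p1 >= 0.5, levels(y)[1], levels(y)[2])
    mean(pred == as.character(y[!tr]))
  }, numeric(1))
  final <- fit_one(features, y)
  structure(list(pc = final$pc, glm = final$glm,
                 n_components = as.integer(n_components),
                 levels = levels(y),
                 cv_accuracy = mean(fold_acc),
                 cv_fold_accuracy = fold_acc,
                 folds = as.integer(folds), n = n),
            class = "pca_logreg")
}

#' @export
print.pca_logreg <- function(x, ...) {
  cat(sprintf("<pca_logreg> %d cases, %d PCs, %d-fold CV accuracy %.3f\n",
              x$n, x$n_components, x$folds, x$cv_accuracy))
  invisible(x)
}

#' @export
predict.pca_logreg <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  z <- predict(object$pc, newdata)[, seq_len(object$n_components), drop = FALSE]
  p2 <- as.numeric(stats::predict(object$glm, newx = z, type = "response"))
  p1 <- 1 - p2
  if (type == "prob") {
    tibble::tibble(p_first = p1, p_second = p2)
  } else {
    factor(ifelse(p1 >= 0.5, object$levels[1], object$levels[2]),
           levels = object$levels)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pca_logreg
#' @export
tidy.pca_logreg <- function(x, ...) {
  co <- as.matrix(stats::coef(x$glm))
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]))
}

#' @method glance pca_logreg
#' @export
glance.pca_logreg <- function(x, ...) {
  tibble::tibble(n = x$n, n_components = x$n_components, folds = x$folds,
                 cv_accuracy = x$cv_accuracy)
}

#' @method tidy ensemble_svm
#' @export
tidy.ensemble_svm <- function(x, ...) {
  tibble::tibble(term = c("(bias)", paste0("w", seq_along(x$svm$w))),
                 estimate = c(x$svm$b, x$svm$w))
}

#' @method glance ensemble_svm
#' @export
glance.ensemble_svm <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, k = x$k, dim = x$dim,
                 lambda = x$svm$lambda, converged = x$svm$converged)
}
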