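test_that("confidence voting picks the more confident modality", {
  v <- confidence_vote(case_probs(0.9, 0.1),
                       case_probs(0.4, 0.6, "radiology"))
  expect_equal(v$label, "oligodendroglioma")        # 0.9 beats 0.6
  expect_equal(v$probs$p_oligo, 0.9)
  expect_equal(v$probs$modality, "fused")
  v2 <- confidence_vote(case_probs(0.3, 0.7),
                        case_probs(0.1, 0.9, "radiology"))
  expect_equal(v2$label, "astrocytoma")
  # exact tie of maxima: pathology wins; argmax tie: class order wins
  tie <- confidence_vote(case_probs(0.5, 0.5), case_probs(0.5, 0.5, "radiology"))
  expect_equal(tie$label, "oligodendroglioma")
  same <- confidence_vote(case_probs(0.2, 0.8), case_probs(0.2, 0.8, "radiology"))
  expect_equal(same$label, "astrocytoma")
  expect_error(case_probs(0.6, 0.6), class = "histofuse_bad_distribution")
})

test_that("weighted averaging is the stated convex combination", {
  p <- case_probs(0.9, 0.1); r <- case_probs(0.5, 0.5, "radiology")
  expect_equal(weighted_average(p, r, 1)$p_oligo, 0.9)
  expect_equal(weighted_average(p, r, 0)$p_oligo, 0.5)
  w6 <- weighted_average(p, r, 0.6)
  expect_equal(w6$p_oligo, 0.74)
  expect_equal(w6$p_astro, 0.26)
  # convexity: output between the inputs, still a distribution
  for (a in seq(0, 1, by = 0.25)) {
    out <- weighted_average(p, r, a)
    expect_gte(out$p_oligo, min(p$p_oligo, r$p_oligo))
    expect_lte(out$p_oligo, max(p$p_oligo, r$p_oligo))
    expect_equal(out$p_oligo + out$p_astro, 1)
  }
})

make_probs <- function(po, modality) {
  lapply(po, function(x) case_probs(x, 1 - x, modality))
}

test_that("alpha estimation finds the smallest maximising weight", {
  set.seed(55)
  labels <- rep(c("oligodendroglioma", "astrocytoma"), each = 10)
  perfect <- make_probs(ifelse(labels == "oligodendroglioma", 0.95, 0.05),
                        "pathology")
  noise <- make_probs(runif(20, 0.3, 0.7), "radiology")
  w <- estimate_alpha(perfect, noise, labels)
  expect_equal(attr(w, "accuracy"), 1)
  # the achieved accuracy equals the exhaustive grid maximum
  prof <- attr(w, "profile")
  expect_equal(attr(w, "accuracy"), max(prof$accuracy))
  # and it is the smallest alpha attaining it
  expect_equal(w$alpha, min(prof$alpha[prof$accuracy == max(prof$accuracy)]))
  # swap roles: radiology perfect -> small alpha; both perfect -> alpha 0
  w2 <- estimate_alpha(noise, perfect2 <- make_probs(
    ifelse(labels == "oligodendroglioma", 0.95, 0.05), "radiology"), labels)
  expect_lt(w2$alpha, 0.5)
  w3 <- estimate_alpha(make_probs(ifelse(labels == "oligodendroglioma",
                                         0.9, 0.1), "pathology"),
                       perfect2, labels)
  expect_equal(w3$alpha, 0)
  expect_error(estimate_alpha(perfect, noise, rep("astrocytoma", 20)),
               class = "histofuse_degenerate_labels")
})

const_extractor <- function(value, len) {
  stochastic_extractor(function(case_id, seed) rep(value, len), len,
                       stochastic = FALSE)
}

test_that("dropout sampling counts, concatenates and reproduces", {
  ch <- gen_cohort(cohort_spec(n_cases = 4, feature_len_path = 6,
                               feature_len_rad = 4, dropout_rate = 0.5,
                               seed = 3))
  s <- dropout_sample(ch$ex_path, ch$ex_rad, as.list(1:4), k = 7, seed = 2)
  expect_equal(nrow(s), 28)
  expect_true(all(lengths(s$features) == 10))
  s2 <- dropout_sample(ch$ex_path, ch$ex_rad, as.list(1:4), k = 7, seed = 2)
  expect_identical(s, s2)                            # bit-for-bit reproducible
  # stochastic extractors vary across draws
  m <- do.call(rbind, s$features[s$case_id == 1])
  expect_gt(sum(apply(m, 2, stats::var)), 0)
  # deterministic extractors yield identical vectors
  d <- dropout_sample(const_extractor(1, 3), const_extractor(2, 2),
                      as.list(1:2), k = 5, seed = 1)
  expect_equal(nrow(d), 10)
  for (f in d$features) expect_equal(f, c(1, 1, 1, 2, 2))
  bad <- stochastic_extractor(function(case_id, seed) rnorm(sample(2:5, 1)), 3)
  expect_error(dropout_sample(bad, const_extractor(0, 2), list(1), k = 2),
               class = "histofuse_length_mismatch")
})

test_that("the ensemble SVM separates a wide-margin cohort and not noise", {
  # linearly separable classes: means +-2, sd 0.5, 32 cases, k = 100
  mk_cohort_extractors <- function(seed) {
    base <- withr::with_seed(seed, {
      b <- matrix(rnorm(32 * 10, 0, 0.5), 32, 10)
      b[, 1] <- b[, 1] + rep(c(2, -2), each = 16)
      b
    })
    make_ex <- function(salt) stochastic_extractor(function(case_id, s) {
      keep <- withr::with_seed((s + salt) %% 2147483647,
                               stats::rbinom(10, 1, 0.8))
      base[case_id, ] * keep
    }, 10, stochastic = TRUE)
    list(path = make_ex(5), rad = make_ex(11))
  }
  labels <- stats::setNames(rep(c("oligodendroglioma", "astrocytoma"),
                                each = 16), 1:32)
  ex <- mk_cohort_extractors(800)
  smp <- dropout_sample(ex$path, ex$rad, as.list(1:32), k = 100, seed = 7)
  clf <- train_ensemble_svm(smp, labels)
  pred <- vapply(1:32, function(id) {
    class_of(predict_ensemble(clf, ex$path, ex$rad, id, k = 25, seed = 9)$p_oligo)
  }, character(1))
  expect_gte(mean(pred == labels), 0.95)
  # shuffled labels land near chance over 20 seeds; memorisation makes the
  # training cases uninformative here, so chance is read off held-out cases
  tr <- c(1:8, 17:24); te <- setdiff(1:32, tr)
  acc <- vapply(1:20, function(s) {
    lab_s <- stats::setNames(withr::with_seed(s, sample(labels)), 1:32)
    smp_s <- dropout_sample(ex$path, ex$rad, as.list(tr), k = 20, seed = s)
    clf_s <- train_ensemble_svm(smp_s, lab_s)
    pr <- vapply(te, function(id) {
      class_of(predict_ensemble(clf_s, ex$path, ex$rad, id, k = 10,
                                seed = s + 40)$p_oligo)
    }, character(1))
    mean(pr == lab_s[te])
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})

test_that("ensemble prediction aggregates votes as stated", {
  # a hand-built classifier with known weights: margin = first feature
  clf <- structure(list(
    svm = structure(list(w = c(1, rep(0, 4)), b = 0,
                         levels = c("oligodendroglioma", "astrocytoma"),
                         center = rep(0, 5), scale = rep(1, 5), lambda = 0,
                         converged = TRUE), class = "linear_svm"),
    n_cases = 2, k = 1, dim = 5), class = "ensemble_svm")
  pos <- const_extractor(1, 3)
  neg <- const_extractor(1, 2)
  p <- predict_ensemble(clf, pos, neg, 1, k = 6, seed = 1)
  expect_equal(p$p_oligo, 1)                      # all votes one class
  p1 <- predict_ensemble(clf, pos, neg, 1, k = 1, seed = 3)
  expect_equal(p1$p_oligo, 1)                     # k = 1: single vector
  pm <- predict_ensemble(clf, pos, neg, 1, k = 4, seed = 1,
                         aggregate = "mean_margin")
  expect_equal(pm$p_oligo, stats::plogis(1))      # margin is exactly 1
})

test_that("pca_logreg head recovers first-PC signal and reports 16 PCs", {
  set.seed(77)
  n <- 60
  X0 <- cbind(rnorm(n, 0, 5), matrix(rnorm(n * 104, 0, 0.1), n))
  labels <- ifelse(X0[, 1] > 0, "oligodendroglioma", "astrocytoma")
  rot <- qr.Q(qr(matrix(rnorm(105 * 105), 105)))
  X <- X0 %*% t(rot)                               # hide the signal direction
  h <- pca_logreg_head(X, labels, n_components = 16, folds = 5, seed = 5)
  expect_gte(h$cv_accuracy, 0.9)
  expect_equal(h$n_components, 16L)
  expect_equal(ncol(h$pc$rotation), 16L)           # fitted transform is 16-dim
  # permuted labels fall to chance
  hp <- pca_logreg_head(X, withr::with_seed(6, sample(labels)),
                        n_components = 16, folds = 5, seed = 5)
  expect_lt(abs(hp$cv_accuracy - 0.5), 0.2)
  # prediction plumbing and broom methods
  pr <- predict(h, X, type = "class")
  expect_gte(mean(as.character(pr) == labels), 0.9)
  expect_equal(nrow(tidy(h)), 17)                  # intercept + 16 PCs
  expect_equal(glance(h)$cv_accuracy, h$cv_accuracy)
  expect_error(pca_logreg_head(X[1:10, ], labels[1:10], n_components = 16),
               "n_components")
})
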