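# L2-regularised squared-hinge linear SVM, fit with BFGS. Written here
# because no SVM package ships in the target environment; at the scales this
# package works at (tens of thousands of sampled feature vectors, a few
# hundred dimensions) a smooth primal solve is entirely adequate.

svm_objective <- function(theta, x, y, lambda) {
  w <- theta[-1L]; b <- theta[1L]
  m <- 1 - y * (x %*% w + b)
  sum(pmax(m, 0)^2) / nrow(x) + lambda * sum(w^2)
}

svm_gradient <- function(theta, x, y, lambda) {
  w <- theta[-1L]; b <- theta[1L]
  m <- as.numeric(1 - y * (x %*% w + b))
  act <- m > 0
  coef <- numeric(length(m))
  coef[act] <- -2 * y[act] * m[act]
  gw <- as.numeric(crossprod(x, coef)) / nrow(x) + 2 * lambda * w
  gb <- sum(coef) / nrow(x)
  c(gb, gw)
}

#' Fit a linear max-margin classifier
#'
#' @param x Numeric matrix of training vectors (rows = samples).
#' @param y Two-level factor or vector of labels; the first level maps to +1.
#' @param lambda L2 penalty on the weights.
#' @return A `linear_svm` object with `w`, `b`, `levels`, and the feature
#'   standardisation used during fitting.
#' @export
linear_svm <- function(x, y, lambda = 1e-2) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(y)
  if (nlevels(y) != 2L) {
    rlang::abort("linear_svm needs exactly two classes",
                 class = "histofuse_degenerate_labels")
  }
  ys <- ifelse(as.integer(y) == 1L, 1, -1)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  theta0 <- numeric(ncol(x) + 1L)
  fit <- stats::optim(theta0, svm_objective, svm_gradient, x = xs, y = ys,
                      lambda = lambda, method = "BFGS",
                      control = list(maxit = 300L, reltol = 1e-10))
  structure(list(w = fit$par[-1L], b = fit$par[1L], levels = levels(y),
                 center = ctr, scale = scl, lambda = lambda,
                 converged = fit$convergence == 0L),
            class = "linear_svm")
}

#' Signed margins of a linear SVM
#' @param object A `linear_svm`.
#' @param x Numeric matrix of vectors to score.
#' @return Numeric vector; positive = first level.
#' @export
svm_margin <- function(object, x) {
  stopifnot(inherits(object, "linear_svm"), is.matrix(x))
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.numeric(xs %*% object$w + object$b)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  m <- svm_margin(object, newdata)
  factor(ifelse(m >= 0, object$levels[1L], object$levels[2L]),
         levels = object$levels)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, classes %s vs %s, lambda %.3g\n",
              length(x$w), x$levels[1], x$levels[2], x$lambda))
  invisible(x)
}
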