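# Soft-margin SVM with a Gaussian RBF kernel, solved in the dual with
# quadprog. Small-cohort scale (tens to a few hundred animals), where a
# dense QP solve is simple and exact.

rbf_kernel <- function(X, Y, gamma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a soft-margin RBF-kernel SVM
#'
#' Solves the dual problem
#' `max sum(alpha) - 1/2 alpha' (yy' * K) alpha` subject to
#' `0 <= alpha_i <= cost`, `sum(alpha_i y_i) = 0`, with a small ridge on
#' the kernel matrix for numerical positive-definiteness. The intercept is
#' averaged over free support vectors (fallback: KKT bound midpoint).
#'
#' @param X numeric matrix (rows = samples)
#' @param y labels coercible to `{-1, +1}` (logical: TRUE = +1)
#' @param gamma RBF kernel width `exp(-gamma * ||x - x'||^2)`
#' @param cost soft-margin penalty (the grid-search axis often written P)
#' @return an `svm_model` (supports [predict()] returning decision values)
#' @export
svm_fit <- function(X, y, gamma, cost) {
  X <- as.matrix(X)
  y <- if (is.logical(y)) ifelse(y, 1, -1) else as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be {-1, +1} or logical")
  if (length(unique(y)) < 2L) stop("both classes required to fit")
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  D <- (y %o% y) * K
  diag(D) <- diag(D) + 1e-8
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  tol <- 1e-7 * max(1, cost)
  sv <- alpha > tol
  coef <- alpha * y
  f0 <- as.numeric(K %*% coef)
  free <- sv & alpha < cost - tol
  b <- if (any(free)) {
    mean(y[free] - f0[free])
  } else {
    # no free SVs: bracket b between the KKT bounds and take the midpoint
    up <- y[alpha < cost - tol] - f0[alpha < cost - tol]
    lo <- y[alpha > tol] - f0[alpha > tol]
    (max(lo, -Inf) + min(up, Inf)) / 2
  }
  if (!is.finite(b)) b <- 0
  structure(list(X = X[sv, , drop = FALSE], coef = coef[sv], b = b,
                 gamma = gamma, cost = cost, n_sv = sum(sv)),
            class = "svm_model")
}

#' @export
#' @param object an `svm_model`
#' @param newdata numeric matrix of samples to score
#' @param ... unused
#' @rdname svm_fit
predict.svm_model <- function(object, newdata, ...) {
  K <- rbf_kernel(as.matrix(newdata), object$X, object$gamma)
  as.numeric(K %*% object$coef + object$b)
}

# Fit wrapped so numerically infeasible grid corners (e.g. cost = 1e13 on
# degenerate folds) yield NA accuracy instead of aborting the grid search.
svm_fit_safe <- function(X, y, gamma, cost) {
  tryCatch(svm_fit(X, y, gamma, cost), error = function(e) NULL)
}
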