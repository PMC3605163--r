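# Core regularized least-squares machinery: the l1l2 solver (accelerated
# iterative soft-thresholding), plain RLS, and the sign classifier.

#' l1l2-regularized least squares by accelerated soft-thresholding
#'
#' Minimizes the convex objective
#' \deqn{J(w) = \frac{1}{n}\|y - Xw\|_2^2 + \ell_1\|w\|_1 + \mu\|w\|_2^2}
#' with FISTA (proximal gradient with Nesterov acceleration); the proximal
#' map of the l1 term is coordinate-wise soft-thresholding.  The squared-l2
#' weight \code{mu} is the correlation parameter: raising it draws groups
#' of correlated variables into the support together instead of picking one
#' representative.  The loss carries a 1/n factor so that penalty grids are
#' comparable across sample sizes.
#'
#' Convergence is declared when the subgradient optimality conditions hold
#' within \code{tol}: \eqn{|g_j + \ell_1 sign(w_j)| \le tol} on the support
#' and \eqn{|g_j| \le \ell_1 + tol} off it, where g is the gradient of the
#' smooth part.
#'
#' @param X n x p numeric matrix (finite values)
#' @param y length-n response (for classification, -1/+1 labels)
#' @param l1 l1 penalty weight (>= 0); at
#'   \code{l1 >= 2 * max_j |mean(X[,j]*y)|} the solution is exactly zero
#' @param mu squared-l2 penalty weight (>= 0)
#' @param tol subgradient tolerance
#' @param maxIter iteration cap; non-convergence yields a warning, not an
#'   error
#' @param w0 optional warm start
#' @return numeric weight vector of length p with attributes
#'   \code{converged}, \code{iterations} and \code{kkt} (final subgradient
#'   residual)
#' @export
l1l2Solve <- function(X, y, l1, mu, tol = 1e-8, maxIter = 20000L,
                      w0 = NULL) {
  stopifnot(is.matrix(X), all(is.finite(X)), nrow(X) >= 2,
            length(y) == nrow(X), l1 >= 0, mu >= 0)
  n <- nrow(X); p <- ncol(X)
  Xty <- crossprod(X, y) / n
  # Lipschitz constant of the smooth gradient: 2 (sigma_max(X)^2 / n + mu)
  smax2 <- if (p == 0L) 0 else svd(X, nu = 0L, nv = 0L)$d[1L]^2
  L <- 2 * (smax2 / n + mu)
  if (L <= 0) L <- 1
  step <- 1 / L
  w <- if (is.null(w0)) numeric(p) else as.numeric(w0)
  z <- w; tAcc <- 1
  soft <- function(v, thr) sign(v) * pmax(abs(v) - thr, 0)
  gradAt <- function(v) 2 * (crossprod(X, X %*% v) / n - Xty + mu * v)
  kktResidual <- function(w, g) {
    on <- w != 0
    r1 <- if (any(on)) max(abs(g[on] + l1 * sign(w[on]))) else 0
    r2 <- if (any(!on)) max(pmax(abs(g[!on]) - l1, 0)) else 0
    max(r1, r2)
  }
  converged <- FALSE; it <- 0L; kkt <- Inf
  while (it < maxIter) {
    it <- it + 1L
    g <- gradAt(z)
    wNew <- soft(z - step * g, step * l1)
    tNew <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
    z <- wNew + ((tAcc - 1) / tNew) * (wNew - w)
    w <- wNew; tAcc <- tNew
    if (it %% 10L == 0L || it == maxIter) {
      kkt <- kktResidual(w, as.numeric(gradAt(w)))
      if (kkt <= tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    kkt <- kktResidual(w, as.numeric(gradAt(w)))
    converged <- kkt <= tol
    if (!converged)
      warning("l1l2Solve: not converged in ", maxIter,
              " iterations (KKT residual ", signif(kkt, 3), ")",
              call. = FALSE)
  }
  w <- as.numeric(w)
  attr(w, "converged") <- converged
  attr(w, "iterations") <- it
  attr(w, "kkt") <- kkt
  w
}

# Objective value of the l1l2 problem (shared by tests and model selection).
l1l2Objective <- function(X, y, w, l1, mu) {
  r <- y - as.numeric(X %*% w)
  sum(r^2) / nrow(X) + l1 * sum(abs(w)) + mu * sum(w^2)
}

# Smallest l1 weight at which the solution is exactly zero (under the 1/n
# loss scaling): 2 * max_j |mean(X_j * y)|.
l1Max <- function(X, y) 2 * max(abs(crossprod(X, y) / nrow(X)))

#' Regularized least squares
#'
#' Solves \eqn{\min_w \frac{1}{n}\|y - Xw\|^2 + \lambda\|w\|^2}, i.e. the
#' regularized normal equations \eqn{(X'X + n\lambda I) w = X'y}.  With
#' \code{lam = 0} the minimum-norm least-squares solution is returned via
#' the SVD pseudo-inverse, handling rank deficiency; on a square invertible
#' system it interpolates exactly.
#'
#' @param X n x p matrix
#' @param y length-n response
#' @param lam ridge weight (>= 0), on the same 1/n loss scale as
#'   [l1l2Solve()]
#' @return numeric weight vector of length p
#' @export
rlsSolve <- function(X, y, lam = 0) {
  stopifnot(is.matrix(X), lam >= 0, length(y) == nrow(X))
  n <- nrow(X); p <- ncol(X)
  if (p == 0L) return(numeric(0))
  if (lam == 0) {
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 1)
    if (!any(pos)) return(numeric(p))
    as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
  } else {
    as.numeric(solve(crossprod(X) + n * lam * diag(p), crossprod(X, y)))
  }
}

#' Sign classifier
#'
#' @param w weight vector
#' @param X n x p matrix
#' @return -1/+1 labels; the tie sign(0) is broken to +1
#' @export
classifyLabels <- function(w, X) {
  s <- as.numeric(X %*% w)
  ifelse(s < 0, -1, 1)
}

# Misclassification fraction of predictions vs truth.
errorRate <- function(pred, truth) mean(pred != truth)

# Confusion counts on -1/+1 labels with +1 as the positive class.
confusionCounts <- function(pred, truth) {
  c(TP = sum(pred == 1 & truth == 1),
    TN = sum(pred == -1 & truth == -1),
    FP = sum(pred == 1 & truth == -1),
    FN = sum(pred == -1 & truth == 1))
}
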