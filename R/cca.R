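#' First canonical correlation with a permutation test
#'
#' Finds the linear combinations of two multivariate blocks (here,
#' cognitive domain z-scores and lesion-derived features) with maximal
#' Pearson correlation. The first canonical pair is computed from the
#' singular value decomposition of the whitened cross-covariance
#' `Sx^{-1/2} Sxy Sy^{-1/2}`; significance is assessed by rebuilding the
#' null distribution of the first canonical correlation from `n_perm`
#' row permutations of `Y`, with `perm_p = (1 + #(r_perm >= r_obs)) /
#' (n_perm + 1)` (so the smallest attainable p is `1 / (n_perm + 1)`).
#'
#' @param X numeric matrix (N x p), e.g. the four domain z-scores.
#' @param Y numeric matrix or vector (N x q), lesion-based features.
#' @param n_perm number of row permutations.
#' @param seed integer seed for the permutations.
#' @return a `cca_result`: list with `r1`, `x_weights`, `y_weights`
#'   (unit-variance convention, sign fixed so the largest-magnitude X
#'   weight is positive), `perm_p`, `perm_r` (null draws), `n_perm`, `n`.
#' @export
cca_first <- function(X, Y, n_perm = 9999L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stop_if(nrow(X) != nrow(Y), "X and Y must have the same number of rows")
  n <- nrow(X)
  stop_if(any(!is.finite(X)) || any(!is.finite(Y)),
          "X and Y must be finite")
  stop_if(n <= ncol(X) + ncol(Y),
          "need more observations than total variables")
  sds <- c(apply(X, 2, stats::sd), apply(Y, 2, stats::sd))
  stop_if(any(sds == 0), "constant columns are not allowed")
  stop_if(n_perm < 1L, "n_perm must be positive")

  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  isqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    stop_if(any(e$values < 1e-10 * max(e$values)),
            "covariance block is (numerically) rank deficient")
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  Wx <- isqrt(crossprod(Xc) / (n - 1))
  Wy <- isqrt(crossprod(Yc) / (n - 1))
  Xw <- Xc %*% Wx
  Yw <- Yc %*% Wy

  first_r <- function(Ywm) svd(crossprod(Xw, Ywm) / (n - 1))$d[1]

  sv <- svd(crossprod(Xw, Yw) / (n - 1))
  r1 <- min(1, sv$d[1])
  xw <- drop(Wx %*% sv$u[, 1])
  yw <- drop(Wy %*% sv$v[, 1])
  s <- sign(xw[which.max(abs(xw))])
  if (s < 0) { xw <- -xw; yw <- -yw }

  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    first_r(Yw[sample.int(n), , drop = FALSE])
  }, numeric(1)))
  perm_p <- (1 + sum(perm_r >= r1)) / (n_perm + 1)

  structure(list(
    r1 = r1,
    x_weights = stats::setNames(xw, colnames(X)),
    y_weights = stats::setNames(yw, colnames(Y)),
    perm_p = perm_p, perm_r = perm_r, n_perm = n_perm, n = n
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf(
    "First canonical correlation r1 = %.4f (n = %d, perm p = %.4g, %d permutations)\n",
    x$r1, x$n, x$perm_p, x$n_perm))
  invisible(x)
}
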