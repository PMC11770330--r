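#' Logistic regression with Wald summaries
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm.fit`) returning, per term: coefficient, Wald
#' standard error from the observed information, odds ratio, Wald 95%
#' confidence interval `exp(beta +/- 1.96 se)`, and Wald p-value; plus the
#' maximized log-likelihood. Perfect or quasi-perfect separation is
#' detected (diverging coefficients / degenerate fitted probabilities) and
#' flagged with a warning rather than silently reported.
#'
#' @param y binary response (0/1).
#' @param x design matrix, including the intercept column if wanted (see
#'   `intercept`).
#' @param intercept prepend an intercept column (default `TRUE`).
#' @return a `logistic_fit`: list with `coef`, `se`, `or`, `ci95` (2-column
#'   matrix), `p`, `loglik`, `n`, `n_params`, `converged`, `separation`.
#' @export
fit_logistic <- function(y, x, intercept = TRUE) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  stop_if(!all(y %in% c(0, 1)), "response must be binary (0/1)")
  stop_if(nrow(x) != length(y), "design and response lengths differ")
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  stop_if(qr(x)$rank < ncol(x), "design matrix is rank deficient")

  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial()))
  beta <- fit$coefficients
  p_hat <- fit$fitted.values
  w <- p_hat * (1 - p_hat)
  info <- crossprod(x, x * w)
  separation <- !fit$converged || any(abs(beta) > 15) ||
    rcond(info) < 1e-12 ||
    all(pmin(p_hat, 1 - p_hat) < 1e-6) # every case fitted as certain
  if (separation) {
    warning("possible separation: coefficient estimates diverge",
            call. = FALSE)
    se <- rep(NA_real_, length(beta))
  } else {
    se <- sqrt(diag(solve(info)))
  }
  loglik <- sum(y * log(pmax(p_hat, 1e-12)) +
                  (1 - y) * log(pmax(1 - p_hat, 1e-12)))
  zval <- beta / se
  structure(list(
    coef = beta,
    se = stats::setNames(se, names(beta)),
    or = exp(beta),
    ci95 = cbind(lower = exp(beta - 1.96 * se),
                 upper = exp(beta + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(zval)),
    loglik = loglik,
    n = length(y),
    n_params = length(beta),
    converged = fit$converged,
    separation = separation
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (n = %d, logLik = %.3f%s)\n", x$n,
              x$loglik, if (x$separation) ", SEPARATION FLAGGED" else ""))
  tab <- data.frame(beta = x$coef, se = x$se, OR = x$or,
                    lo95 = x$ci95[, 1], hi95 = x$ci95[, 2], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested models
#'
#' `chi2 = 2 * (loglik_full - loglik_reduced)` referred to a chi-square
#' distribution with `df_diff` degrees of freedom (the number of extra
#' parameters in the full model).
#'
#' @param loglik_full,loglik_reduced maximized log-likelihoods of the
#'   nested pair.
#' @param df_diff degrees-of-freedom difference (>= 1).
#' @param tol tolerance for a slightly negative statistic due to rounding
#'   of reported log-likelihoods.
#' @return list with `chi2`, `df`, `p`.
#' @examples
#' lr_test(-60.655, -64.047, 1)  # chi2 = 6.784
#' @export
lr_test <- function(loglik_full, loglik_reduced, df_diff, tol = 1e-6) {
  stop_if(df_diff < 1, "df_diff must be at least 1")
  delta <- loglik_full - loglik_reduced
  stop_if(delta < -tol,
          "full model log-likelihood is below the reduced model's: ",
          "the models are not nested or the fits did not converge")
  chi2 <- max(0, 2 * delta)
  list(chi2 = chi2, df = df_diff,
       p = stats::pchisq(chi2, df = df_diff, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values (monotone, capped at 1) and rejection flags at
#' level `q`.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level.
#' @return list with `p_adjusted`, `reject`, `q`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stop_if(any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1),
          "p-values must lie in [0, 1]")
  stop_if(q <= 0 || q >= 1, "q must lie in (0, 1)")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, reject = adj <= q, q = q)
}
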