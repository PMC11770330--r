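# Gauss-Hermite nodes and weights by Golub-Welsch (weight exp(-x^2)).
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Random-intercept logistic regression via adaptive Gauss-Hermite
#' quadrature
#'
#' Fits the longitudinal model `logit P(y_ij = 1) = x_ij' beta + b_i`,
#' `b_i ~ Normal(0, sigma^2)`, by maximizing the marginal likelihood. The
#' intractable per-subject integral over the scalar random intercept is
#' evaluated with adaptive Gauss-Hermite quadrature: for each subject the
#' integrand's mode and curvature are located by Newton steps and the
#' quadrature grid is centered and scaled there (default 15 nodes).
#' Fixed-effect Wald tests use the observed information of the marginal
#' log-likelihood; `sigma` is profiled on the log scale.
#'
#' @param y binary response over all subject-timepoint rows.
#' @param x design matrix (rows aligned with `y`); an intercept column is
#'   prepended unless `intercept = FALSE`.
#' @param subject subject identifier per row (factor or vector).
#' @param nq number of quadrature nodes (>= 15 recommended).
#' @param intercept prepend an intercept column.
#' @return a `mixed_logistic_fit`: list with `coef`, `se`, `t` (Wald z),
#'   `p`, `or`, `sigma2` (random-intercept variance), `loglik`, `nq`,
#'   `converged`, `n_subjects`, `n_obs`.
#' @export
fit_logistic_mixed <- function(y, x, subject, nq = 15L, intercept = TRUE) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  stop_if(!all(y %in% c(0, 1)), "response must be binary (0/1)")
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stop_if(nrow(x) != length(y) || length(subject) != length(y),
          "y, x and subject must be aligned")
  stop_if(stats::var(y) == 0, "outcome has zero variance")
  stop_if(qr(x)$rank < ncol(x), "design matrix is rank deficient")
  subject <- as.integer(factor(subject))
  ns <- max(subject)
  gh <- gauss_hermite(as.integer(nq))
  p_fix <- ncol(x)

  neg_loglik <- function(par) {
    beta <- par[seq_len(p_fix)]
    sigma <- exp(par[p_fix + 1L])
    eta0 <- drop(x %*% beta)
    # per-subject mode of the integrand by Newton iteration
    b <- numeric(ns)
    for (it in 1:25) {
      pr <- stats::plogis(eta0 + b[subject])
      g <- drop(rowsum(y - pr, subject)) - b / sigma^2
      h <- -drop(rowsum(pr * (1 - pr), subject)) - 1 / sigma^2
      step <- g / h
      b <- b - step
      if (max(abs(step)) < 1e-9) break
    }
    pr <- stats::plogis(eta0 + b[subject])
    h <- drop(rowsum(pr * (1 - pr), subject)) + 1 / sigma^2
    s <- 1 / sqrt(h)
    # quadrature grid centered and scaled at each subject's mode
    terms <- matrix(NA_real_, ns, nq)
    for (q in seq_len(nq)) {
      bq <- b + sqrt(2) * s * gh$x[q]
      eta <- eta0 + bq[subject]
      ll_obs <- y * eta - log1p(exp(eta))
      terms[, q] <- log(gh$w[q]) + gh$x[q]^2 +
        drop(rowsum(ll_obs, subject)) +
        stats::dnorm(bq, 0, sigma, log = TRUE)
    }
    m <- apply(terms, 1, max)
    ll <- m + log(rowSums(exp(terms - m))) + log(sqrt(2) * s)
    -sum(ll)
  }

  start_glm <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial())$coefficients)
  par0 <- c(start_glm, log_sigma = log(0.8))
  opt <- stats::optim(par0, neg_loglik, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-8),
                      hessian = TRUE)
  beta <- opt$par[seq_len(p_fix)]
  sigma2 <- unname(exp(opt$par[p_fix + 1L])^2)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, p_fix) else
    sqrt(pmax(0, diag(vc)[seq_len(p_fix)]))
  tval <- beta / se
  structure(list(
    coef = stats::setNames(beta, colnames(x)),
    se = stats::setNames(se, colnames(x)),
    t = tval,
    p = 2 * stats::pnorm(-abs(tval)),
    or = exp(beta),
    sigma2 = sigma2,
    loglik = -opt$value,
    nq = as.integer(nq),
    converged = opt$convergence == 0L,
    n_subjects = ns,
    n_obs = length(y)
  ), class = "mixed_logistic_fit")
}

#' @export
print.mixed_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic model (%d subjects, %d observations, %d-node AGQ)\n",
    x$n_subjects, x$n_obs, x$nq))
  cat(sprintf("  logLik = %.3f, random-intercept variance = %.4f%s\n",
              x$loglik, x$sigma2,
              if (x$converged) "" else " (NOT CONVERGED)"))
  tab <- data.frame(beta = x$coef, se = x$se, t = x$t, OR = x$or, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Build the long-format design for the longitudinal PSCI model
#'
#' Stacks month-6 and month-36 status into one row per subject-timepoint
#' with time coded 0 (month 6) / 1 (month 36), the time-invariant factor
#' loading, its interaction with time, and age/education covariates.
#'
#' @param cohort cohort data.frame (see [sample_cognition()]).
#' @param loading numeric vector of factor loadings (one per subject).
#' @return list with `y`, `x` (columns `loading`, `time`,
#'   `loading:time`, `age`, `education`) and `subject`.
#' @export
longitudinal_design <- function(cohort, loading) {
  stop_if(length(loading) != nrow(cohort),
          "one loading per cohort row is required")
  n <- nrow(cohort)
  y <- c(cohort$psci_m6, cohort$psci_m36)
  time <- rep(c(0, 1), each = n)
  ld <- rep(loading, 2)
  x <- cbind(loading = ld, time = time, `loading:time` = ld * time,
             age = rep(cohort$age, 2), education = rep(cohort$education, 2))
  keep <- !is.na(y)
  list(y = y[keep], x = x[keep, , drop = FALSE],
       subject = rep(seq_len(n), 2)[keep])
}
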