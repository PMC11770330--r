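#' Encode disconnection percentages as pseudo-counts
#'
#' Latent Dirichlet allocation consumes count data, so percent-disconnection
#' profiles are discretized as `round(scale * pct)`; the default scale of 10
#' keeps 0.1% resolution. Subjects whose entire profile is zero carry no
#' information for the factor model: they are excluded from the returned
#' corpus (with a warning) and listed in `excluded_ids`.
#'
#' @param profiles subjects-by-tracts matrix of percent disconnection in
#'   [0, 100] (e.g. from [profile_matrix()]), or a list of
#'   `disconnection_profile` objects.
#' @param scale positive counts-per-percent factor.
#' @return a `disconnection_corpus`: list with integer `counts`
#'   (subjects x tracts), `tract_names`, `subject_ids`, `excluded_ids`,
#'   `scale`.
#' @export
encode_pseudocounts <- function(profiles, scale = 10) {
  if (is.list(profiles) && !is.data.frame(profiles) && !is.matrix(profiles)) {
    profiles <- profile_matrix(profiles)
  }
  profiles <- as.matrix(profiles)
  stop_if(!is.finite(scale) || scale <= 0, "scale must be positive")
  stop_if(any(!is.finite(profiles)) || any(profiles < 0),
          "percent disconnection must be finite and nonnegative")
  counts <- round(scale * profiles)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("sub-%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("tract_%02d", seq_len(ncol(counts)))
  zero <- rowSums(counts) == 0L
  excluded <- rownames(counts)[zero]
  if (length(excluded)) {
    warning(sprintf(
      "%d subject(s) with all-zero disconnection excluded from the corpus: %s",
      length(excluded), paste(excluded, collapse = ", ")), call. = FALSE)
  }
  new_corpus(counts[!zero, , drop = FALSE], excluded_ids = excluded,
             scale = scale)
}

new_corpus <- function(counts, excluded_ids = character(0), scale = NA_real_) {
  structure(list(
    counts = counts,
    tract_names = colnames(counts),
    subject_ids = rownames(counts),
    excluded_ids = excluded_ids,
    scale = scale
  ), class = "disconnection_corpus")
}

#' @export
print.disconnection_corpus <- function(x, ...) {
  cat(sprintf(
    "Disconnection corpus: %d subjects x %d tracts (total count %.0f)\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts)))
  if (length(x$excluded_ids))
    cat(sprintf("  %d all-zero subject(s) excluded\n", length(x$excluded_ids)))
  invisible(x)
}

as_corpus_counts <- function(corpus) {
  if (inherits(corpus, "disconnection_corpus")) return(corpus$counts)
  m <- as.matrix(corpus)
  storage.mode(m) <- "integer"
  m
}

#' Fit a latent disconnection factor model (smoothed LDA, variational EM)
#'
#' Mixed-membership model in which each participant (document) expresses K
#' latent disconnection factors (topics) and each factor is a probability
#' distribution over tracts (words). Inference is mean-field variational
#' EM for smoothed LDA with symmetric Dirichlet priors `alpha` on the
#' participant-factor weights and `eta` on the factor-tract signatures:
#' the E-step iterates the responsibilities
#' `phi(d,t,k) ~ exp(E[log theta_dk]) * exp(E[log beta_kt])` and the
#' variational Dirichlet parameters `gamma_dk = alpha + sum_t n_dt phi`,
#' and the M-step updates `lambda_kt = eta + sum_d n_dt phi`. Every update
#' is a coordinate ascent step on the evidence lower bound (ELBO), which is
#' therefore non-decreasing across iterations; fitting stops when the
#' relative ELBO change drops below `tol`.
#'
#' @param corpus a `disconnection_corpus` or nonnegative integer matrix
#'   (subjects x tracts).
#' @param k number of latent factors (1 <= k <= number of tracts).
#' @param alpha symmetric Dirichlet prior on factor loadings; default `1/k`
#'   so that document-level sparsity grows with K.
#' @param eta symmetric Dirichlet prior on tract signatures; the default
#'   0.01 favors sparse signatures.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum EM iterations.
#' @param tol relative ELBO convergence tolerance.
#' @param inner_iter maximum responsibilities/gamma sweeps per E-step.
#' @param inner_tol per-sweep mean relative change in gamma below which the
#'   E-step stops early.
#' @return a `factor_model`: list with `k`, `beta` (K x T row-stochastic,
#'   Pr(Tract | Factor)), `theta` (N x K row-stochastic,
#'   Pr(Factor | Participant)), `elbo`, `elbo_trace`, `n_iter`, `converged`,
#'   and the hyperparameters used.
#' @examples
#' x <- matrix(rpois(60, 40), 6, 10)
#' fit <- fit_lda(x, k = 2, seed = 1)
#' rowSums(fit$beta)   # each 1
#' @export
fit_lda <- function(corpus, k, alpha = NULL, eta = 0.01, seed = 1L,
                    max_iter = 200L, tol = 1e-6, inner_iter = 10L,
                    inner_tol = 1e-3) {
  X <- as_corpus_counts(corpus)
  N <- nrow(X); T_ <- ncol(X)
  stop_if(N == 0L || sum(X) == 0L, "corpus is empty")
  stop_if(any(X < 0), "corpus counts must be nonnegative")
  stop_if(any(rowSums(X) == 0), "corpus has all-zero subjects; ",
          "exclude them first (see encode_pseudocounts)")
  k <- as.integer(k)
  stop_if(k < 1L, "k must be >= 1")
  stop_if(k > T_, sprintf("k = %d exceeds the number of tracts (%d)", k, T_))
  alpha <- alpha %||% (1 / k)
  stop_if(alpha <= 0 || eta <= 0, "alpha and eta must be positive")
  X <- matrix(as.numeric(X), N, T_, dimnames = dimnames(X))

  # init: each factor signature is a Dirichlet perturbation of the
  # empirical tract frequencies
  freq <- colSums(X) / sum(X)
  lambda <- with_seed(seed, {
    w <- matrix(freq, k, T_, byrow = TRUE) *
      matrix(stats::rgamma(k * T_, shape = 4, rate = 4), k, T_)
    eta + (sum(X) / k) * (w / rowSums(w))
  })
  gamma <- matrix(alpha + rowSums(X) / k, N, k)

  elogt <- function(g) digamma(g) - digamma(rowSums(g))
  A <- exp(elogt(gamma))            # N x K
  B <- exp(elogt(lambda))           # K x T

  elbo_term_dir <- function(par, prior, m) {
    # sum over rows of E[log p(row | prior)] - E[log q(row)]
    el <- digamma(par) - digamma(rowSums(par))
    sum(lgamma(m * prior) - m * lgamma(prior) - lgamma(rowSums(par)) +
          rowSums(lgamma(par)) + rowSums((prior - par) * el))
  }
  compute_elbo <- function() {
    Z <- pmax(A %*% B, 1e-300)
    sum(X * log(Z)) + elbo_term_dir(gamma, alpha, k) +
      elbo_term_dir(lambda, eta, T_)
  }

  elbo_trace <- numeric(0)
  elbo_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: iterate responsibilities and gamma to a fixed point
    for (j in seq_len(inner_iter)) {
      Z <- pmax(A %*% B, 1e-300)
      R <- X / Z
      gamma_new <- alpha + A * (R %*% t(B))
      delta <- mean(abs(gamma_new - gamma) / (abs(gamma) + 1e-8))
      gamma <- gamma_new
      A <- exp(elogt(gamma))
      if (delta < inner_tol) break
    }
    # M-step
    Z <- pmax(A %*% B, 1e-300)
    R <- X / Z
    lambda <- eta + B * (t(A) %*% R)
    B <- exp(elogt(lambda))

    elbo <- compute_elbo()
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_old) &&
        abs(elbo - elbo_old) < tol * abs(elbo_old)) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }

  beta <- lambda / rowSums(lambda)
  theta <- gamma / rowSums(gamma)
  dimnames(beta) <- list(paste0("factor_", seq_len(k)), colnames(X))
  dimnames(theta) <- list(rownames(X), paste0("factor_", seq_len(k)))

  structure(list(
    k = k, beta = beta, theta = theta,
    elbo = elbo_trace[length(elbo_trace)], elbo_trace = elbo_trace,
    n_iter = it, converged = converged,
    alpha = alpha, eta = eta, seed = seed
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf(
    "Latent disconnection factor model: K = %d, %d participants, %d tracts\n",
    x$k, nrow(x$theta), ncol(x$beta)))
  cat(sprintf("  ELBO %.3f after %d EM iterations (%s); alpha = %.3g, eta = %.3g\n",
              x$elbo, x$n_iter,
              if (x$converged) "converged" else "iteration limit", x$alpha,
              x$eta))
  invisible(x)
}

#' Cumulative disconnection load of the top tracts of a factor
#'
#' Sorts one factor's tract signature Pr(Tract | Factor) in decreasing
#' order and reports the `top_k` tract names together with their summed
#' probability (the share of the factor's disconnection load they carry).
#'
#' @param beta_row simplex vector (one row of `factor_model$beta`).
#' @param top_k number of leading tracts to report.
#' @return list with `tracts` (character) and `share` (numeric in [0, 1]).
#' @export
factor_load_share <- function(beta_row, top_k) {
  stop_if(any(beta_row < -1e-9) || abs(sum(beta_row) - 1) > 1e-6,
          "beta_row must lie on the probability simplex")
  stop_if(top_k < 1L || top_k > length(beta_row),
          "top_k must be between 1 and the number of tracts")
  ord <- order(beta_row, decreasing = TRUE)[seq_len(top_k)]
  nm <- names(beta_row) %||% as.character(seq_along(beta_row))
  list(tracts = nm[ord], share = sum(beta_row[ord]))
}
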