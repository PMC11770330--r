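# Optimal one-to-one factor matching between two fitted models, maximizing
# the summed Pearson correlation between tract signatures. Exact assignment
# by dynamic programming over column subsets (K <= ~20).
match_factors <- function(beta_a, beta_b) {
  K <- nrow(beta_a)
  stopifnot(nrow(beta_b) == K)
  C <- suppressWarnings(stats::cor(t(beta_a), t(beta_b)))
  C[!is.finite(C)] <- 0
  full <- bitwShiftL(1L, K)
  dp <- rep(-Inf, full)
  from <- integer(full)
  pick <- integer(full)
  dp[1L] <- 0
  popc <- vapply(0:(full - 1L), function(m) {
    sum(bitwAnd(m, bitwShiftL(1L, 0:(K - 1L))) > 0L)
  }, integer(1))
  order_masks <- order(popc)
  for (m in order_masks) {
    mask <- m - 1L
    if (!is.finite(dp[m])) next
    i <- popc[m] + 1L # next row to assign
    if (i > K) next
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0L) next
      nm <- bitwOr(mask, bit) + 1L
      cand <- dp[m] + C[i, j]
      if (cand > dp[nm]) {
        dp[nm] <- cand
        from[nm] <- m
        pick[nm] <- j
      }
    }
  }
  perm <- integer(K)
  m <- full
  for (i in K:1) {
    perm[i] <- pick[m]
    m <- from[m]
  }
  list(perm = perm,
       mean_cor = dp[full] / K,
       cor = C[cbind(seq_len(K), perm)])
}

#' Cross-run stability of a K-factor model
#'
#' Reproducibility index for a given number of factors: the model is fitted
#' `n_runs` times from different random initializations, factors are
#' matched across each of the `n_runs * (n_runs - 1) / 2` run pairs by the
#' assignment maximizing the summed Pearson correlation between tract
#' signatures, and stability is the mean matched correlation over pairs,
#' clipped to [0, 1].
#'
#' @param corpus a `disconnection_corpus` or count matrix.
#' @param k number of factors.
#' @param n_runs number of random restarts (>= 2).
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param ... further arguments to [fit_lda()].
#' @return stability in [0, 1].
#' @export
lda_stability <- function(corpus, k, n_runs = 10L, seed = 1L, ...) {
  stop_if(n_runs < 2L, "need at least 2 runs to measure stability")
  fits <- lapply(seq_len(n_runs), function(r) {
    fit_lda(corpus, k, seed = seed + r - 1L, ...)
  })
  pairs <- utils::combn(n_runs, 2L)
  vals <- apply(pairs, 2L, function(p) {
    match_factors(fits[[p[1]]]$beta, fits[[p[2]]]$beta)$mean_cor
  })
  min(1, max(0, mean(vals)))
}

#' Stability-based selection of the number of factors
#'
#' Computes [lda_stability()] for every K in `k_min:k_max` and selects the
#' K with the highest stability; ties break toward the smallest K
#' (parsimony).
#'
#' @param corpus a `disconnection_corpus` or count matrix.
#' @param k_min,k_max inclusive K range (`1 <= k_min <= k_max <= `number of
#'   tracts).
#' @param n_runs restarts per K.
#' @param seed base seed (shared across K so runs differ only in K).
#' @param ... further arguments to [fit_lda()].
#' @return a `stability_report`: list with `k_values`, `stability`,
#'   `selected_k`.
#' @export
select_k <- function(corpus, k_min = 2L, k_max = 10L, n_runs = 10L,
                     seed = 1L, ...) {
  X <- as_corpus_counts(corpus)
  stop_if(k_min < 1L || k_min > k_max || k_max > ncol(X),
          "need 1 <= k_min <= k_max <= number of tracts")
  ks <- seq.int(k_min, k_max)
  stab <- vapply(ks, function(k) {
    lda_stability(corpus, k, n_runs = n_runs, seed = seed, ...)
  }, numeric(1))
  structure(list(
    k_values = ks,
    stability = stats::setNames(stab, paste0("K", ks)),
    selected_k = ks[which.max(stab)]
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability-based model selection\n")
  for (i in seq_along(x$k_values)) {
    cat(sprintf("  K = %2d  stability = %.4f%s\n", x$k_values[i],
                x$stability[i],
                if (x$k_values[i] == x$selected_k) "  <- selected" else ""))
  }
  invisible(x)
}
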