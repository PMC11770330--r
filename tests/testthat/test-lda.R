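test_that("pseudo-count encoding rounds percentages and drops empty rows", {
  prof <- rbind(a = c(0, 50, 100), b = c(0, 0, 0), c = c(1.23, 0, 7.68))
  colnames(prof) <- c("t1", "t2", "t3")
  expect_warning(corp <- encode_pseudocounts(prof, scale = 10),
                 "all-zero")
  expect_identical(unname(corp$counts["a", ]), c(0L, 500L, 1000L))
  expect_identical(unname(corp$counts["c", ]), c(12L, 0L, 77L))
  expect_identical(corp$excluded_ids, "b")
  expect_identical(corp$subject_ids, c("a", "c"))
  expect_error(encode_pseudocounts(prof - 5), "nonnegative")
  expect_error(encode_pseudocounts(prof, scale = 0), "positive")
})

test_that("single-factor model degenerates to empirical frequencies", {
  set.seed(5)
  X <- matrix(rpois(80, 30), 8, 10)
  fit <- fit_lda(X, k = 1, eta = 0.01, seed = 3)
  expect_equal(unname(fit$theta[, 1]), rep(1, 8))
  expected <- (0.01 + colSums(X)) / (0.01 * 10 + sum(X))
  expect_equal(unname(fit$beta[1, ]), expected, tolerance = 1e-10)
})

test_that("variational EM is deterministic with monotone ELBO", {
  cfg <- synth_config(n_subjects = 60, n_tracts = 12, k_true = 2, seed = 14)
  sim <- sample_disconnection_corpus(cfg)
  f1 <- fit_lda(sim$corpus, 3, seed = 8)
  f2 <- fit_lda(sim$corpus, 3, seed = 8)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$theta, f2$theta)

  for (sd_ in c(1, 2)) {
    f <- fit_lda(sim$corpus, 3, seed = sd_)
    tr <- f$elbo_trace
    expect_true(all(diff(tr) > -1e-6 * abs(tr[-length(tr)])))
    expect_true(all(abs(rowSums(f$beta) - 1) < 1e-8))
    expect_true(all(abs(rowSums(f$theta) - 1) < 1e-8))
    expect_true(is.finite(f$elbo))
  }

  expect_error(fit_lda(sim$corpus, 0), ">= 1")
  expect_error(fit_lda(sim$corpus, 40), "exceeds")
  expect_error(fit_lda(matrix(0L, 3, 4), 2), "empty|all-zero")
})

test_that("factors with disjoint tract supports are recovered", {
  cfg <- synth_config(n_subjects = 300, n_tracts = 24, k_true = 2,
                      dirichlet_alpha = 0.4, support_overlap = 1e-3,
                      seed = 17)
  sim <- sample_disconnection_corpus(cfg)
  fit <- fit_lda(sim$corpus, 2, seed = 1)
  m <- match_factors <- disconnectr:::match_factors(fit$beta,
                                                    sim$truth$beta_true)
  cosines <- vapply(1:2, function(i) {
    a <- fit$beta[i, ]; b <- sim$truth$beta_true[m$perm[i], ]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_true(all(cosines >= 0.99))
})

test_that("estimates are robust to the pseudo-count scale", {
  cfg <- synth_config(n_subjects = 150, seed = 23)
  sim <- sample_disconnection_corpus(cfg)
  pct <- 100 * sim$corpus$counts / rowSums(sim$corpus$counts)
  f1 <- fit_lda(encode_pseudocounts(pct, scale = 1), 3, seed = 2)
  f10 <- fit_lda(encode_pseudocounts(pct, scale = 10), 3, seed = 2)
  m <- disconnectr:::match_factors(f1$beta, f10$beta)
  th10 <- f10$theta[, m$perm]
  expect_gt(cor(as.vector(f1$theta), as.vector(th10)), 0.95)

  # integer count scaling leaves signatures nearly unchanged
  f5 <- fit_lda(sim$corpus$counts * 5L, 3, seed = 2)
  f1b <- fit_lda(sim$corpus$counts, 3, seed = 2)
  m2 <- disconnectr:::match_factors(f1b$beta, f5$beta)
  tv <- max(rowSums(abs(f1b$beta - f5$beta[m2$perm, ])) / 2)
  expect_lt(tv, 0.01)
})

test_that("factor load share sorts and sums the signature", {
  expect_equal(factor_load_share(rep(1 / 20, 20), 10)$share, 0.5)
  onehot <- c(1, rep(0, 9))
  names(onehot) <- paste0("t", 1:10)
  ls <- factor_load_share(onehot, 1)
  expect_equal(ls$share, 1)
  expect_equal(ls$tracts, "t1")
  set.seed(9)
  row <- as.vector(disconnectr:::rdirichlet(1, rep(0.4, 15)))
  names(row) <- paste0("t", 1:15)
  ls2 <- factor_load_share(row, 6)
  expect_equal(ls2$share, sum(sort(row, decreasing = TRUE)[1:6]))
  expect_error(factor_load_share(c(0.5, 0.2), 1), "simplex")
})
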