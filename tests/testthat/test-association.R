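test_that("domain summaries average available tests per domain", {
  ds <- domain_summary(list(memory = -1, attention = c(-1, 0, 1),
                            visuospatial = c(-2, -1), language = 0.5))
  expect_equal(unname(ds$domain_z),
               c(-1, 0, -1.5, 0.5))
  with_na <- domain_summary(list(m = c(-1, NA), a = NA_real_))
  expect_equal(unname(with_na$domain_z[1]), -1)
  expect_true(with_na$incomplete[["a"]])
  expect_equal(unname(with_na$n_missing), c(1L, 1L))
})

test_that("PSCI rule triggers on any domain at or below threshold", {
  expect_equal(psci_classify(c(0, 0, 0, 0)), 0L)
  expect_equal(psci_classify(c(-1.6, 0, 0, 0)), 1L)
  expect_equal(psci_classify(rep(-1.5, 4)), 1L)   # boundary inclusive
  expect_equal(psci_classify(c(-1.49, -1.49, -1.49, -1.49)), 0L)
  expect_true(is.na(psci_classify(c(NA, 0, 0, 0))))
  # threshold configurable
  expect_equal(psci_classify(c(-1.2, 0, 0, 0), threshold = -1), 1L)
})

test_that("logistic fits agree with glm and report consistent likelihood", {
  set.seed(7)
  n <- 300
  x <- cbind(age = rnorm(n, 60, 10), exposure = runif(n))
  y <- rbinom(n, 1, plogis(-1 + 0.03 * (x[, 1] - 60) + 1.2 * x[, 2]))
  f <- fit_logistic(y, x)
  g <- stats::glm(y ~ x, family = binomial())
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-5)
  # internal consistency: loglik equals the Bernoulli log-likelihood at
  # the returned coefficients
  eta <- cbind(1, x) %*% f$coef
  ll <- sum(y * eta - log1p(exp(eta)))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
  expect_equal(unname(f$or), exp(unname(f$coef)))
  expect_true(all(f$ci95[, 1] <= f$or & f$or <= f$ci95[, 2]))
})

test_that("separation and rank deficiency are flagged, not silently fit", {
  y <- rep(c(0, 1), each = 10)
  x <- cbind(z = c(rnorm(10, -5), rnorm(10, 5)))
  expect_warning(f <- fit_logistic(y, x), "separation")
  expect_true(f$separation)
  expect_error(fit_logistic(y, cbind(a = 1:20, b = 2 * (1:20))),
               "rank deficient")
})

test_that("likelihood-ratio test reproduces the worked comparisons", {
  lt <- lr_test(-60.655, -64.047, 1)
  expect_equal(lt$chi2, 6.784)
  expect_equal(lt$p, 0.0092, tolerance = 0.01)
  lt2 <- lr_test(-56.829, -60.977, 1)
  expect_equal(lt2$chi2, 8.296)
  expect_equal(lt2$p, 0.0039, tolerance = 0.02)
  expect_equal(lr_test(-10, -10, 1)$chi2, 0)
  expect_equal(lr_test(-10, -10, 1)$p, 1)
  expect_error(lr_test(-12, -10, 1), "not nested|below")
  expect_error(lr_test(-10, -12, 0), "at least 1")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  expect_equal(bh_fdr(rep(0.04, 5))$p_adjusted, rep(0.04, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$p_adjusted, rep(0.04, 4))
  r <- bh_fdr(c(0.001, 0.2, 0.9), q = 0.05)
  expect_identical(r$reject, c(TRUE, FALSE, FALSE))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("transition table reproduces the cohort bookkeeping", {
  p6 <- rep(c(1, 1, 0, 0), c(30, 25, 10, 40))
  p36 <- rep(c(1, 0, 1, 0), c(30, 25, 10, 40))
  tt <- transition_table(p6, p36)
  expect_equal(tt$both, 30)
  expect_equal(tt$six_only, 25)
  expect_equal(tt$thirtysix_only, 10)
  expect_equal(tt$neither, 40)
  expect_equal(tt$month6_total, 55)
  expect_equal(tt$month36_total, 40)
  expect_equal(tt$converters, 35)
  expect_equal(tt$n, 105)
  expect_error(transition_table(c(0, 1), c(1)), "length")
})
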