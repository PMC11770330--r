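make_long_data <- function(ns, sigma, seed, b_load = 1.2, b_time = -0.5,
                           b_int = 0) {
  set.seed(seed)
  b <- rnorm(ns, 0, sigma)
  load <- runif(ns)
  age <- rnorm(ns)
  subj <- rep(seq_len(ns), 2)
  time <- rep(c(0, 1), each = ns)
  x <- cbind(loading = load[subj], time = time,
             `loading:time` = load[subj] * time, age = age[subj])
  eta <- -0.4 + b_load * x[, 1] + b_time * x[, 2] + b_int * x[, 3] +
    0.3 * x[, 4] + b[subj]
  list(y = rbinom(2 * ns, 1, plogis(eta)), x = x, subject = subj)
}

test_that("zero random-intercept variance collapses to plain logistic", {
  d <- make_long_data(400, sigma = 0, seed = 2)
  mf <- fit_logistic_mixed(d$y, d$x, d$subject, nq = 15)
  gf <- fit_logistic(d$y, d$x)
  expect_lt(max(abs(mf$coef - gf$coef) / pmax(abs(gf$coef), 0.05)), 0.02)
  expect_lt(mf$sigma2, 0.05)
})

test_that("quadrature is converged at 15 nodes", {
  d <- make_long_data(250, sigma = 1, seed = 3)
  f15 <- fit_logistic_mixed(d$y, d$x, d$subject, nq = 15)
  f31 <- fit_logistic_mixed(d$y, d$x, d$subject, nq = 31)
  expect_lt(max(abs(f15$coef - f31$coef)), 1e-3)
  expect_lt(abs(f15$sigma2 - f31$sigma2), 1e-3)
})

test_that("marginal likelihood maximization matches an independent
           adaptive-quadrature implementation", {
  d <- make_long_data(300, sigma = 1, seed = 4)
  mf <- fit_logistic_mixed(d$y, d$x, d$subject, nq = 15)
  dd <- data.frame(y = d$y, d$x, s = d$subject, check.names = FALSE)
  gm <- lme4::glmer(
    y ~ loading + time + `loading:time` + age + (1 | s),
    data = dd, family = binomial(), nAGQ = 15,
    control = lme4::glmerControl(calc.derivs = FALSE))
  expect_equal(unname(mf$coef), unname(lme4::fixef(gm)), tolerance = 1e-3)
  expect_equal(mf$sigma2,
               as.numeric(lme4::VarCorr(gm)$s), tolerance = 0.02)
  expect_equal(mf$loglik, as.numeric(stats::logLik(gm)), tolerance = 1e-4)
})

test_that("degenerate longitudinal inputs are rejected", {
  d <- make_long_data(50, sigma = 0.5, seed = 5)
  expect_error(fit_logistic_mixed(rep(1, length(d$y)), d$x, d$subject),
               "zero variance")
  expect_error(fit_logistic_mixed(d$y, cbind(d$x, dup = d$x[, 1]),
                                  d$subject), "rank deficient")
})

test_that("longitudinal design stacks timepoints with time-invariant
           loading", {
  cfg <- synth_config(n_subjects = 30, seed = 61)
  sim <- sample_disconnection_corpus(cfg)
  coh <- sample_cognition(sim$truth$theta_true, cfg)
  ld <- longitudinal_design(coh, coh$theta_2)
  expect_equal(length(ld$y), 60)
  expect_equal(unname(ld$x[, "time"]), rep(c(0, 1), each = 30))
  expect_equal(ld$x[1:30, "loading"], ld$x[31:60, "loading"])
  expect_equal(unname(ld$x[, "loading:time"]),
               unname(ld$x[, "loading"] * ld$x[, "time"]))
})
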