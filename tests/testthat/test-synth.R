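test_that("synth configuration is validated", {
  cfg <- synth_config()
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$n_subjects, 105L)
  expect_equal(cfg$k_true, 3L)
  expect_length(cfg$dirichlet_alpha, 3)
  expect_error(synth_config(k_true = 30, n_tracts = 24), "k_true")
  expect_error(synth_config(dirichlet_alpha = c(1, 1)), "dirichlet_alpha")
  expect_error(synth_config(total_pseudocount = 0), "positive")
  expect_error(synth_config(causal_factor = 5), "causal_factor")
})

test_that("planted corpus follows the generative model", {
  cfg <- synth_config(n_subjects = 40, seed = 3)
  sim <- sample_disconnection_corpus(cfg)
  expect_equal(dim(sim$corpus$counts), c(40L, 24L))
  expect_true(all(sim$corpus$counts >= 0))
  expect_equal(unname(rowSums(sim$corpus$counts)), rep(1000, 40))
  expect_lt(max(abs(rowSums(sim$truth$beta_true) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(sim$truth$theta_true) - 1)), 1e-9)
  expect_identical(sim$corpus$counts,
                   sample_disconnection_corpus(cfg)$corpus$counts)

  # degenerate single-factor case
  one <- sample_disconnection_corpus(synth_config(n_subjects = 10,
                                                  k_true = 1,
                                                  causal_factor = 1,
                                                  seed = 4))
  expect_equal(unname(one$truth$theta_true[, 1]), rep(1, 10))
})

test_that("corpus column sums match the planted mixture at large N", {
  cfg <- synth_config(n_subjects = 2000, seed = 9)
  sim <- sample_disconnection_corpus(cfg)
  mix <- sim$truth$theta_true %*% sim$truth$beta_true
  expected <- cfg$total_pseudocount * colSums(mix)
  obs <- colSums(sim$corpus$counts)
  # within multinomial error: 6 sigma, sigma^2 <= sum of mean counts
  expect_true(all(abs(obs - expected) <= 6 * sqrt(expected + 1)))
})

test_that("cognition links PSCI to the causal loading with confounds", {
  cfg <- synth_config(n_subjects = 2000, seed = 12)
  sim <- sample_disconnection_corpus(cfg)
  coh <- sample_cognition(sim$truth$theta_true, cfg, seed = 13)
  expect_identical(coh, sample_cognition(sim$truth$theta_true, cfg,
                                         seed = 13))
  expect_true(all(coh$psci_m6 %in% 0:1))

  # top vs bottom tertile of the causal loading
  load <- sim$truth$theta_true[, cfg$causal_factor]
  qs <- quantile(load, c(1 / 3, 2 / 3))
  hi <- mean(coh$psci_m6[load >= qs[2]])
  lo <- mean(coh$psci_m6[load <= qs[1]])
  expect_gt(hi, lo + 0.2)

  # MoCA tracks mean month-6 cognition
  zbar <- rowMeans(coh[, grep("^z_.*_m6$", names(coh))])
  expect_gt(cor(coh$moca, zbar), 0.5)

  # age/education confounding in the planted direction
  expect_lt(cor(coh$age, zbar), 0)
  expect_gt(cor(coh$education, zbar), 0)
})

test_that("null effect and null confounds give a null logistic slope", {
  cfg <- synth_config(n_subjects = 105, effect_beta = 0, confound_age = 0,
                      confound_edu = 0, seed = 1)
  zs <- vapply(1:200, function(r) {
    cfg_r <- synth_config(n_subjects = 105, effect_beta = 0,
                          confound_age = 0, confound_edu = 0, seed = r)
    sim <- sample_disconnection_corpus(cfg_r)
    coh <- sample_cognition(sim$truth$theta_true, cfg_r)
    load <- sim$truth$theta_true[, cfg_r$causal_factor]
    f <- suppressWarnings(fit_logistic(coh$psci_m6, cbind(load = load)))
    unname(f$coef["load"] / f$se["load"])
  }, numeric(1))
  zs <- zs[is.finite(zs)]
  # slope ~ 0 on average and nominal rejection rate
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)) + 0.15)
  expect_lt(mean(abs(zs) > 1.96), 0.10)
})
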