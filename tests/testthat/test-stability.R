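test_that("factor matching finds the optimal permutation", {
  set.seed(4)
  beta <- disconnectr:::rdirichlet(4, rep(0.3, 12))
  perm <- c(3, 1, 4, 2)
  m <- disconnectr:::match_factors(beta, beta[perm, ])
  # matched rows are identical, so each correlation is 1
  expect_equal(m$cor, rep(1, 4), tolerance = 1e-12)
  expect_equal(order(perm), m$perm)
  expect_equal(m$mean_cor, 1, tolerance = 1e-12)
})

test_that("stability is 1 for a single factor and bounded in [0, 1]", {
  cfg <- synth_config(n_subjects = 50, n_tracts = 10, k_true = 1,
                      causal_factor = 1, seed = 31)
  sim <- sample_disconnection_corpus(cfg)
  expect_equal(lda_stability(sim$corpus, 1, n_runs = 3, seed = 1), 1)

  set.seed(12)
  noise <- matrix(rpois(40 * 10, 20), 40, 10)
  s <- lda_stability(noise, 3, n_runs = 3, seed = 1)
  expect_gte(s, 0)
  expect_lte(s, 1)
  expect_error(lda_stability(noise, 3, n_runs = 1), "at least 2")
})

test_that("a planted 3-factor corpus is more stable at K=3 than K=6", {
  cfg <- synth_config(n_subjects = 300, seed = 44)
  sim <- sample_disconnection_corpus(cfg)
  s3 <- lda_stability(sim$corpus, 3, n_runs = 5, seed = 2)
  s6 <- lda_stability(sim$corpus, 6, n_runs = 5, seed = 2)
  expect_gt(s3, s6)
  expect_gt(s3, 0.95)
})

test_that("select_k reports one stability per K and breaks ties low", {
  cfg <- synth_config(n_subjects = 80, n_tracts = 12, seed = 51)
  sim <- sample_disconnection_corpus(cfg)
  rep_ <- select_k(sim$corpus, 2, 4, n_runs = 3, seed = 1)
  expect_equal(rep_$k_values, 2:4)
  expect_length(rep_$stability, 3)
  expect_true(rep_$selected_k %in% 2:4)
  expect_equal(rep_$stability[[paste0("K", rep_$selected_k)]],
               max(rep_$stability))

  one <- select_k(sim$corpus, 3, 3, n_runs = 3, seed = 1)
  expect_equal(one$selected_k, 3)
  expect_error(select_k(sim$corpus, 0, 3), "k_min")
})
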