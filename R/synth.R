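#' Synthetic study configuration
#'
#' Collects every knob of the synthetic cohort generator in one validated
#' list. The defaults describe the study conditions the package is tested
#' under: 105 participants, 24 tracts, 3 latent disconnection factors, and
#' an outcome effect on one causal factor with age/education confounding.
#'
#' @param n_subjects cohort size.
#' @param grid_shape,voxel_mm template grid (voxels, mm).
#' @param n_tracts number of atlas tracts.
#' @param streamlines_per_tract streamlines per bundle.
#' @param k_true number of planted latent factors.
#' @param dirichlet_alpha Dirichlet concentration for the participant
#'   factor weights; a scalar (symmetric) or a length-`k_true` vector. The
#'   default (`NULL`) uses 0.2 for every factor except the causal one,
#'   which gets 0.055: sparse mixed memberships in which most participants
#'   predominantly express a single factor and a minority (about 11%)
#'   carries the causal one, the regime in which a cohort of 105 can both
#'   detect the causal factor and keep its compositional shadow on the
#'   other factors small.
#' @param beta_concentration on-support Dirichlet pseudo-count for the
#'   planted tract signatures.
#' @param support_overlap off-support Dirichlet pseudo-count; small values
#'   give nearly disjoint tract supports across factors.
#' @param total_pseudocount multinomial total per participant.
#' @param causal_factor index of the factor that drives cognition.
#' @param effect_beta strength (in domain z-score units per unit loading)
#'   with which the causal factor depresses cognitive scores.
#' @param confound_age,confound_edu z-score shift per standard deviation of
#'   age and education.
#' @param noise_sd residual standard deviation of domain z-scores.
#' @param domain_weights relative vulnerability of the four cognitive
#'   domains (memory, attention/executive, visuospatial, language) to the
#'   causal factor.
#' @param baseline_z mean domain z-score of an unexposed average
#'   participant at months 6 and 36 (length-2 vector).
#' @param psci_threshold impairment threshold on the minimum domain
#'   z-score.
#' @param seed master seed.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 105L,
                         grid_shape = c(40L, 40L, 40L),
                         voxel_mm = c(4, 4, 4),
                         n_tracts = 24L,
                         streamlines_per_tract = 20L,
                         k_true = 3L,
                         dirichlet_alpha = NULL,
                         beta_concentration = 2,
                         support_overlap = 0.05,
                         total_pseudocount = 1000L,
                         causal_factor = 2L,
                         effect_beta = 1.05,
                         confound_age = -0.25,
                         confound_edu = 0.25,
                         noise_sd = 0.6,
                         domain_weights = c(memory = 0.6, attention = 1,
                                            visuospatial = 0.7,
                                            language = 0.9),
                         baseline_z = c(m6 = -0.78, m36 = -0.56),
                         psci_threshold = -1.5,
                         seed = 1L) {
  causal_factor <- as.integer(causal_factor)
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- rep(0.2, k_true)
    if (causal_factor >= 1L && causal_factor <= k_true)
      dirichlet_alpha[causal_factor] <- 0.055
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
              n_tracts = as.integer(n_tracts),
              streamlines_per_tract = as.integer(streamlines_per_tract),
              k_true = as.integer(k_true),
              dirichlet_alpha = dirichlet_alpha,
              beta_concentration = beta_concentration,
              support_overlap = support_overlap,
              total_pseudocount = as.integer(total_pseudocount),
              causal_factor = as.integer(causal_factor),
              effect_beta = effect_beta,
              confound_age = confound_age, confound_edu = confound_edu,
              noise_sd = noise_sd, domain_weights = domain_weights,
              baseline_z = baseline_z, psci_threshold = psci_threshold,
              seed = as.integer(seed))
  stop_if(cfg$n_subjects < 1L || cfg$n_tracts < 2L ||
            cfg$streamlines_per_tract < 1L || cfg$total_pseudocount < 1L,
          "all counts must be positive")
  stop_if(cfg$k_true < 1L || cfg$k_true > cfg$n_tracts,
          "k_true must be between 1 and n_tracts")
  stop_if(!length(cfg$dirichlet_alpha) %in% c(1L, cfg$k_true) ||
            any(cfg$dirichlet_alpha <= 0),
          "dirichlet_alpha must be a positive scalar or length-k_true vector")
  stop_if(cfg$beta_concentration <= 0 || cfg$support_overlap <= 0,
          "Dirichlet concentrations must be positive")
  stop_if(cfg$causal_factor < 1L || cfg$causal_factor > cfg$k_true,
          "causal_factor must index one of the k_true factors")
  stop_if(cfg$noise_sd <= 0, "noise_sd must be positive")
  stop_if(length(cfg$domain_weights) != 4L || any(cfg$domain_weights < 0),
          "domain_weights must be 4 nonnegative values")
  stop_if(length(cfg$baseline_z) != 2L, "baseline_z must have 2 timepoints")
  class(cfg) <- "synth_config"
  cfg
}

#' Sample a disconnection corpus from the exact factor-model generative
#' process
#'
#' Draws participant factor weights `theta` from a Dirichlet, factor tract
#' signatures `beta` from sparse Dirichlets with (nearly) disjoint supports
#' across factors, and each participant's tract counts from a multinomial
#' with mean `theta_d %*% beta`. Because this bypasses lesion geometry,
#' parameter-recovery tests against the returned ground truth are
#' exact-model tests of the estimator; the geometric route
#' (lesions -> disconnectome -> pseudo-counts) exercises the full chain
#' instead.
#'
#' @param config a `synth_config`.
#' @return list with `corpus` (a `disconnection_corpus`) and `truth`
#'   (list with row-stochastic `beta_true` (k x T), `theta_true` (N x k),
#'   `causal_factor_index`, `outcome_coeffs`).
#' @export
sample_disconnection_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  k <- config$k_true
  T_ <- config$n_tracts
  N <- config$n_subjects
  alpha <- rep(config$dirichlet_alpha, length.out = k)

  with_seed(config$seed, {
    support <- rep_len(seq_len(k), T_) # round-robin tract blocks
    beta_true <- t(vapply(seq_len(k), function(f) {
      a <- ifelse(support == f, config$beta_concentration,
                  config$support_overlap)
      drop(rdirichlet(1L, a))
    }, numeric(T_)))
    theta_true <- if (k == 1L) matrix(1, N, 1L) else rdirichlet(N, alpha)
    mix <- theta_true %*% beta_true
    counts <- t(vapply(seq_len(N), function(d) {
      drop(stats::rmultinom(1L, config$total_pseudocount, mix[d, ]))
    }, numeric(T_)))
    storage.mode(counts) <- "integer"
    tn <- canonical_registry()
    colnames(counts) <- if (T_ <= length(tn)) tn[seq_len(T_)] else
      sprintf("tract_%02d", seq_len(T_))
    rownames(counts) <- sprintf("sub-%03d", seq_len(N))
    colnames(beta_true) <- colnames(counts)
    rownames(theta_true) <- rownames(counts)

    list(
      corpus = new_corpus(counts),
      truth = list(
        beta_true = beta_true,
        theta_true = theta_true,
        causal_factor_index = config$causal_factor,
        outcome_coeffs = c(effect_beta = config$effect_beta,
                           confound_age = config$confound_age,
                           confound_edu = config$confound_edu)
      )
    )
  })
}

#' Sample cognitive outcomes linked to a causal disconnection factor
#'
#' Generates a cohort table: demographics (age ~ Normal(63, 12), education
#' ~ Normal(12, 4)), intracranial volume, lognormal infarct and WMH volume
#' surrogates, four domain z-scores at months 6 and 36, MoCA correlated
#' with mean cognition, and PSCI status at both timepoints from the
#' threshold rule ([psci_classify()]). Each domain z-score is
#' `baseline - effect_beta * w_domain * theta[, causal] + confounds +
#' noise`, with noise split into a subject-by-domain component shared
#' across timepoints and an independent timepoint component, so cognitive
#' status is correlated, but not frozen, across visits.
#'
#' @param theta_true row-stochastic matrix of participant factor loadings
#'   (N x k), e.g. from [sample_disconnection_corpus()].
#' @param config a `synth_config`.
#' @param seed integer seed (independent of the corpus seed).
#' @return data.frame with one row per participant: `subject_id`, `age`,
#'   `education`, `moca`, `icv_cm3`, `infarct_volume`, `wmh_volume`,
#'   `z_<domain>_m<t>` (8 columns), `psci_m6`, `psci_m36`, and the true
#'   loadings `theta_<j>`.
#' @export
sample_cognition <- function(theta_true, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synth_config"))
  theta_true <- as.matrix(theta_true)
  stop_if(any(abs(rowSums(theta_true) - 1) > 1e-6),
          "theta_true rows must sum to 1")
  N <- nrow(theta_true)
  wd <- config$domain_weights
  domains <- c("memory", "attention", "visuospatial", "language")

  with_seed(seed, {
    age <- stats::rnorm(N, 63, 12)
    edu <- stats::rnorm(N, 12, 4)
    icv <- stats::rnorm(N, 1450, 130)
    # lognormal volume surrogates matched to cohort moments
    # (infarct 10.28 +/- 17.10 cm^3, WMH 9.01 +/- 15.83 cm^3)
    ln_pars <- function(m, s) {
      s2 <- log(1 + (s / m)^2)
      c(mu = log(m) - s2 / 2, sd = sqrt(s2))
    }
    pi_ <- ln_pars(10.28, 17.10)
    pw <- ln_pars(9.01, 15.83)
    infarct_vol <- stats::rlnorm(N, pi_["mu"], pi_["sd"])
    wmh_vol <- stats::rlnorm(N, pw["mu"], pw["sd"])

    conf <- config$confound_age * (age - 63) / 12 +
      config$confound_edu * (edu - 12) / 4
    load <- theta_true[, config$causal_factor]

    u <- matrix(stats::rnorm(N * 4, 0, config$noise_sd), N, 4) # shared
    zmat <- function(baseline) {
      e <- matrix(stats::rnorm(N * 4, 0, config$noise_sd), N, 4)
      sweep(-outer(config$effect_beta * load, wd), 1, conf + baseline, `+`) +
        sqrt(0.35) * u + sqrt(0.65) * e
    }
    z6 <- zmat(config$baseline_z[1])
    z36 <- zmat(config$baseline_z[2])
    colnames(z6) <- paste0("z_", domains, "_m6")
    colnames(z36) <- paste0("z_", domains, "_m36")

    psci6 <- apply(z6, 1, psci_classify, threshold = config$psci_threshold)
    psci36 <- apply(z36, 1, psci_classify, threshold = config$psci_threshold)

    moca <- round(pmin(30, pmax(0, 26 + 1.6 * rowMeans(z6) +
                                  stats::rnorm(N, 0, 1.2))))

    out <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(N)),
      age = age, education = edu, moca = moca, icv_cm3 = icv,
      infarct_volume = infarct_vol, wmh_volume = wmh_vol,
      z6, z36, psci_m6 = psci6, psci_m36 = psci36,
      stringsAsFactors = FALSE
    )
    theta_cols <- as.data.frame(theta_true)
    names(theta_cols) <- paste0("theta_", seq_len(ncol(theta_true)))
    cbind(out, theta_cols)
  })
}
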