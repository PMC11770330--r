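# Pipeline orchestration: simulate -> map-lesions -> disconnect ->
# factorize -> associate, as one configured, seeded, manifest-logged run.

pipeline_stages <- c("simulate", "map_lesions", "disconnect", "factorize",
                     "associate")

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()]:
#' a master `seed` (per-stage seeds are derived deterministically from it),
#' the `synth` block (see [synth_config()]), and per-stage parameter
#' blocks. Any subset can be overridden via a YAML file or an in-memory
#' list; unknown keys are rejected before any stage runs.
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    synth = list(),          # overrides for synth_config()
    disconnect = list(step_mm = NULL),
    factorize = list(scale = 10, k_min = 2L, k_max = 6L, n_runs = 5L,
                     eta = 0.01, source = "planted"),
    associate = list(n_perm = 9999L, q = 0.05, nq = 15L)
  )
}

validate_run_config <- function(config) {
  def <- default_run_config()
  bad <- setdiff(names(config), names(def))
  stop_if(length(bad) > 0,
          "unknown configuration key(s): ", paste(bad, collapse = ", "))
  out <- utils::modifyList(def, config)
  for (blk in c("disconnect", "factorize", "associate")) {
    bad <- setdiff(names(out[[blk]]), names(def[[blk]]))
    stop_if(length(bad) > 0, sprintf("unknown key(s) in '%s': %s", blk,
                                     paste(bad, collapse = ", ")))
  }
  stop_if(!is.numeric(out$seed) || length(out$seed) != 1L,
          "seed must be a single integer")
  stop_if(!out$factorize$source %in% c("planted", "geometric"),
          "factorize$source must be 'planted' or 'geometric'")
  # synth block is validated by synth_config itself
  do.call(synth_config, c(out$synth, list(seed = derive_seed(out$seed,
                                                             "simulate"))))
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the keys of
#'   [default_run_config()].
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

config_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stage_outputs <- function(stage, out_dir) {
  f <- function(...) file.path(out_dir, ...)
  switch(stage,
    simulate = c(f("template", "meta.json"), f("atlas", "header.json"),
                 f("atlas", "coordinates.csv"), f("cohort.csv"),
                 f("corpus.csv"), f("truth_beta.csv"), f("truth_theta.csv"),
                 f("masks_index.csv")),
    map_lesions = c(f("volumes_infarct.csv"), f("volumes_wmh.csv"),
                    f("parcel_loads.csv")),
    disconnect = c(f("profiles_infarct.csv"), f("profiles_wmh.csv")),
    factorize = c(f("factors", "stability.csv"), f("factors", "beta.csv"),
                  f("factors", "theta.csv"), f("factors", "model.json")),
    associate = c(f("associations", "logistic_factors.csv"),
                  f("associations", "lrt.json"), f("associations", "cca.json"),
                  f("associations", "mixed.json"),
                  f("associations", "transition.json"))
  )
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

stage_simulate <- function(cfg, out_dir) {
  seed <- derive_seed(cfg$seed, "simulate")
  scfg <- do.call(synth_config, c(cfg$synth, list(seed = seed)))
  tpl <- make_template(scfg$grid_shape, scfg$voxel_mm,
                       seed = derive_seed(seed, "template"))
  atl <- make_atlas(tpl, scfg$n_tracts, scfg$streamlines_per_tract,
                    seed = derive_seed(seed, "atlas"))
  inf <- sample_lesions(tpl, "infarct", scfg$n_subjects,
                        seed = derive_seed(seed, "infarct"))
  wmh <- sample_lesions(tpl, "wmh", scfg$n_subjects,
                        seed = derive_seed(seed, "wmh"))
  sim <- sample_disconnection_corpus(scfg)
  coh <- sample_cognition(sim$truth$theta_true, scfg,
                          seed = derive_seed(seed, "cognition"))

  write_template(tpl, file.path(out_dir, "template"))
  write_atlas(atl, file.path(out_dir, "atlas"))
  idx <- list()
  for (kind in c("infarct", "wmh")) {
    d <- file.path(out_dir, "masks", kind)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    masks <- if (kind == "infarct") inf else wmh
    for (m in masks) {
      write_nifti_grid(m$grid, m$affine,
                       file.path(d, paste0(m$subject_id, ".nii")))
    }
    idx[[kind]] <- data.frame(subject_id = vapply(masks, `[[`, character(1),
                                                  "subject_id"),
                              kind = kind,
                              file = file.path("masks", kind,
                                               paste0(vapply(masks, `[[`,
                                                             character(1),
                                                             "subject_id"),
                                                      ".nii")))
  }
  utils::write.csv(do.call(rbind, idx), file.path(out_dir, "masks_index.csv"),
                   row.names = FALSE)
  utils::write.csv(coh, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write_matrix_csv(sim$corpus$counts, file.path(out_dir, "corpus.csv"))
  write_matrix_csv(sim$truth$beta_true, file.path(out_dir, "truth_beta.csv"))
  write_matrix_csv(sim$truth$theta_true, file.path(out_dir, "truth_theta.csv"))
  invisible(NULL)
}

read_masks <- function(out_dir, kind) {
  idx <- utils::read.csv(file.path(out_dir, "masks_index.csv"))
  idx <- idx[idx$kind == kind, , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(i) {
    g <- read_nifti_grid(file.path(out_dir, idx$file[i]))
    lesion_mask(array(as.integer(round(g$grid)), dim(g$grid)), g$affine,
                idx$subject_id[i], kind)
  })
}

stage_map_lesions <- function(cfg, out_dir) {
  tpl <- read_template(file.path(out_dir, "template"))
  coh <- utils::read.csv(file.path(out_dir, "cohort.csv"))
  parc <- bullseye_parcellation(tpl)
  mean_icv <- mean(coh$icv_cm3)
  for (kind in c("infarct", "wmh")) {
    masks <- read_masks(out_dir, kind)
    rows <- lapply(masks, function(m) {
      raw <- lesion_volume(m)
      icv <- coh$icv_cm3[match(m$subject_id, coh$subject_id)]
      tv <- territory_volumes(m, tpl)
      c(list(subject_id = m$subject_id, raw_cm3 = raw,
             normalized_cm3 = normalize_volume(raw, icv, mean_icv),
             dominant_territory = tv$dominant),
        as.list(tv$per_territory_cm3))
    })
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, check.names = FALSE)))
    utils::write.csv(df, file.path(out_dir,
                                   sprintf("volumes_%s.csv", kind)),
                     row.names = FALSE)
    if (kind == "wmh") {
      pl <- t(vapply(masks, parcel_loads, numeric(36),
                     parcellation = parc))
      rownames(pl) <- vapply(masks, `[[`, character(1), "subject_id")
      write_matrix_csv(pl, file.path(out_dir, "parcel_loads.csv"))
    }
  }
  invisible(NULL)
}

stage_disconnect <- function(cfg, out_dir) {
  atl <- read_atlas(file.path(out_dir, "atlas"))
  raster <- rasterize_atlas(atl, step_mm = cfg$disconnect$step_mm)
  for (kind in c("infarct", "wmh")) {
    masks <- read_masks(out_dir, kind)
    profs <- lapply(masks, function(m)
      disconnection_profile(atl, m, raster = raster))
    write_matrix_csv(profile_matrix(profs),
                     file.path(out_dir, sprintf("profiles_%s.csv", kind)))
  }
  invisible(NULL)
}

stage_factorize <- function(cfg, out_dir) {
  fz <- cfg$factorize
  seed <- derive_seed(cfg$seed, "factorize")
  if (fz$source == "planted") {
    counts <- read_matrix_csv(file.path(out_dir, "corpus.csv"))
    storage.mode(counts) <- "integer"
    corpus <- new_corpus(counts)
  } else {
    prof <- read_matrix_csv(file.path(out_dir, "profiles_wmh.csv"))
    corpus <- encode_pseudocounts(prof, scale = fz$scale)
  }
  rep_ <- select_k(corpus, fz$k_min, fz$k_max, n_runs = fz$n_runs,
                   seed = seed, eta = fz$eta)
  fit <- fit_lda(corpus, rep_$selected_k, eta = fz$eta, seed = seed)
  d <- file.path(out_dir, "factors")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(k = rep_$k_values,
                              stability = unname(rep_$stability)),
                   file.path(d, "stability.csv"), row.names = FALSE)
  write_matrix_csv(fit$beta, file.path(d, "beta.csv"))
  write_matrix_csv(fit$theta, file.path(d, "theta.csv"))
  jsonlite::write_json(
    list(k = fit$k, alpha = fit$alpha, eta = fit$eta, seed = fit$seed,
         elbo = fit$elbo, n_iter = fit$n_iter, converged = fit$converged,
         selected_k = rep_$selected_k, source = fz$source,
         stability_metric = paste(
           "mean pairwise optimal-assignment Pearson correlation of",
           "tract signatures across restarts"),
         excluded_subjects = corpus$excluded_ids),
    file.path(d, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_associate <- function(cfg, out_dir) {
  as_ <- cfg$associate
  seed <- derive_seed(cfg$seed, "associate")
  coh <- utils::read.csv(file.path(out_dir, "cohort.csv"))
  theta <- read_matrix_csv(file.path(out_dir, "factors", "theta.csv"))
  theta <- theta[match(coh$subject_id, rownames(theta)), , drop = FALSE]
  k <- ncol(theta)
  d <- file.path(out_dir, "associations")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)

  # factor-wise logistic models per timepoint, BH within timepoint family
  rows <- list()
  for (tp in c("m6", "m36")) {
    y <- coh[[paste0("psci_", tp)]]
    fits <- lapply(seq_len(k), function(j) {
      suppressWarnings(fit_logistic(
        y, cbind(loading = theta[, j], age = coh$age,
                 education = coh$education)))
    })
    pv <- vapply(fits, function(f) unname(f$p["loading"]), numeric(1))
    adj <- rep(NA_real_, k)
    okp <- is.finite(pv)
    if (any(okp)) adj[okp] <- bh_fdr(pv[okp], q = as_$q)$p_adjusted
    for (j in seq_len(k)) {
      f <- fits[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = tp, factor = j,
        beta = unname(f$coef["loading"]), se = unname(f$se["loading"]),
        or = unname(f$or["loading"]),
        ci_lo = unname(f$ci95[2, "lower"]), ci_hi = unname(f$ci95[2, "upper"]),
        p = pv[j], p_fdr = adj[j], separation = f$separation)
    }
  }
  logit_df <- do.call(rbind, rows)
  utils::write.csv(logit_df, file.path(d, "logistic_factors.csv"),
                   row.names = FALSE)

  # candidate factor = strongest BH-corrected association across timepoints
  best <- logit_df[order(logit_df$p_fdr), ][1, "factor"]

  # nested likelihood-ratio test per timepoint:
  #   reduced: psci ~ moca + wmh_volume + age + education
  #   full:    reduced + candidate factor loading
  lrt <- lapply(c("m6", "m36"), function(tp) {
    y <- coh[[paste0("psci_", tp)]]
    xr <- cbind(moca = coh$moca, wmh = coh$wmh_volume, age = coh$age,
                education = coh$education)
    xf <- cbind(xr, loading = theta[, best])
    fr <- suppressWarnings(fit_logistic(y, xr))
    ff <- suppressWarnings(fit_logistic(y, xf))
    lt <- lr_test(ff$loglik, fr$loglik, df_diff = 1)
    list(timepoint = tp, factor = best, loglik_full = ff$loglik,
         loglik_reduced = fr$loglik, chi2 = lt$chi2, p = lt$p)
  })
  jsonlite::write_json(lrt, file.path(d, "lrt.json"), auto_unbox = TRUE,
                       digits = NA)

  # CCA: domain z-scores vs candidate loading, per timepoint
  cca <- lapply(c("m6", "m36"), function(tp) {
    X <- as.matrix(coh[, paste0("z_", c("memory", "attention",
                                        "visuospatial", "language"),
                                "_", tp)])
    cc <- cca_first(X, theta[, best], n_perm = as_$n_perm,
                    seed = derive_seed(seed, paste0("cca_", tp)))
    list(timepoint = tp, factor = best, r1 = cc$r1, perm_p = cc$perm_p,
         n_perm = cc$n_perm,
         x_weights = as.list(stats::setNames(cc$x_weights, colnames(X))))
  })
  jsonlite::write_json(cca, file.path(d, "cca.json"), auto_unbox = TRUE,
                       digits = NA)

  # longitudinal random-intercept logistic model for the candidate factor
  ld <- longitudinal_design(coh, theta[, best])
  mf <- fit_logistic_mixed(ld$y, ld$x, ld$subject, nq = as_$nq)
  jsonlite::write_json(
    list(factor = best, coef = as.list(mf$coef), se = as.list(mf$se),
         t = as.list(mf$t), or = as.list(mf$or), p = as.list(mf$p),
         p_fdr = as.list(stats::setNames(
           bh_fdr(mf$p[-1])$p_adjusted, names(mf$p)[-1])),
         sigma2 = mf$sigma2, loglik = mf$loglik, nq = mf$nq,
         converged = mf$converged),
    file.path(d, "mixed.json"), auto_unbox = TRUE, digits = NA)

  tt <- transition_table(coh$psci_m6, coh$psci_m36)
  jsonlite::write_json(unclass(tt), file.path(d, "transition.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the full synthetic disconnection pipeline
#'
#' Executes the five stages (simulate, map-lesions, disconnect, factorize,
#' associate) in order into `out_dir`, skipping stages whose outputs
#' already exist with checksums recorded by a previous run under an
#' identical configuration (unless `force = TRUE`). Per-stage seeds are
#' derived deterministically from the master seed, so a stage can be rerun
#' in isolation with identical randomness.
#'
#' @param config configuration list (see [default_run_config()]) or a path
#'   to a YAML file.
#' @param out_dir output directory.
#' @param force rerun all stages regardless of existing outputs.
#' @return a `run_manifest` (invisibly written to `manifest.json`): list
#'   with the config snapshot, package version, and per-stage status,
#'   seeds, output checksums and timings.
#' @export
run_pipeline <- function(config = list(), out_dir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- config_digest(cfg)

  prev <- NULL
  mf_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(mf_path)) {
    prev <- tryCatch(jsonlite::read_json(mf_path, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) && !identical(prev$config_digest, digest)) prev <- NULL
  }

  stages <- list()
  warns <- character(0)
  for (st in pipeline_stages) {
    outs <- stage_outputs(st, out_dir)
    can_skip <- !force && !is.null(prev) && all(file.exists(outs)) &&
      st %in% names(prev$stages) &&
      identical(unname(unlist(prev$stages[[st]]$checksums)),
                unname(tools::md5sum(outs)))
    if (can_skip) {
      stages[[st]] <- prev$stages[[st]]
      stages[[st]]$status <- "skipped"
      next
    }
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch({
        switch(st,
               simulate = stage_simulate(cfg, out_dir),
               map_lesions = stage_map_lesions(cfg, out_dir),
               disconnect = stage_disconnect(cfg, out_dir),
               factorize = stage_factorize(cfg, out_dir),
               associate = stage_associate(cfg, out_dir))
        "ok"
      }, error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", st, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(res, "error")) {
      stop(sprintf("pipeline stage '%s' failed: %s", st,
                   conditionMessage(res)), call. = FALSE)
    }
    rel <- substring(outs, nchar(out_dir) + 2L)
    stages[[st]] <- list(
      status = "run",
      seed = derive_seed(cfg$seed, st),
      checksums = as.list(stats::setNames(unname(tools::md5sum(outs)), rel)),
      elapsed_s = as.numeric(Sys.time() - t0, units = "secs")
    )
  }

  manifest <- list(
    package = "disconnectr",
    version = as.character(utils::packageVersion("disconnectr")),
    config = cfg,
    config_digest = digest,
    stages = stages,
    warnings = warns
  )
  jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

#' Summarize a completed pipeline run
#'
#' Reads the outputs of a finished [run_pipeline()] directory and builds
#' the summary a reader of the study tables would expect: per-factor
#' top-tract tables with cumulative load shares, the stability curve, the
#' factor-wise logistic table, the likelihood-ratio tests, the permutation
#' CCA results, the longitudinal mixed model, and the PSCI transition
#' table.
#'
#' @param out_dir directory of a completed run.
#' @param top_k number of leading tracts to list per factor.
#' @return a `pipeline_report` list; its print method renders the tables.
#' @export
pipeline_report <- function(out_dir, top_k = 10L) {
  need <- c(file.path(out_dir, "factors", "beta.csv"),
            file.path(out_dir, "associations", "logistic_factors.csv"))
  stop_if(!all(file.exists(need)),
          "missing stage outputs; run the pipeline first")
  beta <- read_matrix_csv(file.path(out_dir, "factors", "beta.csv"))
  stab <- utils::read.csv(file.path(out_dir, "factors", "stability.csv"))
  top <- lapply(seq_len(nrow(beta)), function(i) {
    row <- beta[i, ]
    names(row) <- colnames(beta)
    ls <- factor_load_share(row, min(top_k, length(row)))
    list(factor = i, tracts = ls$tracts, share = ls$share)
  })
  structure(list(
    stability = stab,
    top_tracts = top,
    logistic = utils::read.csv(file.path(out_dir, "associations",
                                         "logistic_factors.csv")),
    lrt = jsonlite::read_json(file.path(out_dir, "associations", "lrt.json"),
                              simplifyVector = TRUE),
    cca = jsonlite::read_json(file.path(out_dir, "associations", "cca.json"),
                              simplifyVector = TRUE),
    mixed = jsonlite::read_json(file.path(out_dir, "associations",
                                          "mixed.json"),
                                simplifyVector = TRUE),
    transition = jsonlite::read_json(file.path(out_dir, "associations",
                                               "transition.json"),
                                     simplifyVector = TRUE)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Latent disconnection factor report ==\n\n")
  cat("Stability by K:\n")
  print(x$stability, row.names = FALSE)
  for (tt in x$top_tracts) {
    cat(sprintf("\nFactor %d: top %d tracts carry %.0f%% of the load\n",
                tt$factor, length(tt$tracts), 100 * tt$share))
    cat(paste0("  ", tt$tracts, "\n"), sep = "")
  }
  cat("\nFactor-wise logistic associations (age/education adjusted):\n")
  print(x$logistic, row.names = FALSE, digits = 3)
  cat("\nLikelihood-ratio tests (factor added to moca+wmh+age+edu):\n")
  print(as.data.frame(x$lrt), row.names = FALSE, digits = 4)
  cat("\nPermutation CCA (domain z-scores vs factor loading):\n")
  print(as.data.frame(x$cca[c("timepoint", "factor", "r1", "perm_p")]),
        row.names = FALSE, digits = 4)
  cat(sprintf("\nLongitudinal mixed model: factor OR = %.2f (p = %.3g), sigma2 = %.2f\n",
              x$mixed$or$loading, x$mixed$p$loading, x$mixed$sigma2))
  cat(sprintf("\nTransitions: %d/%d impaired at months 6/36, %d converters of %d\n",
              x$transition$month6_total, x$transition$month36_total,
              x$transition$converters, x$transition$n))
  invisible(x)
}
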