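#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a cohort, classify preferences, fit the requested
#' models hierarchically to the learning trials of the dropout blocks,
#' compare them (PSIS-LOO and held-out trial-11 IC), summarize devaluation
#' behavior and report bias, export wf-normalized regressors for the
#' winning separable-outcome model, and write every table plus a manifest
#' (config, seeds, package version) under `out_dir`.
#'
#' @param config Named list as returned by [read_run_config()]; unknown
#'   models or missing input files abort before any computation.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `labels`, `fits`, `comparison`, `devaluation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  config <- utils::modifyList(read_run_config_defaults(), config)
  for (m in config$models) model_code(m) # validate before any compute
  if (!is.null(config$trials_csv) && !file.exists(config$trials_csv)) {
    stop("trials_csv does not exist: ", config$trials_csv, call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  # --- stage 1: cohort --------------------------------------------------
  if (!is.null(config$trials_csv)) {
    cohort <- read_trials(config$trials_csv)
    reports <- NULL
  } else {
    design <- if (config$design %in% c("online", "fmri")) {
      design_spec(config$design)
    } else if (identical(config$design, "conflict_dropout")) {
      design_conflict_dropout()
    } else {
      read_design_yaml(config$design)
    }
    params <- sample_cohort_params(recovery_hyper(), config$n_agents,
                                   model = "M2Out",
                                   seed = child_seed(seed, 1))
    cohort <- simulate_cohort(params, design, seed = child_seed(seed, 2))
    write_trials(cohort, file.path(config$out_dir, "trials.csv"))
    write_true_params(cohort, file.path(config$out_dir, "true_params.csv"))
    reports <- tryCatch(
      simulate_cohort_reports(cohort, noise_sd = config$noise_sd,
                              seed = child_seed(seed, 3)),
      error = function(e) NULL)
    if (!is.null(reports)) {
      utils::write.csv(as.data.frame(reports),
                       file.path(config$out_dir, "reports.csv"),
                       row.names = FALSE)
    }
  }

  # --- stage 2: classification -----------------------------------------
  labels <- classify_cohort(cohort)
  utils::write.csv(as.data.frame(labels),
                   file.path(config$out_dir, "preference_labels.csv"),
                   row.names = FALSE)

  # --- stage 3: fits ----------------------------------------------------
  has_dropout <- any(cohort$dropout_type != "None")
  fits <- lapply(seq_along(config$models), function(k) {
    fit_hierarchical(config$models[[k]], cohort,
                     trials_subset = "learning_only",
                     blocks = if (has_dropout) "dropout" else "all",
                     config = fit_config(chains = config$chains,
                                         warmup = config$warmup,
                                         draws = config$draws,
                                         seed = child_seed(seed, 10 + k)))
  })
  names(fits) <- config$models
  estimates <- dplyr::bind_rows(lapply(names(fits), function(m) {
    tibble::add_column(point_estimates(fits[[m]]), model = m, .before = 1L)
  }))
  utils::write.csv(as.data.frame(estimates),
                   file.path(config$out_dir, "point_estimates.csv"),
                   row.names = FALSE)

  # --- stage 4: comparison ---------------------------------------------
  comparison <- NULL
  if (has_dropout && any(cohort$trial_index == 11L)) {
    comparison <- compare_models(fits, cohort)
    utils::write.csv(as.data.frame(comparison$looic),
                     file.path(config$out_dir, "looic.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(comparison$trial11_ic),
                     file.path(config$out_dir, "trial11_ic.csv"),
                     row.names = FALSE)
  }

  # --- stage 5: behavioral summaries -----------------------------------
  devaluation <- NULL
  if (has_dropout && any(cohort$trial_index == 11L)) {
    devaluation <- devaluation_summary(cohort, labels)
    utils::write.csv(as.data.frame(devaluation),
                     file.path(config$out_dir, "devaluation.csv"),
                     row.names = FALSE)
  }

  # --- stage 6: regressors for the winning model ------------------------
  if ("M2Out" %in% names(fits)) {
    est <- point_estimates(fits[["M2Out"]])
    regs <- dplyr::bind_rows(lapply(seq_len(nrow(est)), function(i) {
      sid <- est$subject_id[i]
      pars <- model_params("M2Out", wf = min(max(est$wf[i], 1e-6), 1 - 1e-6),
                           lr_m = est$lr_m[i], lr_s = est$lr_s[i],
                           tau = est$tau[i])
      extract_regressors(pars, cohort[cohort$subject_id == sid, ])
    }))
    utils::write.csv(as.data.frame(regs),
                     file.path(config$out_dir, "regressors.csv"),
                     row.names = FALSE)
  }

  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   seed = seed,
                   package_version = as.character(utils::packageVersion("moralbandit")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, labels = labels, fits = fits,
                 comparison = comparison, devaluation = devaluation,
                 manifest = manifest))
}

read_run_config_defaults <- function() {
  list(design = "online", models = c("M0", "M2Out"), n_agents = 10L,
       trials_csv = NULL, seed = 1L, chains = 2L, warmup = 300L,
       draws = 300L, noise_sd = 10, out_dir = "results")
}
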