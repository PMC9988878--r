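#' Read a trial-level cohort from CSV
#'
#' Validates the table on load: required columns, outcome codes in
#' \{+1, -1, 0\}, symbols in \{1, 2\}, contiguous 1-based trial indices
#' within each subject x block, and phase consistent with trial position.
#' Errors name the offending rows.
#'
#' @param path CSV file with columns `subject_id`, `block_id`, `condition`,
#'   `dropout_type`, `trial_index`, `phase`, `chosen_symbol`, `out_money`,
#'   `out_shock`.
#' @return Validated cohort tibble.
#' @export
read_trials <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(dat)) stop("trial file is empty: ", path, call. = FALSE)
  validate_trials(tibble::as_tibble(dat))
}

#' Validate a trial-level cohort table
#'
#' @param cohort Tibble as described in [read_trials()].
#' @return The cohort, invisibly unchanged, or an error naming bad rows.
#' @export
validate_trials <- function(cohort) {
  req <- c("subject_id", "block_id", "condition", "dropout_type",
           "trial_index", "phase", "chosen_symbol", "out_money", "out_shock")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_rows <- function(ok, what) {
    if (any(!ok)) {
      stop(what, " in rows: ",
           paste(utils::head(which(!ok), 5L), collapse = ", "),
           if (sum(!ok) > 5L) " ..." else "", call. = FALSE)
    }
  }
  bad_rows(cohort$condition %in% c("Conflict", "NoConflict"),
           "unknown condition")
  bad_rows(cohort$dropout_type %in% c("None", "MoneyDropout", "ShockDropout"),
           "unknown dropout_type")
  bad_rows(cohort$chosen_symbol %in% c(1L, 2L), "chosen_symbol outside {1, 2}")
  bad_rows(cohort$out_money %in% c(-1, 0, 1), "out_money outside {+1, -1, 0}")
  bad_rows(cohort$out_shock %in% c(-1, 0, 1), "out_shock outside {+1, -1, 0}")
  bad_rows(cohort$phase %in% c("learning", "dropout"), "unknown phase")
  bad_rows((cohort$trial_index <= 10L) == (cohort$phase == "learning"),
           "phase inconsistent with trial_index")
  key <- paste(cohort$subject_id, cohort$block_id)
  per_block <- split(cohort$trial_index, factor(key, levels = unique(key)))
  ok <- vapply(per_block, function(t) identical(as.integer(t), seq_along(t)),
               TRUE)
  if (any(!ok)) {
    stop("non-contiguous trial indices in subject x block: ",
         paste(utils::head(names(per_block)[!ok], 5L), collapse = "; "),
         call. = FALSE)
  }
  cohort
}

#' Write a cohort (and optional sidecars) to CSV
#'
#' @param cohort Trial tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  req <- c("subject_id", "block_id", "condition", "dropout_type",
           "trial_index", "phase", "chosen_symbol", "out_money", "out_shock")
  utils::write.csv(as.data.frame(cohort)[, req], path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth generating parameters of a simulated cohort
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_true_params <- function(cohort, path) {
  tp <- attr(cohort, "true_params")
  if (is.null(tp)) stop("cohort carries no true parameters", call. = FALSE)
  tab <- dplyr::bind_rows(lapply(seq_along(tp), function(i) {
    p <- tp[[i]]
    tibble::as_tibble(c(list(subject_id = i, model = p$model),
                        p[model_param_names(p$model)]))
  }))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized fields: `design` (`"online"`, `"fmri"`, or a path to a design
#' YAML), `models` (character vector), `n_agents`, `trials_csv` (ingest
#' instead of simulating), `seed`, `chains`, `warmup`, `draws`, `noise_sd`,
#' `out_dir`.
#'
#' @param path YAML file.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(design = "online", models = c("M0", "M2Out"),
                   n_agents = 10L, trials_csv = NULL, seed = 1L,
                   chains = 2L, warmup = 300L, draws = 300L,
                   noise_sd = 10, out_dir = "results")
  utils::modifyList(defaults, cfg)
}
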