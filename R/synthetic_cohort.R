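#' Describe a synthetic agent
#'
#' @param model Generating model name.
#' @param params A [model_params()] for that model.
#' @param seed Optional integer seed used when the agent is simulated.
#' @return An `agent_spec` list.
#' @export
agent_spec <- function(model, params, seed = NULL) {
  model_code(model)
  stopifnot(inherits(params, "model_params"), params$model == model)
  structure(list(model = model, params = params, seed = seed),
            class = "agent_spec")
}

#' Draw heterogeneous cohort parameters from group-level distributions
#'
#' Each parameter has a latent value on the unconstrained scale, drawn from
#' a normal with the given group mean and SD, then mapped through the
#' standard normal CDF onto \[0, 1\] (scaled by 5 for `tau`). This is the
#' same transform used by the hierarchical prior, so simulated cohorts live
#' on the support the fit assumes.
#'
#' @param hyper Named list: for each parameter of `model`, a numeric
#'   `c(mean, sd)` on the unconstrained scale. A parameter may instead be
#'   given as `list(uniform = c(lo, hi))` to draw it uniformly on the
#'   constrained scale (used for the recovery cohort's weighting factor).
#' @param n Number of agents (>= 1).
#' @param model Model the parameters are for (default `"M2Out"`).
#' @param seed Optional seed.
#' @return List of `n` [model_params()] objects.
#' @export
sample_cohort_params <- function(hyper, n, model = "M2Out", seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  need <- model_param_names(model)
  miss <- setdiff(need, names(hyper))
  if (length(miss)) {
    stop("hyper lacks entries for: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    draws <- lapply(need, function(p) {
      h <- hyper[[p]]
      if (is.list(h) && !is.null(h$uniform)) {
        runif(n, h$uniform[1], h$uniform[2]) *
          (if (param_kind(p) == "tau") 1 else 1)
      } else {
        constrain(rnorm(n, h[1], h[2]), param_kind(p))
      }
    })
    names(draws) <- need
    lapply(seq_len(n), function(i) {
      do.call(model_params, c(list(model = model),
                              lapply(draws, function(d) d[i])))
    })
  })
}

# default generating distributions for recovery cohorts: the weighting
# factor spans almost the whole unit interval; learning rates and inverse
# temperature sit in the region typical of probabilistic bandit learners
# (median lr ~ 0.31, median tau ~ 3.1)
recovery_hyper <- function() {
  list(wf = list(uniform = c(0.02, 0.98)),
       lr_m = c(-0.5, 0.5),
       lr_s = c(-0.5, 0.5),
       tau = c(0.3, 0.4))
}

#' Simulate one agent's choices on a design
#'
#' Outcome schedules are pre-drawn for both symbols via
#' [generate_design_schedules()]; at each trial the agent chooses by its
#' softmax probability, sees the chosen symbol's outcomes, and updates.
#' Dropout transitions are applied before trial 11 of dropout blocks.
#'
#' @param agent An [agent_spec()].
#' @param design A [design_spec()].
#' @param seed Optional seed (falls back to the agent's own seed).
#' @param randomize_order Shuffle block order (default `TRUE`).
#' @return Trial tibble (columns `block_id`, `condition`, `dropout_type`,
#'   `trial_index`, `phase`, `chosen_symbol`, `out_money`, `out_shock`) with
#'   attributes `true_params` (the generating [model_params()]) and
#'   `final_ev` (per-block end-of-block `EV_M`/`EV_S` per symbol, used by
#'   [simulate_reports()]).
#' @export
simulate_agent <- function(agent, design, seed = NULL, randomize_order = TRUE) {
  stopifnot(inherits(agent, "agent_spec"), inherits(design, "design_spec"))
  seed <- seed %||% agent$seed
  with_seed(seed, {
    sched <- generate_design_schedules(design, seed = NULL,
                                       randomize_order = randomize_order)
    sched <- sched[order(sched$block_id, sched$trial_index, sched$symbol), ]
    blocks <- sched[!duplicated(sched$block_id),
                    c("block_id", "condition", "dropout_type")]
    block_len <- as.integer(table(factor(sched$block_id,
                                         levels = blocks$block_id))) / 2L
    drop_code <- match(blocks$dropout_type,
                       c("None", "MoneyDropout", "ShockDropout")) - 1L
    sim <- cpp_simulate_blocks(model_code(agent$model),
                               params_vector(agent$params),
                               sched$out_money, sched$out_shock,
                               block_len, drop_code)
    per_trial <- sched[sched$symbol == 1L,
                       c("block_id", "condition", "dropout_type",
                         "trial_index", "phase")]
    out <- tibble::as_tibble(per_trial)
    out$chosen_symbol <- as.integer(sim$choice)
    out$out_money <- sim$out_money
    out$out_shock <- sim$out_shock
    attr(out, "true_params") <- agent$params
    attr(out, "final_ev") <- tibble::tibble(
      block_id = blocks$block_id, condition = blocks$condition,
      dropout_type = blocks$dropout_type,
      ev_m_1 = sim$ev_m_final[, 1], ev_m_2 = sim$ev_m_final[, 2],
      ev_s_1 = sim$ev_s_final[, 1], ev_s_2 = sim$ev_s_final[, 2])
    out
  })
}

#' Simulate a full cohort
#'
#' @param params_list List of [model_params()] (one per subject), e.g. from
#'   [sample_cohort_params()].
#' @param design A [design_spec()].
#' @param model Generating model (must match the parameter objects).
#' @param seed Base seed; each subject gets a derived child seed.
#' @param randomize_order Shuffle each subject's block order.
#' @return Cohort tibble (all subjects' trials, `subject_id` first) with
#'   attributes `true_params` (list), `final_ev` (tibble with `subject_id`),
#'   `design`, and `model`.
#' @export
simulate_cohort <- function(params_list, design, model = params_list[[1]]$model,
                            seed = NULL, randomize_order = TRUE) {
  stopifnot(length(params_list) >= 1L)
  bad <- vapply(params_list, function(p) !identical(p$model, model), TRUE)
  if (any(bad)) stop("all parameter objects must belong to model ", model,
                     call. = FALSE)
  subjects <- lapply(seq_along(params_list), function(i) {
    s <- if (is.null(seed)) NULL else child_seed(seed, i)
    dat <- simulate_agent(agent_spec(model, params_list[[i]]), design,
                          seed = s, randomize_order = randomize_order)
    fe <- attr(dat, "final_ev")
    fe <- tibble::add_column(fe, subject_id = i, .before = 1L)
    list(trials = tibble::add_column(dat, subject_id = i, .before = 1L),
         final_ev = fe)
  })
  out <- dplyr::bind_rows(lapply(subjects, `[[`, "trials"))
  attr(out, "true_params") <- params_list
  attr(out, "final_ev") <- dplyr::bind_rows(lapply(subjects, `[[`, "final_ev"))
  attr(out, "design") <- design
  attr(out, "model") <- model
  out
}

#' The default parameter-recovery cohort
#'
#' 79 agents generated from `M2Out` on 8 ConflictDropout blocks (4 money-
#' dropout + 4 shock-dropout), the layout whose first 10 trials per block
#' enter the hierarchical fit. Weighting factors are drawn uniformly on
#' (0.02, 0.98); learning rates and inverse temperature from the documented
#' default generating distributions (see [sample_cohort_params()]).
#'
#' @param n Number of agents (default 79).
#' @param seed Base seed.
#' @return A simulated cohort (see [simulate_cohort()]).
#' @export
simulate_recovery_cohort <- function(n = 79L, seed = NULL) {
  params <- sample_cohort_params(recovery_hyper(), n, model = "M2Out",
                                 seed = if (is.null(seed)) NULL else child_seed(seed, 104729))
  simulate_cohort(params, design_conflict_dropout(), model = "M2Out",
                  seed = seed)
}

#' Simulated explicit probability reports for one block
#'
#' A declared stand-in for human probability reports, used to exercise the
#' report-difference and bias statistics: the reported probability of the
#' high outcome is a linear readout of the block-final expected value on the
#' outcome-value scale, `rpM = 50 + 50 * EV_M` and `rpS = 50 - 50 * EV_S`
#' (the sign flips because high shock is value -1), plus Gaussian noise,
#' clipped to \[0, 100\]. An uninformed agent (all EVs 0) reports 50
#' everywhere, matching the slider's starting position.
#'
#' @param final_ev One row of the `final_ev` attribute of a simulated agent
#'   or cohort (fields `condition`, `ev_m_1`, `ev_m_2`, `ev_s_1`, `ev_s_2`).
#' @param noise_sd Noise SD in percentage points (>= 0).
#' @param seed Optional seed.
#' @return Tibble with columns `rp_m_high`, `rp_m_low`, `rp_s_high`,
#'   `rp_s_low` (reported probabilities, in \[0, 100\], for the symbols
#'   actually associated with high/low money and high/low shock).
#' @export
simulate_reports <- function(final_ev, noise_sd = 10, seed = NULL) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    clip <- function(x) pmin(100, pmax(0, x))
    noise <- function(n) if (noise_sd == 0) rep(0, n) else rnorm(n, 0, noise_sd)
    n <- nrow(final_ev)
    # symbol 1 is always the high-money symbol; the high-shock symbol is 1 in
    # Conflict and 2 in NoConflict
    hs <- ifelse(final_ev$condition == "Conflict", 1L, 2L)
    ev_s <- cbind(final_ev$ev_s_1, final_ev$ev_s_2)
    ev_s_high <- ev_s[cbind(seq_len(n), hs)]
    ev_s_low <- ev_s[cbind(seq_len(n), 3L - hs)]
    tibble::tibble(
      rp_m_high = clip(50 + 50 * final_ev$ev_m_1 + noise(n)),
      rp_m_low  = clip(50 + 50 * final_ev$ev_m_2 + noise(n)),
      rp_s_high = clip(50 - 50 * ev_s_high + noise(n)),
      rp_s_low  = clip(50 - 50 * ev_s_low + noise(n)))
  })
}

#' Simulated reports for every NoDropout block of a cohort
#'
#' @param cohort A cohort from [simulate_cohort()] generated from an M2
#'   family model (separable expectations are required for per-quantity
#'   reports).
#' @param noise_sd Noise SD in percentage points.
#' @param seed Base seed.
#' @return Tibble keyed by `subject_id`, `block_id`, `condition` with the
#'   four report columns of [simulate_reports()].
#' @export
simulate_cohort_reports <- function(cohort, noise_sd = 10, seed = NULL) {
  model <- attr(cohort, "model")
  if (!is.null(model) && !model %in% c("M2Out", "M2Dec", "M2DO")) {
    stop("explicit reports require separable expectations (M2 family)",
         call. = FALSE)
  }
  fe <- attr(cohort, "final_ev")
  if (is.null(fe)) stop("cohort has no final_ev attribute", call. = FALSE)
  fe <- fe[fe$dropout_type == "None", , drop = FALSE]
  rp <- simulate_reports(fe, noise_sd = noise_sd, seed = seed)
  dplyr::bind_cols(fe[, c("subject_id", "block_id", "condition")], rp)
}
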