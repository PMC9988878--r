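# Independent brute-force oracles and shared fixtures.
#
# The oracle below recomputes the sequential choice log-likelihood with
# straight-line code (no shared state machinery with the package) so the
# package's block/state plumbing is checked against a direct transcription
# of the update equations.

oracle_loglik <- function(model, pars, block) {
  # block: data.frame with chosen_symbol, out_money, out_shock, dropout_type
  evm <- c(0, 0); evs <- c(0, 0); ev <- c(0, 0)
  wf <- pars$wf %||% 0.5
  tau <- pars$tau
  alpha <- pars$alpha %||% 1
  wf_eff <- wf
  dropped <- FALSE
  removed <- switch(block$dropout_type[1],
                    MoneyDropout = "money", ShockDropout = "shock", "none")
  out <- numeric(nrow(block))
  for (t in seq_len(nrow(block))) {
    if (removed != "none" && t == 11L) {
      dropped <- TRUE
      wf_eff <- if (removed == "shock") 1 else 0
      if (model %in% c("M2Out", "M2Dec", "M2DO")) {
        if (removed == "money") evm <- c(0, 0) else evs <- c(0, 0)
      }
    }
    v <- switch(model,
      M0 = c(0, 0),
      M1 = ev,
      M2Out = if (dropped) wf_eff * evm + (1 - wf_eff) * evs else evm + evs,
      M2Dec = if (dropped) wf_eff * evm + (1 - wf_eff) * evs
              else wf * evm + (1 - wf) * evs,
      M2DO = if (dropped) wf_eff * evm + (1 - wf_eff) * evs
             else wf^(1 - alpha) * evm + (1 - wf)^(1 - alpha) * evs)
    p <- exp(tau * v) / sum(exp(tau * v))
    c0 <- block$chosen_symbol[t]
    out[t] <- log(p[c0])
    om <- block$out_money[t]; os <- block$out_shock[t]
    if (model == "M1") {
      ev[c0] <- ev[c0] + pars$lr * ((wf_eff * om + (1 - wf_eff) * os) - ev[c0])
    } else if (model %in% c("M2Out", "M2Dec", "M2DO")) {
      mult <- if (model == "M2Dec") c(1, 1)
              else if (dropped) c(wf_eff, 1 - wf_eff)
              else if (model == "M2Out") c(wf, 1 - wf)
              else c(wf^alpha, (1 - wf)^alpha)
      evm[c0] <- evm[c0] + pars$lr_m * (mult[1] * om - evm[c0])
      evs[c0] <- evs[c0] + pars$lr_s * (mult[2] * os - evs[c0])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random but valid single-subject trial table
random_subject_data <- function(n_blocks = 2L, n_trials = 10L,
                                dropout = "None", seed = 1L) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_blocks), function(b) {
    n <- n_trials
    tibble::tibble(
      block_id = b,
      condition = "Conflict",
      dropout_type = dropout,
      trial_index = seq_len(n),
      phase = ifelse(seq_len(n) <= 10L, "learning", "dropout"),
      chosen_symbol = sample(1:2, n, replace = TRUE),
      out_money = sample(c(-1, 1), n, replace = TRUE),
      out_shock = sample(c(-1, 1), n, replace = TRUE))
  }))
}

# quick fit settings for tests that need a converged-enough posterior fast
quick_config <- function(seed = 1L, chains = 2L, warmup = 400L, draws = 400L) {
  fit_config(chains = chains, warmup = warmup, draws = draws, thin = 1L,
             seed = seed)
}

# heavy shared fixtures, computed once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fx_recovery_cohort <- function() {
  fixture("recovery_cohort", simulate_recovery_cohort(n = 79, seed = 11))
}

fx_model_fits <- function() {
  fixture("model_fits", {
    co <- fx_recovery_cohort()
    models <- c("M0", "M1", "M2Out", "M2Dec")
    fits <- suppressWarnings(lapply(seq_along(models), function(k) {
      fit_hierarchical(models[[k]], co, "learning_only",
                       config = quick_config(seed = 100 + k))
    }))
    names(fits) <- models
    fits
  })
}
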