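#' Construct and validate model parameters
#'
#' All models share a softmax inverse temperature `tau` in \[0, 5\]. The
#' learning models add a weighting factor `wf` in \[0, 1\] balancing
#' self-money (wf = 1) against other-shock (wf = 0), and Rescorla-Wagner
#' learning rates: a single `lr` for the combined-history model `M1`,
#' separate `lr_m` / `lr_s` for the separable-outcome `M2` family. `M2DO`
#' adds `alpha` in \[0, 1\] distributing the preference weight between the
#' outcome phase (`alpha` = 1, equals `M2Out`) and the decision phase
#' (`alpha` = 0, equals `M2Dec`).
#'
#' @param model Model name, see [model_names()].
#' @param wf,lr,lr_m,lr_s,tau,alpha Numeric parameter values; irrelevant
#'   fields for the given model may be omitted.
#' @param maintain_wf_at_dropout If `TRUE`, `M2Dec` keeps its preference
#'   weight in the decision rule after an outcome is withdrawn instead of
#'   switching to the unweighted remaining value.
#' @return A `model_params` list.
#' @export
model_params <- function(model, wf = NULL, lr = NULL, lr_m = NULL,
                         lr_s = NULL, tau = NULL, alpha = NULL,
                         maintain_wf_at_dropout = FALSE) {
  code <- model_code(model)
  vals <- list(wf = wf, lr = lr, lr_m = lr_m, lr_s = lr_s, tau = tau,
               alpha = alpha)
  need <- model_param_names(model)
  missing <- need[vapply(vals[need], is.null, TRUE)]
  if (length(missing)) {
    stop("model ", model, " needs parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (p in need) {
    v <- vals[[p]]
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
    hi <- if (param_kind(p) == "tau") 5 else 1
    if (v < 0 || v > hi) {
      stop("parameter ", p, " = ", v, " outside [0, ", hi, "]", call. = FALSE)
    }
  }
  structure(c(vals[need],
              list(model = model, maintain_wf_at_dropout = maintain_wf_at_dropout)),
            class = "model_params")
}

# constrained parameter vector in the canonical order of the C++ backend
params_vector <- function(params) {
  unlist(params[model_param_names(params$model)])
}

#' Initialize a learner's state at the start of a block
#'
#' Expected values start at 0 for every symbol: with outcomes value-coded as
#' +1/-1, zero is the symmetric no-information point. The effective decision
#' weight starts at the model's `wf` and the block is in its conflict
#' (learning) phase.
#'
#' @param model Model name.
#' @param params A [model_params()] object.
#' @return A `model_state` list with fields `ev_m`, `ev_s` (M2 family),
#'   `ev` (M1), `wf_eff`, and `phase`.
#' @export
init_state <- function(model, params = NULL) {
  code <- model_code(model)
  structure(list(model = model,
                 ev = c(0, 0), ev_m = c(0, 0), ev_s = c(0, 0),
                 wf_eff = if (!is.null(params$wf)) params$wf else NA_real_,
                 phase = "conflict"),
            class = "model_state")
}

#' Utility of each symbol under a model
#'
#' The quantity contrasted by the softmax. `M0`: 0 for both symbols. `M1`:
#' the combined expected value. `M2Out`: `EV_M + EV_S` (the weighting already
#' happened at the outcome phase). `M2Dec`: `wf * EV_M + (1 - wf) * EV_S`.
#' `M2DO`: `wf^(1 - alpha) * EV_M + (1 - wf)^(1 - alpha) * EV_S`. After a
#' dropout transition the decision is based on the remaining expected value
#' alone (see [apply_dropout()]).
#'
#' @param model Model name.
#' @param state A `model_state`.
#' @param params A [model_params()].
#' @param symbol Optional symbol index (1 or 2); default returns both.
#' @return Scalar utility, or length-2 vector when `symbol` is `NULL`.
#' @export
decision_value <- function(model, state, params, symbol = NULL) {
  code <- model_code(model)
  v <- if (code == 0L) {
    c(0, 0)
  } else if (code == 1L) {
    state$ev
  } else {
    w <- decision_weights(code, state, params)
    w[1] * state$ev_m + w[2] * state$ev_s
  }
  if (is.null(symbol)) v else v[[symbol]]
}

# money/shock weights entering the decision rule for the M2 family
decision_weights <- function(code, state, params) {
  if (state$phase != "conflict") {
    # one outcome is withdrawn: decide on the remaining EV, unweighted
    # (wf_eff = 1 when shocks removed, 0 when money removed); optionally
    # M2Dec keeps its wf (maintain_wf_at_dropout variant)
    if (code == 3L && isTRUE(params$maintain_wf_at_dropout)) {
      return(c(params$wf, 1 - params$wf))
    }
    return(c(state$wf_eff, 1 - state$wf_eff))
  }
  switch(as.character(code),
    "2" = c(1, 1),
    "3" = c(params$wf, 1 - params$wf),
    "4" = c(params$wf^(1 - params$alpha), (1 - params$wf)^(1 - params$alpha)))
}

#' Softmax choice probabilities over the two symbols
#'
#' `p(a) = exp(tau * V_a) / sum_b exp(tau * V_b)`, computed with
#' max-subtraction for numerical stability.
#'
#' @inheritParams decision_value
#' @return Length-2 probability vector summing to 1.
#' @export
choice_prob <- function(model, state, params) {
  tau <- params$tau
  if (is.null(tau) || !is.finite(tau) || tau < 0 || tau > 5) {
    stop("tau must lie in [0, 5]", call. = FALSE)
  }
  v <- tau * decision_value(model, state, params)
  e <- exp(v - max(v))
  e / sum(e)
}

#' Rescorla-Wagner update after an outcome
#'
#' Only the chosen symbol is updated; the other symbol's expectations carry
#' over unchanged. Per model (for the chosen symbol):
#' \describe{
#'   \item{M0}{no update.}
#'   \item{M1}{`PE = (wf*Out_M + (1-wf)*Out_S) - EV`; `EV <- EV + lr*PE`.}
#'   \item{M2Out}{`PE_M = wf*Out_M - EV_M`; `PE_S = (1-wf)*Out_S - EV_S`;
#'     each EV moves by its learning rate times its PE.}
#'   \item{M2Dec}{`PE_M = Out_M - EV_M`, `PE_S = Out_S - EV_S`; same update.}
#'   \item{M2DO}{outcome multipliers `wf^alpha` and `(1-wf)^alpha` replace
#'     `wf` and `1-wf` in the M2Out prediction errors.}
#' }
#' During a dropout phase the effective weight (1 or 0) replaces `wf` so all
#' learning capacity goes to the remaining outcome; the withheld outcome is
#' 0 and its expectation stays at 0.
#'
#' @inheritParams decision_value
#' @param chosen_symbol Chosen symbol index (1 or 2).
#' @param out_m,out_s Value-coded outcomes in \{+1, -1, 0\}.
#' @return List with elements `state` (updated), `pe_m`, `pe_s` (combined PE
#'   in `pe_m` for M1), and `choice_prob` (probabilities at the decision that
#'   preceded this outcome).
#' @export
update_state <- function(model, state, chosen_symbol, out_m, out_s, params) {
  code <- model_code(model)
  if (!chosen_symbol %in% c(1L, 2L)) stop("chosen_symbol must be 1 or 2", call. = FALSE)
  if (!out_m %in% c(-1, 0, 1) || !out_s %in% c(-1, 0, 1)) {
    stop("outcome values must be in {+1, -1, 0}", call. = FALSE)
  }
  p <- choice_prob(model, state, params)
  i <- chosen_symbol
  pe_m <- pe_s <- 0
  wf_use <- if (state$phase == "conflict") params$wf else state$wf_eff
  if (code == 1L) {
    pe_m <- (wf_use * out_m + (1 - wf_use) * out_s) - state$ev[i]
    state$ev[i] <- state$ev[i] + params$lr * pe_m
  } else if (code %in% c(2L, 3L, 4L)) {
    mult <- switch(as.character(code),
      "2" = c(wf_use, 1 - wf_use),
      "3" = c(1, 1),
      "4" = if (state$phase == "conflict") {
        c(params$wf^params$alpha, (1 - params$wf)^params$alpha)
      } else c(state$wf_eff, 1 - state$wf_eff))
    pe_m <- mult[1] * out_m - state$ev_m[i]
    pe_s <- mult[2] * out_s - state$ev_s[i]
    state$ev_m[i] <- state$ev_m[i] + params$lr_m * pe_m
    state$ev_s[i] <- state$ev_s[i] + params$lr_s * pe_s
  }
  list(state = state, pe_m = pe_m, pe_s = pe_s, choice_prob = p)
}

#' Devaluation (dropout) transition before the 11th trial
#'
#' Implements what an informed learner does when told one outcome will no
#' longer be delivered. For the M2 family the expectation of the removed
#' quantity is set to 0 for both symbols and the effective decision weight
#' becomes 1 (shocks removed) or 0 (money removed), so the next decision is
#' based on the remaining expected value alone. M1 has no separable
#' representation, so its combined expectation must remain unchanged; only
#' the effective weight used for subsequent outcome combination changes.
#'
#' @inheritParams decision_value
#' @param removed `"money"` or `"shock"`.
#' @return The transitioned `model_state`.
#' @export
apply_dropout <- function(model, state, params, removed = c("money", "shock")) {
  removed <- match.arg(removed)
  code <- model_code(model)
  if (state$phase != "conflict") {
    stop("dropout transition already applied to this state", call. = FALSE)
  }
  if (code %in% c(2L, 3L, 4L)) {
    if (removed == "money") state$ev_m <- c(0, 0) else state$ev_s <- c(0, 0)
  }
  state$wf_eff <- if (removed == "shock") 1 else 0
  state$phase <- paste0("dropout-", removed)
  state
}

# ---- sequential evaluation over a subject's trials --------------------------

# split a subject's trial table into blocks (validated, ordered)
split_blocks <- function(subject_data) {
  req <- c("block_id", "trial_index", "chosen_symbol", "out_money", "out_shock")
  miss <- setdiff(req, names(subject_data))
  if (length(miss)) {
    stop("subject data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  blocks <- split(subject_data, factor(subject_data$block_id,
                                       levels = unique(subject_data$block_id)))
  for (b in blocks) {
    if (!identical(as.integer(b$trial_index), seq_len(nrow(b)))) {
      stop("trial indices must be contiguous from 1 within block ",
           b$block_id[1], call. = FALSE)
    }
  }
  blocks
}

block_removed <- function(block) {
  d <- block$dropout_type[1] %||% "None"
  switch(d, MoneyDropout = "money", ShockDropout = "shock", NULL)
}

#' Pointwise log-likelihood of a subject's choices
#'
#' Walks each block in order, resetting the learner's state at the block
#' start, applying the dropout transition before trial 11 of dropout blocks,
#' and accumulating the log probability of each observed choice prior to the
#' outcome update.
#'
#' @param model Model name.
#' @param params A [model_params()].
#' @param subject_data Tibble of one subject's trials with columns
#'   `block_id`, `dropout_type`, `trial_index`, `chosen_symbol`,
#'   `out_money`, `out_shock` (ordered; trial indices contiguous from 1
#'   within each block).
#' @param trials Which trials contribute: `"learning"` (trial_index <= 10),
#'   `"trial11"` (the first post-dropout decision only), or `"all"`.
#' @return Numeric vector of per-trial log choice probabilities, in trial
#'   order, for the included trials.
#' @export
loglik_subject <- function(model, params, subject_data,
                           trials = c("learning", "trial11", "all")) {
  trials <- match.arg(trials)
  blocks <- split_blocks(subject_data)
  out <- numeric(0)
  for (b in blocks) {
    state <- init_state(model, params)
    removed <- block_removed(b)
    for (t in seq_len(nrow(b))) {
      if (!is.null(removed) && b$trial_index[t] == 11L) {
        state <- apply_dropout(model, state, params, removed)
      }
      p <- choice_prob(model, state, params)
      keep <- switch(trials,
        learning = b$trial_index[t] <= 10L,
        trial11 = b$trial_index[t] == 11L,
        all = TRUE)
      if (keep) out <- c(out, log(p[[b$chosen_symbol[t]]]))
      state <- update_state(model, state, b$chosen_symbol[t],
                            b$out_money[t], b$out_shock[t], params)$state
    }
  }
  out
}

#' Latent trajectories and wf-normalized regressors
#'
#' Runs the separable-outcome model `M2Out` over a subject's trials and
#' returns, per trial, the chosen option's expected values at decision time
#' and the prediction errors at outcome time, together with wf-normalized
#' versions: `PE_M / wf`, `PE_S / (1 - wf)` (and likewise for EVs). The
#' normalization puts every subject's learning signal on the outcome scale
#' regardless of their preference weight — e.g. the first shock prediction
#' error of a block is exactly -1 after a high-shock outcome and +1 after a
#' low-shock outcome. With `center = TRUE` each modulator is additionally
#' mean-subtracted across the subject's trials, the usual convention before
#' entering a GLM design matrix.
#'
#' @param params A [model_params()] for `M2Out` with `wf` strictly inside
#'   (0, 1).
#' @param subject_data Trial table as in [loglik_subject()].
#' @param center Mean-subtract each modulator across trials (default `TRUE`).
#' @return Tibble with columns `block_id`, `trial_index`, `ev_m`, `ev_s`,
#'   `pe_m`, `pe_s`, `ev_m_norm`, `ev_s_norm`, `pe_m_norm`, `pe_s_norm`
#'   (plus `subject_id` when present in the input).
#' @export
extract_regressors <- function(params, subject_data, center = TRUE) {
  if (params$model != "M2Out") {
    stop("regressors are defined for the winning separable-outcome model M2Out",
         call. = FALSE)
  }
  wf <- params$wf
  if (wf <= 0 || wf >= 1) {
    stop("wf-normalization is undefined for wf in {0, 1}", call. = FALSE)
  }
  blocks <- split_blocks(subject_data)
  rows <- lapply(blocks, function(b) {
    state <- init_state("M2Out", params)
    removed <- block_removed(b)
    res <- vector("list", nrow(b))
    for (t in seq_len(nrow(b))) {
      if (!is.null(removed) && b$trial_index[t] == 11L) {
        state <- apply_dropout("M2Out", state, params, removed)
      }
      i <- b$chosen_symbol[t]
      ev_m <- state$ev_m[i]; ev_s <- state$ev_s[i]
      st <- update_state("M2Out", state, i, b$out_money[t], b$out_shock[t], params)
      state <- st$state
      res[[t]] <- tibble::tibble(block_id = b$block_id[t],
                                 trial_index = b$trial_index[t],
                                 ev_m = ev_m, ev_s = ev_s,
                                 pe_m = st$pe_m, pe_s = st$pe_s)
    }
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(rows)
  out$ev_m_norm <- out$ev_m / wf
  out$ev_s_norm <- out$ev_s / (1 - wf)
  out$pe_m_norm <- out$pe_m / wf
  out$pe_s_norm <- out$pe_s / (1 - wf)
  if (center) {
    for (col in c("ev_m_norm", "ev_s_norm", "pe_m_norm", "pe_s_norm")) {
      out[[col]] <- out[[col]] - mean(out[[col]])
    }
  }
  if ("subject_id" %in% names(subject_data)) {
    out <- tibble::add_column(out, subject_id = subject_data$subject_id[1],
                              .before = 1L)
  }
  out
}
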