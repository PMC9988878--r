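#' Map an unconstrained value onto a parameter's support
#'
#' The probit-style transform used throughout the hierarchy: `Phi(u)` for
#' unit-interval parameters and `5 * Phi(u)` for the inverse temperature.
#' Strictly increasing and bijective onto the open interval.
#'
#' @param u Unconstrained numeric vector.
#' @param kind `"unit"` or `"tau"`.
#' @return Constrained values.
#' @export
constrain <- function(u, kind = c("unit", "tau")) {
  kind <- match.arg(kind)
  v <- pnorm(u)
  if (kind == "tau") 5 * v else v
}

#' Settings for a hierarchical fit
#'
#' Defaults retain 4,000 post-warmup draws (4 chains of 1,000), the draw
#' count used for all draw-wise comparison statistics.
#'
#' @param chains Number of chains (>= 1).
#' @param warmup Warmup iterations per chain (discarded; used for proposal
#'   adaptation).
#' @param draws Post-warmup draws per chain.
#' @param seed Integer seed; each chain derives its own child seed.
#' @param thin Keep every `thin`-th post-warmup iteration (the retained
#'   draw count stays `draws`; thinning trades compute for lower
#'   autocorrelation).
#' @param sigma_prior_scale Scale of the half-Normal prior on group scales
#'   (unconstrained space).
#' @return A `fit_config` list.
#' @export
fit_config <- function(chains = 4L, warmup = 1000L, draws = 1000L,
                       seed = 1L, thin = 2L, sigma_prior_scale = 0.2) {
  stopifnot(chains >= 1L, warmup >= 0L, draws >= 1L, thin >= 1L,
            sigma_prior_scale > 0)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 thin = as.integer(thin), sigma_prior_scale = sigma_prior_scale),
            class = "fit_config")
}

# ---- cohort flattening for the C++ backend ---------------------------------

# order trials subject/block/trial and produce the flat arrays the C++
# routines consume; `blocks` and `trials_subset` select what is fitted
flatten_cohort <- function(cohort, blocks = c("dropout", "all"),
                           conditions = c("Conflict", "NoConflict"),
                           max_trial = NULL) {
  blocks <- match.arg(blocks)
  cohort <- cohort[cohort$condition %in% conditions, , drop = FALSE]
  if (!nrow(cohort)) stop("no trials left for conditions: ",
                          paste(conditions, collapse = ", "), call. = FALSE)
  req <- c("subject_id", "block_id", "dropout_type", "trial_index",
           "chosen_symbol", "out_money", "out_shock")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (blocks == "dropout") {
    cohort <- cohort[cohort$dropout_type != "None", , drop = FALSE]
    if (!nrow(cohort)) stop("cohort contains no dropout blocks", call. = FALSE)
  }
  if (!is.null(max_trial)) {
    cohort <- cohort[cohort$trial_index <= max_trial, , drop = FALSE]
  }
  cohort <- cohort[order(match(cohort$subject_id, unique(cohort$subject_id)),
                         cohort$block_id, cohort$trial_index), , drop = FALSE]
  subj <- unique(cohort$subject_id)
  key <- paste(cohort$subject_id, cohort$block_id)
  block_f <- factor(key, levels = unique(key))
  lens <- as.integer(table(block_f))
  first <- !duplicated(block_f)
  # validate contiguity within each block
  expect <- sequence(lens)
  if (!identical(as.integer(cohort$trial_index), expect)) {
    stop("trial indices must be contiguous from 1 within each block",
         call. = FALSE)
  }
  drop_code <- match(cohort$dropout_type[first],
                     c("None", "MoneyDropout", "ShockDropout")) - 1L
  blocks_per_subj <- as.integer(table(factor(cohort$subject_id[first],
                                             levels = subj)))
  list(choice = as.integer(cohort$chosen_symbol),
       outm = as.numeric(cohort$out_money),
       outs = as.numeric(cohort$out_shock),
       block_ptr = c(0L, cumsum(lens)),
       block_drop = drop_code,
       subj_block_ptr = c(0L, cumsum(blocks_per_subj)),
       subject_ids = subj,
       trial_table = cohort)
}

subset_code <- function(trials_subset) {
  switch(trials_subset, learning_only = 1L, learning = 1L, trial11 = 2L,
         all = 3L, stop("unknown trials subset: ", trials_subset, call. = FALSE))
}

# ---- convergence diagnostics ------------------------------------------------

# split-Rhat over a draws x chains matrix
split_rhat <- function(x) {
  n <- nrow(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from lag-autocorrelations (Geyer truncation)
ess_basic <- function(x) {
  x <- as.vector(x)
  n <- length(x)
  if (var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(ac) - 1) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Hierarchical Bayesian fit of a learning model to a cohort
#'
#' Non-centered hierarchy with the probit-style constraint transform: for
#' each parameter, group location ~ Normal(0, 1), group scale ~
#' half-Normal(0, `sigma_prior_scale`), subject offsets ~ Normal(0, 1), and
#' subject parameter = [constrain()] (location + scale * offset). Sampling
#' is by adaptive Metropolis-within-Gibbs (subject offsets coordinate-wise,
#' then group location and scale per parameter), with proposal scales
#' adapted during warmup only.
#'
#' @param model Model name.
#' @param cohort Trial tibble (see [read_trials()] / [simulate_cohort()]).
#' @param trials_subset `"learning_only"` fits trials 1-10 of the dropout
#'   blocks (the design used for model arbitration); `"all"` fits every
#'   trial of every block.
#' @param config A [fit_config()].
#' @param blocks Which blocks enter the fit: `"dropout"` (default for
#'   `learning_only`) or `"all"` (e.g. for designs with no dropout blocks).
#' @param conditions Conditions fitted together; defaults to Conflict
#'   blocks only, since Conflict and NoConflict contingencies are always
#'   fitted separately.
#' @return An `rl_posterior` list: `theta` (draws x subjects x parameters,
#'   constrained), `mu`, `sigma` (draws x parameters, unconstrained
#'   hyperparameters), `diagnostics` (split-Rhat / ESS per hyperparameter,
#'   with a `converged` flag and a warning when any Rhat > 1.05), the
#'   flattened data, and metadata. Pointwise log-likelihoods are computed on
#'   demand by [loglik_matrix()].
#' @export
fit_hierarchical <- function(model, cohort,
                             trials_subset = c("learning_only", "all"),
                             config = fit_config(),
                             blocks = NULL, conditions = "Conflict") {
  trials_subset <- match.arg(trials_subset)
  code <- model_code(model)
  blocks <- blocks %||% (if (trials_subset == "learning_only") "dropout" else "all")
  flat <- flatten_cohort(cohort, blocks = blocks, conditions = conditions,
                         max_trial = if (trials_subset == "learning_only") 10L else NULL)
  n_subj <- length(flat$subject_ids)
  pn <- model_param_names(model)
  P <- length(pn)

  chains <- lapply(seq_len(config$chains), function(ch) {
    with_seed(child_seed(config$seed, ch), {
      cpp_mcmc_chain(code, flat$choice, flat$outm, flat$outs, flat$block_ptr,
                     flat$block_drop, flat$subj_block_ptr,
                     config$warmup, config$draws, config$thin %||% 1L,
                     config$sigma_prior_scale,
                     3L) # flattened data already restricted to fitted trials
    })
  })

  mu <- do.call(rbind, lapply(chains, `[[`, "mu"))
  sigma <- do.call(rbind, lapply(chains, `[[`, "sigma"))
  colnames(mu) <- colnames(sigma) <- pn
  theta <- array(NA_real_, dim = c(config$chains * config$draws, n_subj, P),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(chains)) {
    rows <- (ch - 1L) * config$draws + seq_len(config$draws)
    theta[rows, , ] <- chains[[ch]]$theta
  }

  diag_tbl <- dplyr::bind_rows(lapply(seq_len(P), function(p) {
    mu_mat <- sapply(chains, function(c) c$mu[, p])
    sig_mat <- sapply(chains, function(c) c$sigma[, p])
    tibble::tibble(parameter = pn[p],
                   rhat_mu = if (config$chains > 1L || config$draws >= 4L)
                     split_rhat(as.matrix(mu_mat)) else NA_real_,
                   rhat_sigma = split_rhat(as.matrix(sig_mat)),
                   ess_mu = ess_basic(mu_mat),
                   ess_sigma = ess_basic(sig_mat))
  }))
  rh <- c(diag_tbl$rhat_mu, diag_tbl$rhat_sigma)
  converged <- all(is.na(rh) | rh < 1.05)
  if (!converged) {
    warning("fit may not have converged: max split-Rhat = ",
            round(max(rh, na.rm = TRUE), 3), call. = FALSE)
  }

  structure(list(model = model, theta = theta, mu = mu, sigma = sigma,
                 subject_ids = flat$subject_ids,
                 diagnostics = list(table = diag_tbl, converged = converged),
                 trials_subset = trials_subset, blocks = blocks,
                 conditions = conditions,
                 data = flat, config = config),
            class = "rl_posterior")
}

#' Pointwise log-likelihood matrix for a fitted posterior
#'
#' @param posterior An `rl_posterior`.
#' @param cohort Optional trial tibble to evaluate on (defaults to the
#'   fitted trials). Required for held-out trial-11 evaluation, where the
#'   cohort must contain the full dropout blocks.
#' @param trials `"learning"`, `"trial11"`, or `"all"`.
#' @param thin Keep every `thin`-th draw (default 1 = all draws).
#' @return Matrix of log choice probabilities, draws x trials.
#' @export
loglik_matrix <- function(posterior, cohort = NULL,
                          trials = c("learning", "trial11", "all"), thin = 1L) {
  trials <- match.arg(trials)
  stopifnot(inherits(posterior, "rl_posterior"))
  flat <- if (is.null(cohort)) posterior$data else
    flatten_cohort(cohort, blocks = posterior$blocks,
                   conditions = posterior$conditions %||%
                     c("Conflict", "NoConflict"))
  keep <- seq(1L, dim(posterior$theta)[1], by = as.integer(thin))
  theta <- posterior$theta[keep, , , drop = FALSE]
  perm <- match(flat$subject_ids, posterior$subject_ids)
  if (anyNA(perm) || length(flat$subject_ids) != length(posterior$subject_ids)) {
    stop("cohort subjects do not match the fitted subjects", call. = FALSE)
  }
  theta <- theta[, perm, , drop = FALSE]
  cpp_loglik_matrix(model_code(posterior$model), as.numeric(theta),
                    length(keep), length(flat$subject_ids), flat$choice,
                    flat$outm, flat$outs, flat$block_ptr, flat$block_drop,
                    flat$subj_block_ptr, subset_code(trials))
}

#' Posterior-mean point estimates per subject
#'
#' @param posterior An `rl_posterior`.
#' @return Tibble with `subject_id` and one column per model parameter
#'   (posterior means on the constrained scale).
#' @export
point_estimates <- function(posterior) {
  stopifnot(inherits(posterior, "rl_posterior"))
  if (dim(posterior$theta)[1] < 1L) stop("empty posterior", call. = FALSE)
  est <- apply(posterior$theta, c(2, 3), mean)
  out <- tibble::as_tibble(as.data.frame(est))
  names(out) <- dimnames(posterior$theta)[[3]]
  tibble::add_column(out, subject_id = posterior$subject_ids, .before = 1L)
}

#' Export posterior draws as a long table
#'
#' @param posterior An `rl_posterior`.
#' @return Tibble with columns `chain`, `draw`, `parameter`, `subject_id`,
#'   `value` (subject-level constrained draws) plus hyperparameter rows with
#'   `subject_id = NA`.
#' @export
posterior_draws <- function(posterior) {
  stopifnot(inherits(posterior, "rl_posterior"))
  cfg <- posterior$config
  S <- dim(posterior$theta)[1]
  chain <- rep(seq_len(cfg$chains), each = cfg$draws)[seq_len(S)]
  draw <- rep(seq_len(cfg$draws), times = cfg$chains)[seq_len(S)]
  pn <- dimnames(posterior$theta)[[3]]
  subj <- dplyr::bind_rows(lapply(seq_along(pn), function(p) {
    dplyr::bind_rows(lapply(seq_along(posterior$subject_ids), function(i) {
      tibble::tibble(chain = chain, draw = draw, parameter = pn[p],
                     subject_id = posterior$subject_ids[i],
                     value = posterior$theta[, i, p])
    }))
  }))
  hyper <- dplyr::bind_rows(lapply(seq_along(pn), function(p) {
    tibble::tibble(chain = rep(chain, 2), draw = rep(draw, 2),
                   parameter = paste0(rep(c("mu_", "sigma_"), each = S), pn[p]),
                   subject_id = NA, value = c(posterior$mu[, p],
                                              posterior$sigma[, p]))
  }))
  dplyr::bind_rows(subj, hyper)
}
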