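# ---- Pareto-smoothed importance sampling -----------------------------------

# Zhang & Stephens (2009) posterior-mean fit of a generalized Pareto
# distribution to exceedances x (ascending), with the mild prior
# regularization toward k = 0.5 customary in PSIS diagnostics
gpd_fit <- function(x) {
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  # profile likelihood in the Zhang-Stephens parameterization (their shape
  # is the negative of the usual GPD xi)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  ll <- n * (log(bs / ks) + ks - 1)
  ll[!is.finite(ll)] <- -Inf
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  b <- sum(bs * w)
  k_zs <- -mean(log1p(-b * x))
  sigma <- k_zs / b
  k <- -k_zs # usual tail-index convention: positive = heavy tail
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

# GPD quantile function (shape k, scale sigma, location 0)
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of log importance ratios; returns normalized log
# weights and the Pareto-k diagnostic
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k <- 0
  if (M >= 5 && stats::sd(lr) > 0) {
    ord <- order(lr)
    tail_ids <- ord[(S - M + 1L):S]
    cutoff <- exp(lr[ord[S - M]])
    exc <- sort(exp(lr[tail_ids]) - cutoff)
    if (exc[length(exc)] > 0) {
      exc <- pmax(exc, .Machine$double.eps)
      fit <- gpd_fit(exc)
      k <- fit$k
      p <- (seq_len(M) - 0.5) / M
      sm <- log(gpd_quantile(p, fit$k, fit$sigma) + cutoff)
      lr[tail_ids[order(lr[tail_ids])]] <- pmin(sm, 0)
    }
  }
  list(log_weights = lr - logsumexp(lr), k = k)
}

#' LOOIC by Pareto-smoothed importance-sampling leave-one-out
#'
#' Computes the expected log pointwise predictive density (elpd) of each
#' datapoint under leave-one-out cross-validation, approximated by
#' importance sampling from the full posterior with Pareto-smoothed weights,
#' then `LOOIC = -2 * sum(elpd)` with
#' `SE = 2 * sqrt(N * var(pointwise elpd))`. Lower LOOIC means better
#' expected out-of-sample prediction.
#'
#' @param loglik Matrix of pointwise log-likelihoods, posterior draws in
#'   rows, datapoints in columns (e.g. from [loglik_matrix()]).
#' @return List with `looic`, `se`, `elpd`, `pointwise` (tibble of per-point
#'   `elpd` and Pareto `k`), and `n_high_k` (points with k > 0.7, which also
#'   triggers a warning).
#' @export
compute_looic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (!nrow(loglik) || !ncol(loglik)) stop("empty log-likelihood matrix",
                                           call. = FALSE)
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries",
                                    call. = FALSE)
  pw <- lapply(seq_len(ncol(loglik)), function(i) {
    ll <- loglik[, i]
    ps <- psis_smooth(-ll)
    c(elpd = logsumexp(ps$log_weights + ll), k = ps$k)
  })
  pw <- do.call(rbind, pw)
  elpd_i <- pw[, "elpd"]
  n <- length(elpd_i)
  n_high <- sum(pw[, "k"] > 0.7)
  if (n_high > 0) {
    warning(n_high, " of ", n, " Pareto-k diagnostics exceed 0.7; ",
            "PSIS-LOO may be unreliable for those points", call. = FALSE)
  }
  list(looic = -2 * sum(elpd_i),
       se = if (n > 1L) 2 * sqrt(n * var(elpd_i)) else 0,
       elpd = sum(elpd_i),
       pointwise = tibble::tibble(elpd = elpd_i, k = pw[, "k"]),
       n_high_k = n_high)
}

#' Draw-wise information criterion of the held-out 11th trials
#'
#' For each posterior draw, sums the log probability of every subject's
#' first post-devaluation choice (trial 11 of each dropout block, with the
#' dropout transition applied) and multiplies by -2 to place the value on
#' the information-criterion scale. Trial 11 is never part of the fit, so no
#' cross-validation correction is needed; the full draw-wise distribution is
#' returned so non-overlap between models can be checked directly.
#'
#' @param posterior An `rl_posterior` fitted with
#'   `trials_subset = "learning_only"` (fitting that included trial 11 is an
#'   information leak and raises an error).
#' @param cohort Trial tibble containing the complete dropout blocks.
#' @return Numeric vector, one IC value per posterior draw.
#' @export
trial11_ic_distribution <- function(posterior, cohort) {
  stopifnot(inherits(posterior, "rl_posterior"))
  if (posterior$trials_subset != "learning_only") {
    stop("posterior was fitted on all trials; held-out evaluation of trial 11 ",
         "requires a fit restricted to the learning trials", call. = FALSE)
  }
  if (!any(cohort$dropout_type != "None" & cohort$trial_index == 11L)) {
    stop("cohort contains no 11th trials of dropout blocks", call. = FALSE)
  }
  ll <- loglik_matrix(posterior, cohort, trials = "trial11")
  -2 * rowSums(ll)
}

#' Per-subject likelihood ratio on the held-out 11th trials
#'
#' For each subject, sums the trial-11 log-likelihoods over blocks, averages
#' across posterior draws, and forms `exp(mean_A) / exp(mean_B)`: values
#' above 1 favor the first model for that subject.
#'
#' @param posterior_a,posterior_b Two `rl_posterior` objects fitted on the
#'   same subjects' learning trials.
#' @param cohort Trial tibble with the complete dropout blocks.
#' @param subject Optional single subject id; default returns all subjects.
#' @return Tibble with `subject_id`, `mean_loglik_a`, `mean_loglik_b`,
#'   `ratio` — or a single ratio when `subject` is given.
#' @export
subject_likelihood_ratio <- function(posterior_a, posterior_b, cohort,
                                     subject = NULL) {
  stopifnot(inherits(posterior_a, "rl_posterior"),
            inherits(posterior_b, "rl_posterior"))
  if (length(posterior_a$subject_ids) != length(posterior_b$subject_ids) ||
      !all(posterior_a$subject_ids == posterior_b$subject_ids)) {
    stop("the two posteriors were fitted on different subjects", call. = FALSE)
  }
  mean_subject_ll <- function(posterior) {
    ll <- loglik_matrix(posterior, cohort, trials = "trial11")
    flat <- flatten_cohort(cohort, blocks = posterior$blocks,
                           conditions = posterior$conditions %||%
                             c("Conflict", "NoConflict"))
    # column order is subject-major; count trial-11 columns per subject
    n11 <- vapply(seq_along(flat$subject_ids), function(i) {
      b <- (flat$subj_block_ptr[i] + 1L):flat$subj_block_ptr[i + 1L]
      sum(flat$block_drop[b] != 0L &
            (flat$block_ptr[b + 1L] - flat$block_ptr[b]) >= 11L)
    }, integer(1))
    split_idx <- rep(seq_along(n11), n11)
    ml <- vapply(seq_along(n11), function(i) {
      mean(rowSums(ll[, split_idx == i, drop = FALSE]))
    }, numeric(1))
    names(ml) <- flat$subject_ids
    ml
  }
  a <- mean_subject_ll(posterior_a)
  b <- mean_subject_ll(posterior_b)
  b <- b[names(a)]
  out <- tibble::tibble(subject_id = names(a),
                        mean_loglik_a = unname(a), mean_loglik_b = unname(b),
                        ratio = exp(unname(a) - unname(b)))
  if (!is.null(subject)) {
    row <- out[out$subject_id == subject, ]
    if (!nrow(row)) stop("unknown subject: ", subject, call. = FALSE)
    return(row$ratio)
  }
  out
}

#' Compare fitted models on a cohort
#'
#' Convenience wrapper producing the package's comparison report: PSIS-LOO
#' on the fitted learning trials and the draw-wise trial-11 IC distribution
#' per model.
#'
#' @param fits Named list of `rl_posterior` objects (same cohort, same
#'   subjects).
#' @param cohort Trial tibble with complete dropout blocks.
#' @param thin Thinning applied to the LOOIC log-likelihood matrices.
#' @return List with `looic` (tibble: model, looic, se, n_high_k) and
#'   `trial11_ic` (tibble: model, draw, ic).
#' @export
compare_models <- function(fits, cohort, thin = 1L) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  looic <- dplyr::bind_rows(lapply(names(fits), function(m) {
    lo <- compute_looic(loglik_matrix(fits[[m]], trials = "all", thin = thin))
    tibble::tibble(model = m, looic = lo$looic, se = lo$se,
                   n_high_k = lo$n_high_k)
  }))
  t11 <- dplyr::bind_rows(lapply(names(fits), function(m) {
    ic <- trial11_ic_distribution(fits[[m]], cohort)
    tibble::tibble(model = m, draw = seq_along(ic), ic = ic)
  }))
  list(looic = looic, trial11_ic = t11)
}
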