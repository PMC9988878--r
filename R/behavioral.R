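#' Two-sided binomial classification bounds
#'
#' For `n` choices under chance (p = 0.5), `upper` is the smallest count
#' whose cumulative binomial probability reaches `1 - alpha/2` and `lower`
#' the smallest count whose cumulative probability exceeds `alpha/2`.
#' Preference labels use strict inequalities against these bounds, so for
#' 120 trials the bounds (49, 71) mean more than 71 considerate choices is a
#' considerate preference and fewer than 49 a lucrative one.
#'
#' @param n Trial count (>= 1).
#' @param alpha Two-sided level in (0, 1), default 0.05.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
binomial_bounds <- function(n, alpha = 0.05) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  counts <- 0:n
  cdf <- pbinom(counts, n, 0.5)
  upper <- counts[match(TRUE, cdf >= 1 - alpha / 2)]
  lower <- counts[match(TRUE, cdf > alpha / 2)]
  c(lower = lower, upper = upper)
}

#' Classify a choice preference against chance
#'
#' @param count Number of considerate choices.
#' @param n Number of trials.
#' @param alpha Two-sided binomial level.
#' @return A `preference_label` list: `label` (`"Considerate"`,
#'   `"Lucrative"`, or `"Ambiguous"`), `count`, `n`, and the `bounds` used.
#' @export
classify_preference <- function(count, n, alpha = 0.05) {
  stopifnot(is.numeric(count), length(count) == 1L)
  if (count < 0 || count > n) {
    stop("count must lie in [0, n]", call. = FALSE)
  }
  b <- binomial_bounds(n, alpha)
  label <- if (count > b[["upper"]]) "Considerate"
           else if (count < b[["lower"]]) "Lucrative"
           else "Ambiguous"
  structure(list(label = label, count = count, n = n, bounds = b),
            class = "preference_label")
}

#' Classify every subject of a cohort
#'
#' Counts considerate choices over the first 10 trials of all Conflict
#' blocks (the design-linked default: 120 trials for the online layout with
#' 12 Conflict blocks, 60 for the imaging layout with 6).
#'
#' @param cohort Trial tibble.
#' @param alpha Two-sided binomial level.
#' @return Tibble with `subject_id`, `count`, `n`, `prop_considerate`,
#'   `label`.
#' @export
classify_cohort <- function(cohort, alpha = 0.05) {
  dat <- cohort[cohort$condition == "Conflict" & cohort$trial_index <= 10L, ]
  if (!nrow(dat)) stop("cohort has no Conflict learning trials", call. = FALSE)
  cons <- considerate_symbol("Conflict")
  dplyr::bind_rows(lapply(split(dat, factor(dat$subject_id,
                                            levels = unique(dat$subject_id))),
    function(d) {
      k <- sum(d$chosen_symbol == cons)
      n <- nrow(d)
      tibble::tibble(subject_id = d$subject_id[1], count = k, n = n,
                     prop_considerate = k / n,
                     label = classify_preference(k, n, alpha)$label)
    }))
}

check_reports <- function(report) {
  cols <- c("rp_m_high", "rp_m_low", "rp_s_high", "rp_s_low")
  miss <- setdiff(cols, names(report))
  if (length(miss)) stop("report lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  vals <- unlist(report[cols])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    stop("reported probabilities must lie in [0, 100]", call. = FALSE)
  }
  invisible(report)
}

#' Difference of reported probabilities for one outcome quantity
#'
#' Signed so that perfect learning of the programmed 80/20 contingencies
#' yields +60 percentage points: for shocks, reported probability of high
#' shock for the actually-high-shock symbol minus that for the low-shock
#' symbol; analogously for money.
#'
#' @param report Tibble/row with columns `rp_m_high`, `rp_m_low`,
#'   `rp_s_high`, `rp_s_low` (see [simulate_reports()]).
#' @param quantity `"shock"` or `"money"`.
#' @return Difference(s) in percentage points.
#' @export
report_difference <- function(report, quantity = c("shock", "money")) {
  quantity <- match.arg(quantity)
  check_reports(report)
  if (quantity == "shock") report$rp_s_high - report$rp_s_low
  else report$rp_m_high - report$rp_m_low
}

#' Report bias: difference-of-differences of explicit reports
#'
#' `bias = (rpS(high-shock) - rpS(low-shock)) - (rpM(high-money) -
#' rpM(low-money))`. Positive values mean the shock contingency was learned
#' (or at least reported) more sharply than the money contingency —
#' shock-dominant learning.
#'
#' @param report As in [report_difference()].
#' @return Tibble with `shock_diff`, `money_diff`, `bias`.
#' @export
report_bias <- function(report) {
  check_reports(report)
  sd_ <- report_difference(report, "shock")
  md <- report_difference(report, "money")
  tibble::tibble(shock_diff = sd_, money_diff = md, bias = sd_ - md)
}

#' Pearson correlation between choice preference and report bias
#'
#' @param prop_considerate Per-subject proportion of considerate choices.
#' @param bias Per-subject mean report bias.
#' @return Pearson correlation coefficient.
#' @export
preference_bias_correlation <- function(prop_considerate, bias) {
  stopifnot(length(prop_considerate) == length(bias),
            length(bias) >= 3L)
  if (sd(prop_considerate) == 0 || sd(bias) == 0) {
    stop("zero variance in one of the inputs", call. = FALSE)
  }
  cor(prop_considerate, bias)
}

#' Kendall rank correlation (tau-b)
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return Kendall's tau-b.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector", call. = FALSE)
  cor(x, y, method = "kendall")
}

#' Devaluation summary at the 10th and 11th trials
#'
#' Mean proportion of considerate choices at the last pre-devaluation trial
#' (10) and the first post-devaluation trial (11) of Conflict dropout
#' blocks, split by preference group and by which outcome was withheld.
#'
#' @param cohort Trial tibble with Conflict dropout blocks.
#' @param labels Tibble from [classify_cohort()] (computed if omitted).
#' @return Tibble: `label` x `removed` x `trial` with `mean_considerate`,
#'   `sem`, `n_subjects`; empty cells are flagged with `NA` means.
#' @export
devaluation_summary <- function(cohort, labels = NULL) {
  labels <- labels %||% classify_cohort(cohort)
  dat <- cohort[cohort$condition == "Conflict" &
                  cohort$dropout_type != "None" &
                  cohort$trial_index %in% c(10L, 11L), , drop = FALSE]
  if (!nrow(dat)) stop("cohort has no Conflict dropout blocks", call. = FALSE)
  cons <- considerate_symbol("Conflict")
  dat$considerate <- as.integer(dat$chosen_symbol == cons)
  dat$removed <- ifelse(dat$dropout_type == "MoneyDropout", "money", "shock")
  dat <- dplyr::left_join(dat, labels[, c("subject_id", "label")],
                          by = "subject_id")
  per_subj <- dplyr::summarise(
    dplyr::group_by(dat, .data$label, .data$removed, .data$trial_index,
                    .data$subject_id),
    prop = mean(.data$considerate), .groups = "drop")
  grid <- tidyr::expand_grid(label = c("Considerate", "Lucrative", "Ambiguous"),
                             removed = c("money", "shock"),
                             trial_index = c(10L, 11L))
  out <- dplyr::summarise(
    dplyr::group_by(per_subj, .data$label, .data$removed, .data$trial_index),
    mean_considerate = mean(.data$prop),
    sem = sd(.data$prop) / sqrt(dplyr::n()),
    n_subjects = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(grid, out, by = c("label", "removed", "trial_index"))
  out$n_subjects[is.na(out$n_subjects)] <- 0L
  out
}

#' Group learning curves
#'
#' Mean proportion of considerate choices per trial position over the first
#' 10 trials of Conflict blocks, per preference group.
#'
#' @param cohort Trial tibble.
#' @param labels Tibble from [classify_cohort()] (computed if omitted).
#' @return Tibble: `label`, `trial_index`, `mean_considerate`, `sem`.
#' @export
learning_curves <- function(cohort, labels = NULL) {
  labels <- labels %||% classify_cohort(cohort)
  dat <- cohort[cohort$condition == "Conflict" & cohort$trial_index <= 10L, ]
  cons <- considerate_symbol("Conflict")
  dat$considerate <- as.integer(dat$chosen_symbol == cons)
  dat <- dplyr::left_join(dat, labels[, c("subject_id", "label")],
                          by = "subject_id")
  per_subj <- dplyr::summarise(
    dplyr::group_by(dat, .data$label, .data$trial_index, .data$subject_id),
    prop = mean(.data$considerate), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_subj, .data$label, .data$trial_index),
    mean_considerate = mean(.data$prop),
    sem = sd(.data$prop) / sqrt(dplyr::n()), .groups = "drop")
}
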