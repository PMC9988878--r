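#' Value coding of trial outcomes
#'
#' Outcomes are coded by value for the decider's moral frame: a high monetary
#' gain for the self is good (+1), a low gain bad (-1); a painful (high)
#' shock to the other is bad (-1), a non-painful (low) shock good (+1). An
#' outcome withheld during a dropout phase carries no information (0).
#'
#' @param kind One of `"high_money"`, `"low_money"`, `"high_shock"`,
#'   `"low_shock"`, `"withheld"`.
#' @return `+1`, `-1`, or `0`.
#' @examples
#' outcome_value("high_shock")  # -1
#' outcome_value("withheld")    # 0
#' @export
outcome_value <- function(kind) {
  map <- c(high_money = 1, low_money = -1, high_shock = -1, low_shock = 1,
           withheld = 0)
  if (!is.character(kind) || length(kind) != 1L || !kind %in% names(map)) {
    stop("unknown outcome kind: ", paste(kind, collapse = ", "), call. = FALSE)
  }
  unname(map[[kind]])
}

#' Which symbol is the considerate option
#'
#' Symbol 1 is always the high-money symbol. In the Conflict condition it is
#' also the high-shock (lucrative) symbol, so the considerate option is
#' symbol 2; in the NoConflict condition symbol 1 is high-money *and*
#' low-shock, so it is itself the considerate-compatible best option.
#'
#' @param condition `"Conflict"` or `"NoConflict"`.
#' @return Integer symbol index (1 or 2).
#' @export
considerate_symbol <- function(condition) {
  condition <- match.arg(condition, c("Conflict", "NoConflict"))
  if (condition == "Conflict") 2L else 1L
}

#' Specify one block of the learning task
#'
#' A block presents the same symbol pair for 10 learning trials (plus,
#' in dropout blocks, 10 further trials after one outcome is withdrawn).
#' Contingencies give, per symbol, the probability of the high-money and
#' high-shock outcome; money and shock are drawn independently.
#'
#' @param condition `"Conflict"` (default contingency: symbol 1 = (0.8, 0.8),
#'   symbol 2 = (0.2, 0.2)) or `"NoConflict"` (symbol 1 = (0.8, 0.2),
#'   symbol 2 = (0.2, 0.8)).
#' @param dropout `"None"`, `"MoneyDropout"`, or `"ShockDropout"`.
#' @param n_learning_trials,n_dropout_trials Trial counts; dropout blocks
#'   default to 10 + 10, no-dropout blocks to 10 + 0.
#' @param p_high_money,p_high_shock Optional length-2 probability overrides
#'   (one entry per symbol).
#' @return A `block_spec` list.
#' @export
block_spec <- function(condition = c("Conflict", "NoConflict"),
                       dropout = c("None", "MoneyDropout", "ShockDropout"),
                       n_learning_trials = 10L,
                       n_dropout_trials = NULL,
                       p_high_money = NULL, p_high_shock = NULL) {
  condition <- match.arg(condition)
  dropout <- match.arg(dropout)
  if (is.null(n_dropout_trials)) {
    n_dropout_trials <- if (dropout == "None") 0L else 10L
  }
  n_learning_trials <- as.integer(n_learning_trials)
  n_dropout_trials <- as.integer(n_dropout_trials)
  if (n_learning_trials < 1L || n_dropout_trials < 0L) {
    stop("negative or empty trial counts", call. = FALSE)
  }
  if (dropout == "None" && n_dropout_trials != 0L) {
    stop("dropout = 'None' requires n_dropout_trials = 0", call. = FALSE)
  }
  if (dropout != "None" && n_dropout_trials == 0L) {
    stop("dropout blocks require n_dropout_trials > 0", call. = FALSE)
  }
  if (is.null(p_high_money)) {
    p_high_money <- c(0.8, 0.2)
  }
  if (is.null(p_high_shock)) {
    p_high_shock <- if (condition == "Conflict") c(0.8, 0.2) else c(0.2, 0.8)
  }
  stopifnot(length(p_high_money) == 2L, length(p_high_shock) == 2L)
  assert_prob(p_high_money, "p_high_money")
  assert_prob(p_high_shock, "p_high_shock")
  structure(
    list(condition = condition, dropout = dropout,
         n_learning_trials = n_learning_trials,
         n_dropout_trials = n_dropout_trials,
         p_high_money = as.numeric(p_high_money),
         p_high_shock = as.numeric(p_high_shock)),
    class = "block_spec")
}

#' Experimental design: an ordered list of blocks
#'
#' Two presets mirror the study layouts. `"online"` contains 4 repetitions
#' of each of the 6 block types (Conflict and NoConflict crossed with
#' no-dropout, money-dropout and shock-dropout; 24 blocks). `"fmri"`
#' contains 6 ConflictNoDropout blocks.
#'
#' @param preset `"online"`, `"fmri"`, or `"custom"` (then supply `blocks`).
#' @param blocks For `"custom"`: list of [block_spec()] objects.
#' @return A `design_spec` list with elements `label` and `blocks`.
#' @export
design_spec <- function(preset = c("online", "fmri", "custom"), blocks = NULL) {
  preset <- match.arg(preset)
  if (preset == "online") {
    blocks <- unlist(lapply(c("Conflict", "NoConflict"), function(cond) {
      lapply(rep(c("None", "MoneyDropout", "ShockDropout"), each = 4L),
             function(d) block_spec(cond, d))
    }), recursive = FALSE)
  } else if (preset == "fmri") {
    blocks <- lapply(1:6, function(i) block_spec("Conflict", "None"))
  } else {
    if (is.null(blocks) || !length(blocks) ||
        !all(vapply(blocks, inherits, TRUE, "block_spec"))) {
      stop("custom designs need a non-empty list of block_spec objects",
           call. = FALSE)
    }
  }
  structure(list(label = preset, blocks = blocks), class = "design_spec")
}

#' The design used for model fitting and recovery
#'
#' Eight ConflictDropout blocks (4 money-dropout + 4 shock-dropout), the
#' blocks whose first 10 trials enter the hierarchical fit and whose 11th
#' trials provide the held-out devaluation test.
#'
#' @return A `design_spec`.
#' @export
design_conflict_dropout <- function() {
  design_spec("custom", blocks = lapply(
    rep(c("MoneyDropout", "ShockDropout"), each = 4L),
    function(d) block_spec("Conflict", d)))
}

#' Read a custom design from a YAML file
#'
#' The file must contain a `blocks` list; each entry may give `condition`,
#' `dropout`, `n_learning_trials`, `n_dropout_trials`, `p_high_money`,
#' `p_high_shock`, and an optional `repeat` count.
#'
#' @param path Path to a YAML design file.
#' @return A `design_spec`.
#' @export
read_design_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$blocks)) stop("design file has no 'blocks' entry", call. = FALSE)
  blocks <- unlist(lapply(cfg$blocks, function(b) {
    n <- as.integer(b[["repeat"]] %||% 1L)
    spec <- block_spec(condition = b$condition %||% "Conflict",
                       dropout = b$dropout %||% "None",
                       n_learning_trials = b$n_learning_trials %||% 10L,
                       n_dropout_trials = b$n_dropout_trials,
                       p_high_money = b$p_high_money,
                       p_high_shock = b$p_high_shock)
    rep(list(spec), n)
  }), recursive = FALSE)
  design_spec("custom", blocks = blocks)
}

#' Pre-draw the outcome schedule of a block
#'
#' One independent Bernoulli draw per (trial, symbol, quantity): money comes
#' up high with the symbol's `p_high_money`, shock with `p_high_shock`, coded
#' by value via [outcome_value()]. Outcomes are pre-drawn for both symbols so
#' the schedule is independent of the agent's choices; during the dropout
#' phase the removed quantity is 0 for both symbols.
#'
#' @param spec A [block_spec()].
#' @param seed Optional integer seed (the caller's RNG stream is untouched).
#' @return Tibble with columns `trial_index`, `phase`, `symbol`,
#'   `out_money`, `out_shock`.
#' @export
generate_outcome_schedule <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  with_seed(seed, {
    n <- spec$n_learning_trials + spec$n_dropout_trials
    grid <- expand.grid(symbol = 1:2, trial_index = seq_len(n))
    # draws are made trial-major so each (trial, symbol, quantity) is one
    # independent Bernoulli variate
    high_m <- rbinom(2L * n, 1L, spec$p_high_money[grid$symbol]) == 1L
    high_s <- rbinom(2L * n, 1L, spec$p_high_shock[grid$symbol]) == 1L
    out <- tibble::tibble(
      trial_index = grid$trial_index,
      phase = ifelse(grid$trial_index <= spec$n_learning_trials,
                     "learning", "dropout"),
      symbol = as.integer(grid$symbol),
      out_money = ifelse(high_m, 1, -1),
      out_shock = ifelse(high_s, -1, 1))
    if (spec$dropout == "MoneyDropout") {
      out$out_money[out$phase == "dropout"] <- 0
    } else if (spec$dropout == "ShockDropout") {
      out$out_shock[out$phase == "dropout"] <- 0
    }
    out[order(out$trial_index, out$symbol), , drop = FALSE]
  })
}

#' Generate schedules for every block of a design
#'
#' @param design A [design_spec()].
#' @param seed Integer seed controlling both block-order randomization and
#'   the outcome draws.
#' @param randomize_order Shuffle block order (default `TRUE`); `FALSE`
#'   keeps the design's listed order, useful for fixtures.
#' @return Tibble with columns `block_id`, `condition`, `dropout_type`,
#'   `trial_index`, `phase`, `symbol`, `out_money`, `out_shock`.
#' @export
generate_design_schedules <- function(design, seed = NULL, randomize_order = TRUE) {
  stopifnot(inherits(design, "design_spec"))
  with_seed(seed, {
    ord <- if (randomize_order) sample(seq_along(design$blocks)) else seq_along(design$blocks)
    dplyr::bind_rows(lapply(seq_along(ord), function(i) {
      spec <- design$blocks[[ord[i]]]
      sched <- generate_outcome_schedule(spec)
      tibble::tibble(block_id = i, condition = spec$condition,
                     dropout_type = spec$dropout, sched)
    }))
  })
}
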