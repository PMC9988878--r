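test_that("model registry validates names and parameter ranges", {
  expect_error(init_state("M3"), "unknown model")
  expect_error(model_params("M2Out", wf = 0.5, lr_m = 0.2, lr_s = 0.2,
                            tau = 7), "outside")
  expect_error(model_params("M1", wf = 0.5, tau = 1), "needs parameters")
  s <- init_state("M2Out")
  expect_equal(s$ev_m, c(0, 0))
  expect_equal(s$ev_s, c(0, 0))
  expect_equal(init_state("M1")$ev, c(0, 0))
})

test_that("decision values follow each model's weighting rule", {
  p <- model_params("M2Dec", wf = 0.3, lr_m = 0.2, lr_s = 0.2, tau = 1)
  s <- init_state("M2Dec", p)
  s$ev_m <- c(1, 0); s$ev_s <- c(-1, 0)
  expect_equal(decision_value("M2Dec", s, p, 1), 0.3 * 1 + 0.7 * (-1))
  expect_equal(decision_value("M0", s, p), c(0, 0))
  # alpha = 1 turns the distributed model into the outcome-weighted one
  pdo <- model_params("M2DO", wf = 0.3, lr_m = 0.2, lr_s = 0.2, tau = 1,
                      alpha = 1)
  pout <- model_params("M2Out", wf = 0.3, lr_m = 0.2, lr_s = 0.2, tau = 1)
  sdo <- s; sdo$model <- "M2DO"
  expect_equal(decision_value("M2DO", sdo, pdo), decision_value("M2Out", s, pout))
  # alpha = 0 turns it into the decision-weighted one
  pdo0 <- model_params("M2DO", wf = 0.3, lr_m = 0.2, lr_s = 0.2, tau = 1,
                       alpha = 0)
  expect_equal(decision_value("M2DO", sdo, pdo0), decision_value("M2Dec", s, p))
})

test_that("softmax choice probabilities are stabilized and bounded", {
  p <- model_params("M1", wf = 0.5, lr = 0.2, tau = 1)
  s <- init_state("M1", p)
  expect_equal(choice_prob("M1", s, p), c(0.5, 0.5))
  s$ev <- c(1, -1)
  expect_equal(choice_prob("M1", s, p), c(1 / (1 + exp(-2)), exp(-2) / (1 + exp(-2))),
               tolerance = 1e-12)
  expect_equal(choice_prob("M1", s, p)[1], 0.88080, tolerance = 1e-5)
  p0 <- model_params("M1", wf = 0.5, lr = 0.2, tau = 0)
  expect_equal(choice_prob("M1", s, p0), c(0.5, 0.5))
  p$tau <- 9
  expect_error(choice_prob("M1", s, p), "tau")
})

test_that("updates scale outcomes by the preference weight only where the model says", {
  p <- model_params("M2Out", wf = 0.5, lr_m = 0.5, lr_s = 0.5, tau = 1)
  s <- init_state("M2Out", p)
  r <- update_state("M2Out", s, 1L, 1, 0, p)
  expect_equal(r$pe_m, 0.5)
  expect_equal(r$state$ev_m[1], 0.25)
  expect_error(update_state("M2Out", s, 1L, 2, 0, p), "outcome values")
  # withheld outcome with zero expectation changes nothing
  r0 <- update_state("M2Out", s, 1L, 0, 0, p)
  expect_equal(r0$state$ev_m, c(0, 0))
  expect_equal(r0$pe_m, 0)
  # fully considerate limit: money outcomes never move EV_M upward
  pw0 <- model_params("M2Out", wf = 0, lr_m = 0.5, lr_s = 0.5, tau = 1)
  sw <- init_state("M2Out", pw0); sw$ev_m <- c(0.4, 0)
  rw <- update_state("M2Out", sw, 1L, 1, 1, pw0)
  expect_equal(rw$pe_m, -0.4)
  expect_equal(rw$state$ev_m[1], 0.2)
})

test_that("dropout transition zeroes the removed expectation and reweights decisions", {
  p <- model_params("M2Out", wf = 0.3, lr_m = 0.4, lr_s = 0.4, tau = 2)
  s <- init_state("M2Out", p)
  s$ev_s <- c(-0.4, 0.4); s$ev_m <- c(0.25, -0.25)
  s2 <- apply_dropout("M2Out", s, p, "shock")
  expect_equal(s2$ev_s, c(0, 0))
  expect_equal(s2$wf_eff, 1)
  expect_equal(decision_value("M2Out", s2, p), s$ev_m)
  expect_error(apply_dropout("M2Out", s2, p, "shock"), "already applied")
  # M1 keeps its combined expectation
  pm1 <- model_params("M1", wf = 0.3, lr = 0.4, tau = 2)
  sm1 <- init_state("M1", pm1); sm1$ev <- c(0.5, -0.5)
  sm1b <- apply_dropout("M1", sm1, pm1, "money")
  expect_equal(sm1b$ev, sm1$ev)
  # considerate agent with EV_M ~ 0: removing shocks leaves ~chance choice
  sc <- init_state("M2Out", p); sc$ev_m <- c(0.02, -0.02); sc$ev_s <- c(-0.6, 0.6)
  scd <- apply_dropout("M2Out", sc, p, "shock")
  expect_equal(choice_prob("M2Out", scd, p), c(0.5, 0.5), tolerance = 0.05)
})

test_that("removing the higher-weighted quantity shifts choices more", {
  p <- model_params("M2Out", wf = 0.3, lr_m = 0.4, lr_s = 0.4, tau = 3)
  dat <- random_subject_data(n_blocks = 1L, seed = 21)
  s <- init_state("M2Out", p)
  for (t in seq_len(nrow(dat))) {
    s <- update_state("M2Out", s, dat$chosen_symbol[t], dat$out_money[t],
                      dat$out_shock[t], p)$state
  }
  p_before <- choice_prob("M2Out", s, p)[1]
  p_shock <- choice_prob("M2Out", apply_dropout("M2Out", s, p, "shock"), p)[1]
  p_money <- choice_prob("M2Out", apply_dropout("M2Out", s, p, "money"), p)[1]
  expect_gt(abs(p_shock - p_before), abs(p_money - p_before))
})

test_that("sequential log-likelihood matches the hand-computed worked example", {
  sd3 <- tibble::tibble(block_id = 1L, dropout_type = "None",
                        trial_index = 1:3, chosen_symbol = c(1L, 1L, 1L),
                        out_money = c(1, 1, 1), out_shock = c(-1, 1, 1))
  p <- model_params("M2Out", wf = 0.5, lr_m = 0.5, lr_s = 0.5, tau = 2)
  ll <- loglik_subject("M2Out", p, sd3, "all")
  # trial 1 and 2 utilities cancel (EV_M = 0.25, EV_S = -0.25); trial 3
  # utility 0.5 gives p = 1 / (1 + exp(-1)) = 0.731059
  expect_equal(ll, c(log(0.5), log(0.5), log(1 / (1 + exp(-1)))),
               tolerance = 1e-12)
  expect_equal(sum(ll), -1.6995561, tolerance = 1e-6)
})

test_that("sequential likelihood agrees with the brute-force oracle (R and C++)", {
  cases <- expand.grid(model = c("M1", "M2Out", "M2Dec", "M2DO"),
                       dropout = c("None", "MoneyDropout", "ShockDropout"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    model <- cases$model[k]
    n <- if (cases$dropout[k] == "None") 10L else 20L
    dat <- random_subject_data(n_blocks = 2L, n_trials = n,
                               dropout = cases$dropout[k], seed = 100 + k)
    if (cases$dropout[k] != "None") {
      dat$out_money[dat$trial_index > 10 & dat$dropout_type == "MoneyDropout"] <- 0
      dat$out_shock[dat$trial_index > 10 & dat$dropout_type == "ShockDropout"] <- 0
    }
    set.seed(k)
    pars <- list(wf = runif(1, 0.05, 0.95), lr = runif(1), lr_m = runif(1),
                 lr_s = runif(1), tau = runif(1, 0.1, 5), alpha = runif(1))
    pobj <- do.call(model_params,
                    c(list(model = model),
                      pars[model_param_names(model)]))
    expected <- unlist(lapply(split(dat, dat$block_id), function(b) {
      oracle_loglik(model, pars, b)
    }), use.names = FALSE)
    expect_equal(loglik_subject(model, pobj, dat, "all"), expected,
                 tolerance = 1e-12, label = paste(model, cases$dropout[k]))
    flat <- moralbandit:::flatten_cohort(
      tibble::add_column(dat, subject_id = 1L, .before = 1), blocks = "all")
    llc <- moralbandit:::cpp_pointwise_loglik(
      moralbandit:::model_code(model), moralbandit:::params_vector(pobj),
      flat$choice, flat$outm, flat$outs, flat$block_ptr, flat$block_drop, 3L)
    expect_equal(llc, expected, tolerance = 1e-12,
                 label = paste("cpp", model, cases$dropout[k]))
  }
})

test_that("M1, M2Out and M2Dec are choice-equivalent on learning trials with equal learning rates", {
  for (seed in 1:5) {
    set.seed(seed)
    wf <- runif(1, 0.05, 0.95); lr <- runif(1, 0.05, 0.9)
    tau <- runif(1, 0.5, 5)
    dat <- random_subject_data(n_blocks = 3L, seed = 300 + seed)
    ll <- lapply(list(
      model_params("M1", wf = wf, lr = lr, tau = tau),
      model_params("M2Out", wf = wf, lr_m = lr, lr_s = lr, tau = tau),
      model_params("M2Dec", wf = wf, lr_m = lr, lr_s = lr, tau = tau)),
      function(p) loglik_subject(p$model, p, dat, "learning"))
    expect_lt(max(abs(ll[[1]] - ll[[2]])), 1e-12)
    expect_lt(max(abs(ll[[1]] - ll[[3]])), 1e-12)
  }
})

test_that("M2DO reduces exactly to M2Out at alpha = 1 and M2Dec at alpha = 0, all phases", {
  dat <- random_subject_data(n_blocks = 2L, n_trials = 20L,
                             dropout = "ShockDropout", seed = 9)
  dat$out_shock[dat$trial_index > 10] <- 0
  set.seed(9)
  wf <- runif(1, 0.05, 0.95)
  base <- list(wf = wf, lr_m = 0.3, lr_s = 0.6, tau = 2.5)
  ll_do1 <- loglik_subject("M2DO", do.call(model_params,
            c(list(model = "M2DO"), base, alpha = 1)), dat, "all")
  ll_out <- loglik_subject("M2Out", do.call(model_params,
            c(list(model = "M2Out"), base)), dat, "all")
  expect_equal(ll_do1, ll_out, tolerance = 1e-12)
  ll_do0 <- loglik_subject("M2DO", do.call(model_params,
            c(list(model = "M2DO"), base, alpha = 0)), dat, "all")
  ll_dec <- loglik_subject("M2Dec", do.call(model_params,
            c(list(model = "M2Dec"), base)), dat, "all")
  expect_equal(ll_do0, ll_dec, tolerance = 1e-12)
})

test_that("expected values stay inside their attainable ranges along trajectories", {
  for (seed in 1:10) {
    set.seed(seed)
    wf <- runif(1); lrm <- runif(1); lrs <- runif(1)
    p <- model_params("M2Out", wf = wf, lr_m = lrm, lr_s = lrs, tau = 1)
    s <- init_state("M2Out", p)
    dat <- random_subject_data(n_blocks = 1L, n_trials = 10L,
                               seed = 400 + seed)
    for (t in seq_len(nrow(dat))) {
      s <- update_state("M2Out", s, dat$chosen_symbol[t], dat$out_money[t],
                        dat$out_shock[t], p)$state
      expect_true(all(abs(s$ev_m) <= wf + 1e-12))
      expect_true(all(abs(s$ev_s) <= 1 - wf + 1e-12))
    }
  }
})

test_that("M0 and flat softmax yield chance log-likelihood everywhere", {
  dat <- random_subject_data(n_blocks = 2L, seed = 31)
  p0 <- model_params("M0", tau = 1)
  expect_equal(loglik_subject("M0", p0, dat, "all"),
               rep(log(0.5), nrow(dat)))
  pflat <- model_params("M2Out", wf = 0.4, lr_m = 0.5, lr_s = 0.5, tau = 0)
  expect_equal(loglik_subject("M2Out", pflat, dat, "all"),
               rep(log(0.5), nrow(dat)))
})

test_that("wf-normalized regressors put the first prediction error on the outcome scale", {
  for (wf in c(0.1, 0.37, 0.8)) {
    p <- model_params("M2Out", wf = wf, lr_m = 0.4, lr_s = 0.4, tau = 2)
    dat <- random_subject_data(n_blocks = 2L, seed = 77)
    dat$out_shock[1] <- -1 # high-shock first outcome
    regs <- extract_regressors(p, dat, center = FALSE)
    expect_equal(regs$pe_s_norm[1], -1)
    dat$out_shock[1] <- 1
    regs2 <- extract_regressors(p, dat, center = FALSE)
    expect_equal(regs2$pe_s_norm[1], 1)
  }
  # centered modulators have zero mean
  p <- model_params("M2Out", wf = 0.3, lr_m = 0.4, lr_s = 0.4, tau = 2)
  dat <- random_subject_data(n_blocks = 2L, seed = 78)
  regs <- extract_regressors(p, dat, center = TRUE)
  expect_equal(mean(regs$pe_s_norm), 0, tolerance = 1e-12)
  expect_equal(mean(regs$ev_m_norm), 0, tolerance = 1e-12)
  # degenerate weights are rejected
  pbad <- model_params("M2Out", wf = 1, lr_m = 0.4, lr_s = 0.4, tau = 2)
  expect_error(extract_regressors(pbad, dat), "undefined")
})
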