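test_that("cohort parameters are drawn through the probit pushforward", {
  hyper <- list(wf = c(0, 0), lr_m = c(0, 0), lr_s = c(0, 0), tau = c(0, 0))
  ps <- sample_cohort_params(hyper, 3, seed = 1)
  expect_length(ps, 3L)
  # degenerate SDs pin every draw at the CDF of the mean
  expect_equal(ps[[1]]$wf, 0.5)
  expect_equal(ps[[1]]$tau, 2.5)
  expect_error(sample_cohort_params(hyper, 0), "positive")
  expect_error(sample_cohort_params(list(wf = c(0, 1)), 2, model = "M2Out"),
               "lacks entries")
  # monotonicity of the transform
  u <- sort(rnorm(50))
  expect_true(all(diff(constrain(u, "unit")) > 0))
  expect_true(all(diff(constrain(u, "tau")) > 0))
})

test_that("agent simulation is seeded and respects the design", {
  p <- model_params("M2Out", wf = 0.2, lr_m = 0.4, lr_s = 0.4, tau = 3)
  a <- agent_spec("M2Out", p, seed = 5)
  d1 <- simulate_agent(a, design_conflict_dropout())
  d2 <- simulate_agent(a, design_conflict_dropout())
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 8L * 20L)
  expect_setequal(unique(d1$dropout_type), c("MoneyDropout", "ShockDropout"))
  expect_true(all(d1$out_money[d1$dropout_type == "MoneyDropout" &
                                 d1$phase == "dropout"] == 0))
  validate_trials(tibble::add_column(d1, subject_id = 1L, .before = 1))
})

test_that("random agents choose at chance and learners reach stable preferences", {
  p0 <- model_params("M2Out", wf = 0.5, lr_m = 0.3, lr_s = 0.3, tau = 0)
  d <- simulate_agent(agent_spec("M2Out", p0, seed = 2), design_spec("online"))
  n <- nrow(d)
  prop <- mean(d$chosen_symbol == 2L)
  # binomial 99% interval around chance
  expect_lt(abs(prop - 0.5), qnorm(0.995) * sqrt(0.25 / n))

  # considerate learners approach the 80/20 asymptote on late learning trials
  pc <- model_params("M2Out", wf = 0.05, lr_m = 0.3, lr_s = 0.3, tau = 5)
  co <- simulate_cohort(rep(list(pc), 400), design_conflict_dropout(),
                        seed = 3)
  late <- co[co$trial_index %in% 7:10, ]
  prop_late <- mean(late$chosen_symbol == considerate_symbol("Conflict"))
  expect_gt(prop_late, 0.7)
  expect_lt(prop_late, 0.9)
})

test_that("extreme-weight cohorts produce monotone-trending group learning curves", {
  pc <- model_params("M2Out", wf = 0.05, lr_m = 0.3, lr_s = 0.3, tau = 4)
  pl <- model_params("M2Out", wf = 0.95, lr_m = 0.3, lr_s = 0.3, tau = 4)
  co <- simulate_cohort(c(rep(list(pc), 250), rep(list(pl), 250)),
                        design_conflict_dropout(), seed = 17)
  lc <- learning_curves(co, classify_cohort(co))
  cons <- lc[lc$label == "Considerate", ]
  lucr <- lc[lc$label == "Lucrative", ]
  # trend over trials 1-10: strong positive (considerate) / negative (lucrative)
  expect_gt(cor(cons$trial_index, cons$mean_considerate), 0.9)
  expect_lt(cor(lucr$trial_index, lucr$mean_considerate), -0.9)
  expect_lt(cons$mean_considerate[1], 0.6) # starts near chance
  expect_gt(cons$mean_considerate[10], 0.75)
})

test_that("simulated reports map expectations onto the probability scale", {
  fe <- tibble::tibble(condition = "Conflict", ev_m_1 = 0, ev_m_2 = 0,
                       ev_s_1 = 0, ev_s_2 = 0)
  r0 <- simulate_reports(fe, noise_sd = 0)
  expect_equal(unlist(r0), c(rp_m_high = 50, rp_m_low = 50,
                             rp_s_high = 50, rp_s_low = 50))
  # saturated expectations hit the scale endpoints
  fe2 <- tibble::tibble(condition = "Conflict", ev_m_1 = 1, ev_m_2 = -1,
                        ev_s_1 = -1, ev_s_2 = 1)
  r2 <- simulate_reports(fe2, noise_sd = 0)
  expect_equal(r2$rp_s_high, 100)
  expect_equal(r2$rp_s_low, 0)
  expect_equal(r2$rp_m_high, 100)
  expect_error(simulate_reports(fe, noise_sd = -1), "non-negative")
  # noisy reports are reproducible and clipped
  set.seed(1)
  rn1 <- simulate_reports(fe2, noise_sd = 30, seed = 8)
  rn2 <- simulate_reports(fe2, noise_sd = 30, seed = 8)
  expect_identical(rn1, rn2)
  expect_true(all(unlist(rn1) >= 0 & unlist(rn1) <= 100))
})

test_that("considerate cohorts show positive report bias and matching classifications", {
  hyper <- list(wf = list(uniform = c(0.03, 0.2)), lr_m = c(-0.5, 0.3),
                lr_s = c(-0.5, 0.3), tau = c(0.5, 0.3))
  params <- sample_cohort_params(hyper, 60, seed = 21)
  co <- simulate_cohort(params, design_spec("online"), seed = 22)
  lab <- classify_cohort(co)
  expect_gt(mean(lab$label == "Considerate"), 0.6)
  rep <- simulate_cohort_reports(co, noise_sd = 5, seed = 23)
  conf <- rep[rep$condition == "Conflict", ]
  bias <- report_bias(conf)$bias
  expect_gt(mean(bias), 0)
})
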