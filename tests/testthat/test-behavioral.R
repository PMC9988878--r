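test_that("binomial bounds match the study's printed values", {
  expect_equal(binomial_bounds(120), c(lower = 49, upper = 71))
  expect_equal(binomial_bounds(60), c(lower = 22, upper = 38))
  expect_equal(unname(binomial_bounds(1)), c(0, 1))
  expect_error(binomial_bounds(120, alpha = 0), "alpha")
  expect_error(binomial_bounds(120, alpha = 1.2), "alpha")
})

test_that("binomial bounds agree with brute-force CDF summation for n up to 500", {
  for (n in c(1:60, seq(61, 500, by = 7))) {
    b <- binomial_bounds(n)
    probs <- cumsum(vapply(0:n, function(k) choose(n, k) * 0.5^n, numeric(1)))
    expect_equal(b[["upper"]], (0:n)[match(TRUE, probs >= 0.975)])
    expect_equal(b[["lower"]], (0:n)[match(TRUE, probs > 0.025)])
  }
  # symmetry around n/2 for even n
  for (n in seq(10, 500, by = 10)) {
    b <- binomial_bounds(n)
    expect_equal(b[["lower"]] + b[["upper"]], n)
  }
})

test_that("preference classification uses strict inequalities against the bounds", {
  expect_equal(classify_preference(72, 120)$label, "Considerate")
  expect_equal(classify_preference(48, 120)$label, "Lucrative")
  expect_equal(classify_preference(60, 120)$label, "Ambiguous")
  # boundary counts stay ambiguous under the strict reading
  expect_equal(classify_preference(71, 120)$label, "Ambiguous")
  expect_equal(classify_preference(49, 120)$label, "Ambiguous")
  expect_equal(classify_preference(39, 60)$label, "Considerate")
  expect_equal(classify_preference(21, 60)$label, "Lucrative")
  expect_error(classify_preference(121, 120), "count")
})

test_that("chance-level cohorts are almost always labelled ambiguous", {
  p0 <- model_params("M2Out", wf = 0.5, lr_m = 0.3, lr_s = 0.3, tau = 0)
  co <- simulate_cohort(rep(list(p0), 600), design_spec("online"), seed = 19)
  lab <- classify_cohort(co)
  expect_equal(lab$n[1], 120L)
  frac <- mean(lab$label == "Ambiguous")
  # nominal coverage ~0.95, allow binomial noise at n = 600
  expect_gt(frac, 0.95 - 3 * sqrt(0.95 * 0.05 / 600))
})

test_that("report differences are signed toward the programmed contingency", {
  r <- tibble::tibble(rp_m_high = 80, rp_m_low = 20, rp_s_high = 80,
                      rp_s_low = 20)
  expect_equal(report_difference(r, "shock"), 60)
  expect_equal(report_difference(r, "money"), 60)
  flat <- tibble::tibble(rp_m_high = 50, rp_m_low = 50, rp_s_high = 50,
                         rp_s_low = 50)
  expect_equal(report_difference(flat, "shock"), 0)
  rev <- tibble::tibble(rp_m_high = 20, rp_m_low = 80, rp_s_high = 20,
                        rp_s_low = 80)
  expect_equal(report_difference(rev, "shock"), -60)
  bad <- tibble::tibble(rp_m_high = 120, rp_m_low = 20, rp_s_high = 50,
                        rp_s_low = 50)
  expect_error(report_difference(bad, "money"), "0, 100")
})

test_that("report bias is the difference of differences and is antisymmetric", {
  mk <- function(sh, sl, mh, ml) tibble::tibble(rp_s_high = sh, rp_s_low = sl,
                                                rp_m_high = mh, rp_m_low = ml)
  expect_equal(report_bias(mk(80, 20, 80, 20))$bias, 0)
  expect_equal(report_bias(mk(80, 20, 70, 30))$bias, 20)
  expect_equal(report_bias(mk(50, 50, 80, 20))$bias, -60)
  # swapping the shock and money pairs flips the sign
  a <- report_bias(mk(75, 35, 60, 45))$bias
  b <- report_bias(mk(60, 45, 75, 35))$bias
  expect_equal(a, -b)
})

test_that("preference-bias correlation behaves at its limits and on synthetic cohorts", {
  x <- seq(0, 1, length.out = 20)
  expect_equal(preference_bias_correlation(x, 5 + 3 * x), 1)
  set.seed(3)
  expect_lt(abs(preference_bias_correlation(rnorm(1e4), rnorm(1e4))), 0.03)
  expect_error(preference_bias_correlation(rep(1, 5), rnorm(5)), "variance")
  # synthetic separable-outcome cohorts spanning wf reproduce the positive link
  hyper <- list(wf = list(uniform = c(0.05, 0.95)), lr_m = c(-0.5, 0.5),
                lr_s = c(-0.5, 0.5), tau = c(0.3, 0.4))
  co <- simulate_cohort(sample_cohort_params(hyper, 80, seed = 31),
                        design_spec("online"), seed = 32)
  rep_ <- simulate_cohort_reports(co, noise_sd = 8, seed = 33)
  conf <- rep_[rep_$condition == "Conflict", ]
  bias <- tapply(report_bias(conf)$bias, conf$subject_id, mean)
  lab <- classify_cohort(co)
  r <- preference_bias_correlation(lab$prop_considerate,
                                   bias[as.character(lab$subject_id)])
  expect_gt(r, 0)
})

test_that("rank correlation reproduces Kendall's tau", {
  expect_equal(rank_correlation(1:10, 1:10), 1)
  expect_equal(rank_correlation(1:10, 10:1), -1)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  expect_error(rank_correlation(rep(2, 5), 1:5), "constant")
})

test_that("devaluation summaries show the asymmetric shift for extreme weights", {
  pc <- model_params("M2Out", wf = 0.05, lr_m = 0.3, lr_s = 0.3, tau = 5)
  co <- simulate_cohort(rep(list(pc), 250), design_conflict_dropout(),
                        seed = 47)
  dv <- devaluation_summary(co)
  cons <- dv[dv$label == "Considerate", ]
  t10_shock <- cons$mean_considerate[cons$removed == "shock" &
                                       cons$trial_index == 10]
  t11_shock <- cons$mean_considerate[cons$removed == "shock" &
                                       cons$trial_index == 11]
  t10_money <- cons$mean_considerate[cons$removed == "money" &
                                       cons$trial_index == 10]
  t11_money <- cons$mean_considerate[cons$removed == "money" &
                                       cons$trial_index == 11]
  # removing the guiding outcome pulls choices toward chance...
  expect_gt(t10_shock, 0.8)
  expect_lt(t11_shock, 0.6)
  expect_gt(t11_shock, 0.35)
  # ...removing the other outcome leaves choices unchanged
  expect_lt(abs(t11_money - t10_money), 0.05)

  # chance agents sit at ~0.5 in every cell
  p0 <- model_params("M0", tau = 1)
  co0 <- simulate_cohort(rep(list(p0), 200), design_conflict_dropout(),
                         seed = 48)
  dv0 <- devaluation_summary(co0)
  amb <- dv0[dv0$label == "Ambiguous", ]
  expect_true(all(abs(amb$mean_considerate - 0.5) < 0.07))
})
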