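test_that("AICc follows the least-squares Gaussian identification", {
  expect_equal(aicc(0.5, 14, 4), 14 * log(0.5 / 14) + 8 + 40 / 9)
  expect_equal(aicc(0.5, 14, 4), -34.21, tolerance = 0.005)
  # penalty arithmetic: equal SSE, k = 3 vs k = 6 at n = 14 differ by 15.6
  expect_equal(aicc(1.3, 14, 6) - aicc(1.3, 14, 3), 15.6)
  # scaling SSE by e adds exactly n
  expect_equal(aicc(exp(1) * 0.7, 14, 4) - aicc(0.7, 14, 4), 14)
  # penalty strictly increases with k at fixed SSE and n
  pen <- vapply(1:6, function(k) aicc(1, 14, k), numeric(1))
  expect_true(all(diff(pen) > 0))
  expect_error(aicc(1, 5, 4), "n_points > k")
  expect_error(aicc(-1, 14, 3), "sse")
})

test_that("objective is a deterministic quadratic form under frozen noise", {
  d <- tiny_cohort(seed = 2, trials = 80)
  p <- pack_params(default_truth())
  s1 <- objective_sse(p, "RL", d, n_trials = 300, seed = 5)
  s2 <- objective_sse(p, "RL", d, n_trials = 300, seed = 5)
  expect_identical(s1, s2)   # common random numbers: bit-identical
  # perturbing one observed d' changes the SSE quadratically:
  # SSE(+delta) + SSE(-delta) - 2 SSE(0) = 2 delta^2 per affected observer
  delta <- 0.25
  perturb <- function(dd, delta) {
    i <- which(dd$observer_id == dd$observer_id[1] &
                 dd$session_label == "D1")
    dd$dprime[i] <- dd$dprime[i] + delta
    dd
  }
  n_in_group <- length(unique(d$observer_id[d$group == d$group[1]]))
  sp <- objective_sse(p, "RL", perturb(d, delta), n_trials = 300, seed = 5)
  sm <- objective_sse(p, "RL", perturb(d, -delta), n_trials = 300, seed = 5)
  expect_equal(sp + sm - 2 * s1, 2 * (delta / n_in_group)^2,
               tolerance = 1e-10)
  expect_error(objective_sse(p, "RL", d, sessions = c("D1", "D9"),
                             n_trials = 300, seed = 5), "absent")
})

test_that("model d-prime reflects the learned reliabilities", {
  # static model: no learning means flat sessions (up to sampling error)
  p0 <- variant_params("RL", 5, 7, rates = c(tau_target = 0,
                                             tau_distractor = 0))
  d1 <- model_dprime(p0, "oblique", 1, n_trials = 4000, seed = 8)
  d6 <- model_dprime(p0, "oblique", 6, n_trials = 4000, seed = 9)
  expect_lt(abs(d1 - d6), 0.2)
  # baseline search asymmetry under orientation-dependent reliability
  pR <- variant_params("R", 5, 10, rates = c(tau = 0.4))
  nc <- model_dprime(pR, "near-cardinal", 1, n_trials = 8000, seed = 10)
  ob <- model_dprime(pR, "oblique", 1, n_trials = 8000, seed = 11)
  expect_gt(ob, nc)
  # Monte-Carlo consistency: repeated-estimate spread shrinks with trials
  reps <- function(n) vapply(1:8, function(i)
    model_dprime(p0, "oblique", 1, n_trials = n, seed = 100 + i), numeric(1))
  expect_lt(sd(reps(4500)), sd(reps(500)))
})

test_that("fitting recovers a self-consistent optimum reproducibly", {
  d <- tiny_cohort(seed = 3, trials = 100)
  f <- fit_search_model(d, "R", n_trials = 300, n_starts = 2, seed = 7,
                        control = list(maxit = 120))
  # internal consistency: stored SSE equals SSE of stored fitted values
  expect_equal(f$sse, sum((f$fitted - f$observed)^2), tolerance = 1e-12)
  expect_equal(f$aicc, aicc(f$sse, f$n_points, f$k))
  expect_identical(f$n_points, 14L)
  expect_identical(f$k, 3L)
  expect_true(f$sse <= min(f$starts$final_sse) + 1e-12)
  # bit-for-bit determinism given identical seed and inputs
  f2 <- fit_search_model(d, "R", n_trials = 300, n_starts = 2, seed = 7,
                         control = list(maxit = 120))
  expect_identical(coef(f), coef(f2))
  expect_identical(f$sse, f2$sse)
  expect_identical(f$starts, f2$starts)

  # a dataset whose group means equal the fitted trajectories gives SSE 0
  # under the same frozen noise (self-consistency of the objective)
  d0 <- mean_dataset(f$fitted)
  expect_equal(objective_sse(coef(f), "R", d0, n_trials = 300, seed = 7), 0,
               tolerance = 1e-20)
})

test_that("a zero-iteration budget returns the best start unchanged", {
  d <- tiny_cohort(seed = 4, trials = 80)
  f <- fit_search_model(d, "RL", n_trials = 200, n_starts = 3, seed = 13,
                        control = list(maxit = 0))
  starts <- as.matrix(f$starts[, 1:4])
  best <- f$best_start
  # rates below the log-transform floor are clamped to it
  expect_equal(unname(coef(f)), unname(pmax(starts[best, ], 1e-3)),
               tolerance = 1e-12)
  expect_equal(f$sse, min(f$starts$final_sse))
})

test_that("start sampling respects the documented ranges", {
  d <- tiny_cohort(seed = 5, trials = 80)
  f <- fit_search_model(d, "RL", n_trials = 200, n_starts = 25, seed = 17,
                        sigma_range = c(1, 50), tau_range = c(0, 2),
                        control = list(maxit = 0))
  sig_starts <- c(f$starts$start_sigma_cardinal, f$starts$start_sigma_oblique)
  tau_starts <- c(f$starts$start_tau_target, f$starts$start_tau_distractor)
  # sigma starts above 20 are capped: flat objective there (zero hit rates)
  expect_true(all(sig_starts >= 1 & sig_starts <= 20))
  expect_true(all(tau_starts >= 0 & tau_starts <= 2))
})

test_that("transfer prediction requires a training-only fit", {
  d <- tiny_cohort(seed = 6, trials = 80)
  f_all <- fit_search_model(d, "R", n_trials = 200, n_starts = 1, seed = 1,
                            control = list(maxit = 30))
  expect_error(predict_transfer(f_all), "training")
  f_tr <- fit_search_model(d, "R", sessions = "training", n_trials = 200,
                           n_starts = 1, seed = 1,
                           control = list(maxit = 30))
  expect_false("OrTest" %in% f_tr$sessions_used)
  expect_identical(f_tr$n_points, 12L)
  pred <- predict_transfer(f_tr)
  expect_named(pred, c("near-cardinal", "oblique"))
  expect_true(all(is.finite(pred)))
})

test_that("no-learning truth makes test performance mirror the other group's baseline", {
  # tau = 0 everywhere: the orientation test is exactly the other group's
  # day-1 arrangement, so predicted test d' equals that baseline
  p0 <- variant_params("RL", 5, 8, rates = c(tau_target = 0,
                                             tau_distractor = 0))
  test_nc <- model_dprime(p0, "near-cardinal", phase = "orientation-test",
                          n_trials = 20000, seed = 41)
  base_ob <- model_dprime(p0, "oblique", 1, n_trials = 20000, seed = 42)
  expect_equal(test_nc, base_ob, tolerance = 0.1)
})
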