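test_that("learning curve has the right endpoints and shape", {
  expect_equal(uncertainty_at(5, 0.65, 0), 10)
  expect_equal(uncertainty_at(5, 0.65, 1), 5 * (1 + exp(-0.65)))
  expect_equal(uncertainty_at(5, 0.65, 1), 7.610, tolerance = 1e-3)
  # strictly decreasing towards the asymptote, bounded in (sigma0, 2*sigma0]
  v <- uncertainty_at(5, 0.65, 0:30)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 5 & v <= 10))
  expect_equal(uncertainty_at(5, 0.65, 1e6), 5)
  # tau = 0: no learning
  expect_equal(uncertainty_at(3, 0, c(0, 5, 50)), rep(6, 3))
  expect_error(uncertainty_at(5, 0.65, -1), "t")
  expect_error(uncertainty_at(-5, 0.65, 1), "sigma0")
})

test_that("role mapping assigns orientations to roles by group", {
  expect_identical(role_mapping("near-cardinal"),
                   c(sigma_target = "cardinal", sigma_distractor = "oblique"))
  expect_identical(role_mapping("oblique"),
                   c(sigma_target = "oblique", sigma_distractor = "cardinal"))
  # the two assignments are transposes of each other
  nc <- role_mapping("near-cardinal"); ob <- role_mapping("oblique")
  expect_identical(unname(nc), unname(rev(ob)))
  expect_error(role_mapping("diagonal"), "group")
})

test_that("variant parameter sets enforce their structure", {
  expect_identical(n_free_params("R"), 3L)
  expect_identical(n_free_params("L"), 3L)
  expect_identical(n_free_params("RL"), 4L)
  expect_identical(n_free_params("RLG"), 6L)
  expect_error(variant_params("R", 5, 8, rates = c(tau_target = 1)), "tau")
  expect_error(variant_params("L", 5, 8, rates = c(tau_target = 1,
                                                   tau_distractor = 1)),
               "single initial uncertainty")
  expect_error(variant_params("RL", 5, 8, rates = c(tau_target = -0.1,
                                                    tau_distractor = 1)),
               ">= 0")
})

test_that("pack/unpack is a length-checked round trip for every variant", {
  sets <- list(
    variant_params("R", 5, 8, rates = c(tau = 0.4)),
    variant_params("L", 6, rates = c(tau_target = 0.2, tau_distractor = 0.7)),
    variant_params("RL", 5.5, 6.9,
                   rates = c(tau_target = 0.24, tau_distractor = 0.65)),
    variant_params("RLG", 5, 8,
                   rates = c(tau_target_cardinal = 0.1,
                             tau_distractor_cardinal = 0.2,
                             tau_target_oblique = 0.3,
                             tau_distractor_oblique = 0.4)))
  lens <- c(3L, 3L, 4L, 6L)
  for (i in seq_along(sets)) {
    v <- pack_params(sets[[i]])
    expect_length(v, lens[i])
    expect_equal(unpack_params(v, sets[[i]]$variant), sets[[i]])
  }
  expect_error(unpack_params(rep(1, 5), "RLG"), "length 6")
})

test_that("session reliabilities follow the learning rules per variant", {
  # shared rate (R): both roles shrink by the identical factor day 1 -> 6
  pR <- variant_params("R", 5, 8, rates = c(tau = 0.5))
  r1 <- session_reliabilities(pR, "near-cardinal", 1)
  r6 <- session_reliabilities(pR, "near-cardinal", 6)
  shrink <- (1 + exp(-0.5 * 5)) / (1 + exp(-0.5 * 0))
  expect_equal(r6$sigma_target / r1$sigma_target, shrink)
  expect_equal(r6$sigma_distractor / r1$sigma_distractor, shrink)
  # R: the oblique/cardinal ratio is constant across sessions
  rats <- vapply(1:6, function(s) {
    r <- session_reliabilities(pR, "near-cardinal", s)
    r$sigma_distractor / r$sigma_target
  }, numeric(1))
  expect_equal(rats, rep(8 / 5, 6))

  # L: day-1 uncertainties equal for the two orientations
  pL <- variant_params("L", 6, rates = c(tau_target = 0.2,
                                         tau_distractor = 0.7))
  rL <- session_reliabilities(pL, "oblique", 1)
  expect_equal(rL$sigma_target, rL$sigma_distractor)

  # RL, near-cardinal group, orientation test: the new target is the oblique
  # orientation with its day-6 value learned at the distractor rate
  pRL <- default_truth()
  rt <- session_reliabilities(pRL, "near-cardinal",
                              phase = "orientation-test")
  expect_equal(rt$sigma_target, 6.9 * (1 + exp(-0.65 * 5)))
  expect_equal(rt$sigma_distractor, 5.5 * (1 + exp(-0.24 * 5)))

  # RLG rates attach to role-by-orientation, independent across groups
  pG <- variant_params("RLG", 5, 8,
                       rates = c(tau_target_cardinal = 0.1,
                                 tau_distractor_cardinal = 0.2,
                                 tau_target_oblique = 0.3,
                                 tau_distractor_oblique = 0.4))
  r_nc <- session_reliabilities(pG, "near-cardinal", 3)
  expect_equal(r_nc$sigma_target, 5 * (1 + exp(-0.1 * 2)))
  expect_equal(r_nc$sigma_distractor, 8 * (1 + exp(-0.4 * 2)))
  r_ob <- session_reliabilities(pG, "oblique", 3)
  expect_equal(r_ob$sigma_target, 8 * (1 + exp(-0.3 * 2)))
  expect_equal(r_ob$sigma_distractor, 5 * (1 + exp(-0.2 * 2)))

  # all-zero rates: constant reliabilities in every session and at test
  p0 <- variant_params("RL", 5, 8, rates = c(tau_target = 0,
                                             tau_distractor = 0))
  for (s in c(1, 4, 6)) {
    r <- session_reliabilities(p0, "oblique", s)
    expect_equal(c(r$sigma_target, r$sigma_distractor), c(16, 10))
  }
  expect_error(session_reliabilities(pRL, "near-cardinal", 7), "1..6")
})

test_that("uncertainties stay within the learning-curve band everywhere", {
  p <- default_truth()
  for (g in c("near-cardinal", "oblique")) {
    traj <- sigma_trajectories(p, g)
    expect_true(all(traj$sigma_target > 5.5 - 1e-12))
    expect_true(all(traj$sigma_target <= 2 * 6.9 + 1e-12))
    expect_true(all(traj$sigma_distractor <= 2 * 6.9 + 1e-12))
    expect_identical(traj$session_label, c(paste0("D", 1:6), "OrTest"))
  }
})

test_that("faster distractor learning closes the gap in the near-cardinal group", {
  # the transfer-asymmetry mechanism: with tau_D > tau_T and
  # sigma_oblique > sigma_cardinal, the between-orientation gap shrinks
  # faster when the oblique orientation is the (fast-learning) distractor
  p <- default_truth()
  gap <- function(group, s) {
    r <- session_reliabilities(p, group, s)
    abs(r$sigma_target - r$sigma_distractor)
  }
  closed_nc <- gap("near-cardinal", 1) - gap("near-cardinal", 6)
  closed_ob <- gap("oblique", 1) - gap("oblique", 6)
  expect_gt(closed_nc, closed_ob)
})
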