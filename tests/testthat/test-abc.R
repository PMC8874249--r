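# toy simulator: summary = dose * k with slope k in [1, 2]
toy_sim <- function(draw) draw[["PORALDOSE"]] * draw[["k"]]
toy_ranges <- tibble::tibble(parameter = "k", lower = 1, upper = 2)

# brute-force grid sample from the toy conditional given the tolerance band
toy_grid <- function(tol) {
  g <- expand.grid(d = seq(0.2, 1.5, length.out = 2000),
                   k = seq(1, 2, length.out = 1500))
  g$d[abs(g$d * g$k - 1) <= tol]
}

test_that("response preprocessing follows the published transforms", {
  expect_equal(preprocess_response(2.711, "log2_fold_induction"), 6.55,
               tolerance = 1e-3)
  expect_equal(preprocess_response(-0.050, "log2_fold_induction"), 0.966,
               tolerance = 1e-3)
  expect_equal(preprocess_response(c(-6.989, 26.914), "percentage_activity"),
               c(1.00, 27.914))
  # flagged anomalies are clamped before the +1 shift
  expect_equal(preprocess_response(c(2.33, -0.599, 3.617),
                                   "percentage_activity",
                                   anomalies = c(1, 3)),
               c(1, 1, 1))
  expect_error(preprocess_response(1, "fold_change"), "arg")
})

test_that("the matched summary behaves at its edges", {
  sim <- quick_sim(dose = dose_event(0), duration = 6, step = 0.05)
  expect_equal(match_summary(sim, "CVli"), 0)
  # a constant synthetic tissue series returns that constant either way
  fake <- list(times = seq(0, 3, 0.1),
               series = tibble::tibble(time = seq(0, 3, 0.1), CVli = 2),
               dose = dose_event(1))
  expect_equal(match_summary(fake, "CVli", "peak", c(0, 3)), 2)
  expect_equal(match_summary(fake, "CVli", "auc_mean", c(0, 3)), 2,
               tolerance = 1e-12)
})

test_that("the tissue summary is non-decreasing in dose", {
  cfg <- abc_config(statistic = "peak", window = c(0, 8))
  fn <- pbk_summary_fn(cfg, step = 0.05)
  doses <- c(1, 5, 20, 100, 500)
  vals <- vapply(doses, function(d) fn(c(PORALDOSE = d)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("rejection phase retains exactly the in-band draws", {
  cfg <- abc_config(phase1_n = 3000, phase2_iters = 100, seed = 7)
  ph1 <- rejection_phase(toy_sim, 1, toy_ranges, c(0.2, 1.5), cfg)
  # definitional re-check of the band
  expect_true(all(abs(ph1$retained$summary - 1) <= 0.075))
  recomputed <- ph1$retained$PORALDOSE * ph1$retained$k
  expect_equal(recomputed, ph1$retained$summary, tolerance = 1e-12)
  # acceptance fraction matches the brute-force band area
  g <- expand.grid(d = seq(0.2, 1.5, length.out = 1000),
                   k = seq(1, 2, length.out = 1000))
  area <- mean(abs(g$d * g$k - 1) <= 0.075)
  expect_lt(abs(ph1$acceptance - area), 0.02)
  expect_error(rejection_phase(toy_sim, 0, toy_ranges, c(0.2, 1.5), cfg),
               "target")
  expect_error(rejection_phase(toy_sim, 50, toy_ranges, c(0.2, 1.5), cfg),
               "bracketing")
})

test_that("ABC MCMC matches the brute-force conditional distribution", {
  cfg <- abc_config(phase1_n = 4000, phase2_chains = 4, phase2_iters = 4000,
                    seed = 7)
  ph1 <- rejection_phase(toy_sim, 1, toy_ranges, c(0.2, 1.5), cfg)
  post <- abc_mcmc(toy_sim, 1, ph1, toy_ranges, c(0.2, 1.5), cfg)
  # every pooled sample is inside the 5% band
  s <- post$samples$PORALDOSE * post$samples$k
  expect_true(all(abs(s - 1) / 1 <= 0.05))
  # distributional agreement with the grid oracle
  oracle <- toy_grid(0.05)
  ks <- suppressWarnings(stats::ks.test(post$samples$PORALDOSE, oracle))
  expect_lt(unname(ks$statistic), 0.05)
  # phase-1-only and two-phase means agree within Monte-Carlo error
  ph1_tight <- rejection_phase(toy_sim, 1, toy_ranges, c(0.2, 1.5),
                               abc_config(phase1_n = 4000,
                                          phase1_tol = 0.05,
                                          phase2_tol = 0.03,
                                          phase2_iters = 100, seed = 11))
  expect_equal(post$mean, mean(ph1_tight$retained$PORALDOSE),
               tolerance = 0.03)
  # plausible acceptance rates
  expect_true(all(post$acceptance_phase2 > 0.01 &
                    post$acceptance_phase2 < 0.6))
  expect_equal(tidy(post)$mean, post$mean)
})

test_that("dose bracketing finds a range containing the matching dose", {
  rng <- bracket_dose(toy_sim, 1, toy_ranges, dose_limits = c(1e-3, 1e3))
  # true matching doses lie in [1/2, 1/0.925]
  expect_lt(rng[1], 0.5)
  expect_gt(rng[2], 1.1)
  expect_error(bracket_dose(toy_sim, 1e9, toy_ranges,
                            dose_limits = c(1e-3, 1e3)), "bracketing")
})

test_that("dose-response assembly is order-invariant and aligned", {
  post <- tibble::tibble(free_conc = c(0.3, 0.1, 0.2),
                         mean = c(3, 1, 2), q2.5 = c(2, 0.5, 1),
                         q97.5 = c(4, 1.5, 3))
  resp <- c(30, 10, 20)
  out <- assemble_dose_response(post, resp)
  expect_equal(nrow(out), 9)
  m <- out[out$set == "mean", ]
  expect_equal(m$dose, c(1, 2, 3))
  expect_equal(m$response, c(10, 20, 30))
  # shuffling rows jointly leaves the output unchanged
  idx <- c(2, 3, 1)
  out2 <- assemble_dose_response(post[idx, ], resp[idx])
  expect_equal(out2, out)
  # single concentration
  one <- assemble_dose_response(post[1, ], resp[1])
  expect_equal(nrow(one), 3)
  expect_error(assemble_dose_response(post, resp[1:2]), "alignment")
})
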