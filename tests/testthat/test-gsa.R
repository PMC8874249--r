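test_that("Morris screening ranks an additive model correctly", {
  fn <- function(p) 10 * p[["a"]] + 1 * p[["b"]] + 0 * p[["c"]]
  rk <- morris_rank(fn, list(a = c(0, 1), b = c(0, 1), c = c(0, 1)),
                    trajectories = 10, repeats = 3, seed = 1)
  expect_equal(rk$parameter, c("a", "b", "c"))
  expect_equal(rk$mu_star, c(10, 1, 0), tolerance = 1e-9)
  # a parameter absent from the model has zero elementary effect
  expect_equal(rk$mu_star[rk$parameter == "c"], 0)
})

test_that("the modal Morris ranking is stable across seeds", {
  fn <- function(p) 5 * p[["a"]]^2 + 2 * p[["b"]] + 0.1 * p[["c"]]
  ranges <- list(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  r1 <- morris_rank(fn, ranges, trajectories = 20, repeats = 6, seed = 1)
  r2 <- morris_rank(fn, ranges, trajectories = 20, repeats = 6, seed = 99)
  expect_equal(r1$parameter, r2$parameter)
})

test_that("eFAST reproduces the closed-form Ishigami decomposition", {
  truth <- ishigami_indices()
  r <- efast(ishigami, ishigami_ranges, samples_per_param = 1025,
             resamples = 2, seed = 2)
  got_sm <- setNames(r$S_M, r$parameter)[names(truth$S_M)]
  got_st <- setNames(r$S_T, r$parameter)[names(truth$S_T)]
  expect_lt(max(abs(got_sm - truth$S_M)), 0.05)
  expect_lt(max(abs(got_st - truth$S_T)), 0.06)
  # index-ordering invariants
  expect_true(all(r$S_T >= r$S_M - 0.01))
  expect_lte(sum(r$S_M), 1.05)
})

test_that("eFAST matches analytic variance shares on a linear model", {
  fn <- function(p) 3 * p[["a"]] + 1 * p[["b"]]
  r <- efast(fn, list(a = c(0, 1), b = c(0, 1)), samples_per_param = 513,
             resamples = 2, seed = 1)
  expect_equal(r$S_M[r$parameter == "a"], 9 / 10, tolerance = 0.03)
  expect_equal(r$S_M[r$parameter == "b"], 1 / 10, tolerance = 0.03)
})

test_that("an output independent of a parameter has negligible S_T", {
  fn <- function(p) sin(p[["a"]]) + 0 * p[["x"]]
  r <- efast(fn, list(a = c(-1, 1), x = c(0, 1)), samples_per_param = 513,
             resamples = 2, seed = 1)
  expect_lte(r$S_T[r$parameter == "x"], 0.02)
})

test_that("a constant output is flagged degenerate with zero indices", {
  fn <- function(p) 42
  r <- efast(fn, list(a = c(0, 1), b = c(0, 1)), samples_per_param = 129,
             seed = 1)
  expect_true(all(r$degenerate))
  expect_true(all(r$S_M == 0 & r$S_T == 0))
})

test_that("eFAST handles vector outputs with smoothly varying indices", {
  # linear blend: influence of a decreases, b increases along the output
  fn <- function(p) {
    w <- c(0.9, 0.7, 0.5, 0.3, 0.1)
    setNames(w * p[["a"]] + (1 - w) * p[["b"]], paste0("t", 1:5))
  }
  r <- efast(fn, list(a = c(0, 1), b = c(0, 1)), samples_per_param = 257,
             resamples = 2, seed = 1)
  sa <- r$S_M[r$parameter == "a"]
  expect_true(all(diff(sa) < 0))
  expect_true(all(abs(diff(sa)) < 0.5))
})

test_that("Lowry ribbon bounds behave for additive and interacting models", {
  # purely additive: S_M = S_T so the ribbon collapses
  res <- tibble::tibble(parameter = c("a", "b"), S_M = c(0.7, 0.3),
                        S_T = c(0.7, 0.3))
  rb <- lowry_bounds(res)
  expect_equal(rb$lower, rb$upper)
  expect_true(all(rb$lower >= 0 & rb$upper <= 1))
  expect_true(all(diff(rb$lower) >= 0) && all(diff(rb$upper) >= 0))

  # pure interaction y = a * b on [0,1]^2: analytic decomposition gives
  # S1 = S2 = 3/7 and an interaction share of 1/7
  r <- efast(function(p) p[["a"]] * p[["b"]],
             list(a = c(0, 1), b = c(0, 1)), samples_per_param = 513,
             resamples = 4, seed = 3)
  rb2 <- lowry_bounds(r)
  width <- rb2$upper[2] - rb2$lower[2]
  expect_equal(width, 1 / 7, tolerance = 0.05)
  expect_true(all(rb2$upper >= rb2$lower))

  expect_s3_class(plot_lowry(r), "ggplot")
})

test_that("posterior ranges combine global, individual and prior sources", {
  rng <- posterior_ranges(c("KM_liv_BPA_in_vitro", "MPY", "VspdC"))
  # global: the calibrated 95% interval
  expect_equal(unlist(rng[rng$parameter == "KM_liv_BPA_in_vitro",
                          c("lower", "upper")]),
               c(lower = 0.75, upper = 2.44))
  # individual-scope: min/max over the 14 volunteers
  expect_equal(unlist(rng[rng$parameter == "MPY", c("lower", "upper")]),
               c(lower = 14.0, upper = 53.7))
  # uncalibrated: prior bounds
  expect_equal(unlist(rng[rng$parameter == "VspdC", c("lower", "upper")]),
               c(lower = 0.45, upper = 0.75))
  expect_error(posterior_ranges("NOT_A_PARAM"), "NOT_A_PARAM")
})
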