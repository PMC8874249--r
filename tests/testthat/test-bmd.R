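test_that("dose-response validation enforces its invariants", {
  expect_error(dose_response_set(c(0, 1, 2), c(1, 2, 3)), "length|distinct")
  expect_error(dose_response_set(c(0, 1, 2, 3), c(1, 2, 3, -1)), "> 0")
  expect_error(dose_response_set(c(-1, 1, 2, 3), rep(1, 4)), ">= 0")
  expect_s3_class(dose_response_set(c(0, 1, 2, 3), c(1, 1, 2, 3)),
                  "dose_response_set")
})

test_that("a generating exponential model is recovered from clean data", {
  set.seed(9)
  x <- rep(c(1, 3, 10, 30, 100, 300, 600, 1000), len = 50)
  th <- c(a = 2, b = 0.003, d = 1)
  y <- exp(rnorm(50, log(th["a"] * exp(th["b"] * x^th["d"])), 0.02))
  fits <- fit_model_family(dose_response_set(x, y))
  got <- fits$theta[[which(fits$model == "exp3")]]
  expect_equal(got[1], th[["a"]], tolerance = 0.1)
  expect_equal(got[2] * mean(x)^got[3] / (th[["b"]] * mean(x)),
               1, tolerance = 0.1)  # b and d jointly identified
  expect_true(all(fits$converged))
})

test_that("a flat response is flagged and yields no BMD", {
  flat <- dose_response_set(c(1, 10, 100, 1000), rep(2, 4))
  fits <- fit_model_family(flat)
  expect_true(isTRUE(attr(fits, "flat")))
  expect_error(bmd_at_bmr(fits), "flat")
})

test_that("Hill-generated data favour the Hill family", {
  # near-noiseless data from the 5-parameter Hill form: its own family must
  # fit (essentially) exactly, the exponential family only approximately
  dr <- hill_data(top = 4, h = 2, sigma = 1e-3)
  fits <- fit_model_family(dr)
  ll <- setNames(fits$loglik, fits$model)
  expect_gte(max(ll[c("hill3", "hill5")]), max(ll[c("exp3", "exp5")]))
})

test_that("per-family BMD solutions match their closed forms", {
  fams <- bmd_families()
  # hill3 with b = 5, d = 1: BMD = 5 * (0.1/0.9)
  expect_equal(fams$hill3$bmd(c(1, 5, 1), 0.1), 5 / 9, tolerance = 1e-12)
  # exp3 with b, d: BMD = (log(1.1)/b)^(1/d)
  expect_equal(fams$exp3$bmd(c(2, 0.01, 1), 0.1), log(1.1) / 0.01,
               tolerance = 1e-12)
  # exp5/hill5 plateaus below the BMR give no finite BMD
  expect_true(is.na(fams$exp5$bmd(c(1, 1, 0.05, 1), 0.1)))
  expect_true(is.na(fams$hill5$bmd(c(1, 1, 0.05, 1), 0.1)))
})

test_that("Akaike averaging weights behave in the edge cases", {
  fams <- bmd_families()
  fits <- tibble::tibble(
    model = c("exp3", "hill3"),
    converged = c(TRUE, TRUE),
    loglik = c(0, 0), k = c(4, 4), sigma = c(0.1, 0.1),
    theta = list(c(1, 0.01, 1), c(1, 5, 1)),
    aic = c(8, 8)
  )
  attr(fits, "flat") <- FALSE
  out <- bmd_at_bmr(fits, 0.1)
  b1 <- fams$exp3$bmd(c(1, 0.01, 1), 0.1)
  b2 <- fams$hill3$bmd(c(1, 5, 1), 0.1)
  # equal AIC -> equal weights -> arithmetic mean
  expect_equal(out$by_model$weight, c(0.5, 0.5))
  expect_equal(out$bmd, (b1 + b2) / 2, tolerance = 1e-12)
  # a single converged family carries all the weight
  fits$converged[2] <- FALSE
  out1 <- bmd_at_bmr(fits, 0.1)
  expect_equal(out1$bmd, b1, tolerance = 1e-12)
  expect_equal(out1$by_model$weight, c(1, 0))
})

test_that("bootstrap limits bracket the BMD and shrink with noise", {
  dr <- hill_data(sigma = 0.1)
  res <- bootstrap_bmdl(dr, replicates = 300, seed = 1)
  expect_true(res$bmdl10 <= res$bmd && res$bmd <= res$bmdu10)
  expect_s3_class(glance(res), "tbl_df")

  # near-zero noise collapses the bootstrap interval onto the BMD
  quiet <- hill_data(sigma = 1e-4, seed = 7)
  resq <- bootstrap_bmdl(quiet, replicates = 200, seed = 1)
  expect_lt((resq$bmdu10 - resq$bmdl10) / resq$bmd, 0.02)
})

test_that("the averaged BMD is close to truth and scale-equivariant", {
  # truth: Hill with a = 1, top = 5, ac50 = 100, h = 1.5; the dose giving a
  # 10% rise in the median solves 5 x^h/(ac50^h + x^h) = 0.1
  true_bmd <- 100 * (0.1 / 5 / (1 - 0.1 / 5))^(1 / 1.5)
  dr <- hill_data(sigma = 0.1, seed = 3)
  res <- bootstrap_bmdl(dr, replicates = 200, seed = 1)
  expect_lt(abs(res$bmd - true_bmd) / true_bmd, 0.15)

  dr10 <- dose_response_set(dr$dose * 10, dr$response)
  res10 <- bootstrap_bmdl(dr10, replicates = 200, seed = 1)
  expect_equal(res10$bmd / res$bmd, 10, tolerance = 0.02)
  expect_equal(res10$bmdl10 / res$bmdl10, 10, tolerance = 0.05)
})

test_that("bootstrap BMDL is stable across seeds", {
  dr <- hill_data(sigma = 0.1, seed = 3)
  r1 <- bootstrap_bmdl(dr, replicates = 1000, seed = 1)
  r2 <- bootstrap_bmdl(dr, replicates = 1000, seed = 2)
  expect_lt(abs(r1$bmdl10 - r2$bmdl10) / r1$bmdl10, 0.05)
})

test_that("CSAF and HED arithmetic reproduce the worked examples", {
  expect_equal(apply_csaf(1300, 2.52), 516, tolerance = 1e-3)
  expect_equal(apply_csaf(960, 2.52), 381, tolerance = 1e-3)
  expect_equal(apply_csaf(42, 1), 42)
  expect_error(apply_csaf(100, 0.5), ">= 1")

  ht <- hed_and_tdi(8960, 0.068, 150)
  expect_equal(ht$hed, 609, tolerance = 1e-3)
  expect_equal(ht$tdi, 4, tolerance = 0.02)
  expect_equal(ht$hed / 150, 609.28 / 150, tolerance = 1e-3)
  ident <- hed_and_tdi(5, 1, 1)
  expect_equal(unlist(ident), c(hed = 5, tdi = 5))
  expect_error(hed_and_tdi(-1, 1, 1), "> 0")
})
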