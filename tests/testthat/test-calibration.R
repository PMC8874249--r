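# analytic one-compartment predictor used as a fast stand-in for the PBK model
toy_predictor <- function(params, obs) {
  10 * exp(-params[["K1Lymph"]] * obs$time)
}

toy_data <- function(kel = 0.5, sigma = 0, seed = 5) {
  set.seed(seed)
  d <- tidyr::crossing(individual = 1, time = c(1, 2, 4, 8),
                       analyte = c("BPA", "BPAG", "BPAS"))
  d$conc <- 10 * exp(-kel * d$time) + rnorm(nrow(d), 0, sigma)
  d
}

test_that("the Gaussian log-likelihood matches its closed form", {
  d <- toy_data(sigma = 0)
  sig <- c(BPA = 1, BPAG = 1, BPAS = 1)
  ll <- hbm_log_likelihood(c(K1Lymph = 0.5), list(), sig, d,
                           predictor = toy_predictor)
  expect_equal(ll, -nrow(d) / 2 * log(2 * pi), tolerance = 1e-12)
})

test_that("log-likelihood decreases when residuals grow, invariant to order", {
  d <- toy_data(sigma = 0.3)
  sig <- c(BPA = 0.5, BPAG = 0.5, BPAS = 0.5)
  ll1 <- hbm_log_likelihood(c(K1Lymph = 0.5), list(), sig, d,
                            predictor = toy_predictor)
  # doubling every residual strictly lowers the likelihood
  d2 <- d
  pred <- toy_predictor(c(K1Lymph = 0.5), d)
  d2$conc <- pred + 2 * (d$conc - pred)
  ll2 <- hbm_log_likelihood(c(K1Lymph = 0.5), list(), sig, d2,
                            predictor = toy_predictor)
  expect_lt(ll2, ll1)
  # permutation invariance
  perm <- d[sample.int(nrow(d)), ]
  llp <- hbm_log_likelihood(c(K1Lymph = 0.5), list(), sig, perm,
                            predictor = toy_predictor)
  expect_equal(llp, ll1, tolerance = 1e-12)
  # independent spreadsheet-style evaluation: explicit sum of densities
  by_hand <- sum(dnorm(d$conc, pred, 0.5, log = TRUE))
  expect_equal(ll1, by_hand, tolerance = 1e-10)
})

test_that("posterior summaries have the right quantile behaviour", {
  fake_fit <- function(draws, labels = colnames(draws)) {
    structure(list(draws = list(draws),
                   param_table = tibble::tibble(parameter = labels,
                                                individual = NA_character_),
                   burn_in = 0, iterations = nrow(draws)),
              class = "pbk_mcmc")
  }
  const <- fake_fit(matrix(3.5, 100, 1, dimnames = list(NULL, "c")))
  s <- summarize_chains(const)
  expect_equal(unlist(s[, c("median", "q2.5", "q97.5")]),
               c(median = 3.5, q2.5 = 3.5, q97.5 = 3.5))

  set.seed(1)
  unif <- fake_fit(matrix(runif(1e5), ncol = 1, dimnames = list(NULL, "u")))
  s2 <- summarize_chains(unif)
  expect_lt(abs(s2$median - 0.5), 0.01)
  expect_lt(abs(s2$q2.5 - 0.025), 0.005)
  expect_lt(abs(s2$q97.5 - 0.975), 0.005)
  expect_true(s2$q2.5 <= s2$median && s2$median <= s2$q97.5)
  expect_error(summarize_chains(fake_fit(matrix(numeric(0), 0, 1,
                                                dimnames = list(NULL, "x")))),
               "empty")
})

test_that("CSAF is the 97.5% quantile to median ratio", {
  # printed posterior summary of the plasma-binding fraction
  expect_equal(csaf(median = 0.119, q97.5 = 0.300), 2.52, tolerance = 2e-3)
  expect_equal(csaf(rep(7, 100)), 1)
  set.seed(2)
  ln <- exp(rnorm(2e5, 0, 1))
  expect_equal(csaf(ln), exp(qnorm(0.975)), tolerance = 0.05)
  expect_error(csaf(median = 0, q97.5 = 1), "zero")
  expect_error(csaf(numeric(0)), "empty")
})

test_that("a prior-only run recovers the prior quantiles", {
  d <- toy_data()
  sp <- tibble::tibble(analyte = c("BPA", "BPAG", "BPAS"),
                       lower = 0.01, upper = 1)
  fit <- run_mcmc(d, "K1Lymph", sigma_priors = sp,
                  predictor = toy_predictor, chains = 2,
                  iterations = 2000, seed = 3, use_likelihood = FALSE)
  s <- summarize_chains(fit)
  row <- s[s$parameter == "K1Lymph", ]
  # uniform(0.262, 0.738) prior
  expect_lt(abs(row$median - 0.5), 0.02)
  expect_lt(abs(row$q2.5 - (0.262 + 0.025 * 0.476)), 0.02)
  expect_lt(abs(row$q97.5 - (0.738 - 0.025 * 0.476)), 0.02)
})

test_that("the sampler recovers a known rate and converges across chains", {
  d <- toy_data(kel = 0.5, sigma = 0.1)
  sp <- tibble::tibble(analyte = c("BPA", "BPAG", "BPAS"),
                       lower = 0.01, upper = 1)
  fit <- run_mcmc(d, "K1Lymph", sigma_priors = sp,
                  predictor = toy_predictor, chains = 2,
                  iterations = 500, seed = 2)
  s <- summarize_chains(fit)
  row <- s[s$parameter == "K1Lymph", ]
  expect_true(row$q2.5 <= 0.5 && 0.5 <= row$q97.5)
  expect_equal(row$median, 0.5, tolerance = 0.05)
  expect_lt(max(gelman_rubin(fit)$rhat), 1.1)
  gl <- glance(fit)
  expect_equal(gl$chains, 2)
})
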