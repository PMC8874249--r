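test_that("the virtual population reproduces the prior moments", {
  # marginal fidelity of the raw draws: truncated-normal mean of the liver
  # volume fraction within Monte-Carlo error of its prior mean
  set.seed(4)
  raw <- sample_priors(10000, parameters = "VliC")
  se <- sd(raw$VliC) / sqrt(nrow(raw))
  expect_lt(abs(mean(raw$VliC) - 0.035), 2 * se + 1e-4)

  pop <- sample_population(10000, seed = 4)
  # after mass-balance rescaling of overflowing draws the mean shifts by
  # at most ~2%
  expect_lt(abs(mean(pop$VliC) - 0.035), 0.002)
  # every row satisfies the parameter-set invariants
  flows <- rowSums(pop[, c("QhepartC", "QstC", "QguC", "QkiC", "QfaC",
                           "QspdC", "QrpdC")])
  expect_true(all(abs(flows - 1) < 1e-9))
  vols <- rowSums(pop[, c("VliC", "VstC", "VguC", "VkiC", "VlymphC",
                          "VfaC", "VspdC", "VrpdC", "VBldC")])
  expect_true(all(vols < 1))
  expect_true(all(pop$BW > 40 & pop$BW < 150))

  one <- sample_population(1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_silent(build_parameter_set(as.list(one[1, ])))
})

test_that("noiseless synthetic observations equal the model predictions", {
  spec <- synthetic_study_spec(n_individuals = 1,
                               sampling_times = c(0.5, 1, 2, 4),
                               sigma = c(BPA = 0, BPAG = 0, BPAS = 0),
                               seed = 2)
  out <- generate_hbm(spec, step = 0.05)
  sim <- simulate_pbk(build_parameter_set(as.list(out$parameters[1,
                        pbk_parameter_names()])),
                      dose_event(100), duration = 4.05, step = 0.05)
  for (an in c("BPA", "BPAG", "BPAS")) {
    obs <- out$data[out$data$analyte == an, ]
    pred <- approx(sim$series$time, sim$series[[paste0("plasma_", an)]],
                   xout = obs$time)$y
    expect_equal(obs$conc, pred, tolerance = 1e-4)
  }
})

test_that("a lymphatic individual shows the double peak; seeds reproduce", {
  spec <- synthetic_study_spec(n_individuals = 1,
                               sampling_times = c(seq(0.05, 2, 0.05),
                                                  seq(2.25, 12, 0.25)),
                               sigma = c(BPA = 0, BPAG = 0, BPAS = 0),
                               seed = 3)
  base <- default_parameters()
  base$FracDOSELymph <- 0.05
  base$Lymphlag <- 1.1
  out <- generate_hbm(spec, base = base, step = 0.01)
  curve <- out$data[out$data$analyte == "BPA", ]
  expect_gte(count_peaks(curve$conc, prominence = 0.005), 2)

  spec2 <- synthetic_study_spec(n_individuals = 3, seed = 17,
                                true_parameters = "sampled_from_priors")
  a <- generate_hbm(spec2, step = 0.1)
  b <- generate_hbm(spec2, step = 0.1)
  expect_identical(a$data, b$data)
  expect_identical(a$parameters, b$parameters)
})

test_that("assay generation satisfies the half-maximal definition", {
  spec <- synthetic_assay_spec(ac50 = 0.5, top = 8, hill_slope = 1.3,
                               concentrations = c(0.05, 0.16, 0.5, 1.6, 5,
                                                  16, 50),
                               sigma = 0,
                               response_type = "percentage_activity")
  tab <- generate_assay(spec)
  expect_equal(tab$response[tab$conc_um == 0.5], 4)

  # log2 fold-induction encoding: natural scale recovers top/2 at the AC50
  spec2 <- synthetic_assay_spec(ac50 = 0.5, top = 8, sigma = 0,
                                concentrations = spec$concentrations,
                                response_type = "log2_fold_induction")
  tab2 <- generate_assay(spec2)
  expect_equal(2^tab2$response[tab2$conc_um == 0.5] - 1, 4,
               tolerance = 1e-9)

  # round-trip: refitting the Hill model recovers the AC50 within 1%
  fit <- fit_hill(tab)
  expect_equal(unname(fit["ac50"]), 0.5, tolerance = 0.01)

  nine <- generate_assay(synthetic_assay_spec(sigma = 0))
  expect_equal(nrow(nine), 9)
})
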