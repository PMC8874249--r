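test_that("packaged assay fixtures read back with the published shapes", {
  path <- system.file("extdata", "assays_bpa.csv", package = "qivive")
  tab <- read_assay_csv(path)
  expect_equal(sum(tab$assay == "ATG_ERE_CIS_up"), 9)
  expect_equal(sum(tab$assay == "ATG_PXR_TRANS_up"), 9)
  expect_equal(sum(tab$assay == "OT_ER_ERaERb_0480"), 18)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_assay_csv(empty), "lacks column|parse")
  expect_error(read_assay_csv("no/such/file.csv"), "no such file")
})

test_that("write/read round trip is the identity", {
  tab <- bpa_assays()
  dir <- withr::local_tempdir()
  paths <- write_results(list(assays = tab), dir)
  back <- read_assay_csv(file.path(dir, "assays.csv"))
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("HBM CSV validation catches schema problems", {
  dir <- withr::local_tempdir()
  d <- tibble::tibble(individual = 1, time = c(1, 2), analyte = "BPA",
                      conc = c(0.5, 0.2))
  readr::write_csv(d, file.path(dir, "hbm.csv"))
  expect_equal(nrow(read_hbm_csv(file.path(dir, "hbm.csv"))), 2)
  d$time[1] <- -1
  readr::write_csv(d, file.path(dir, "bad.csv"))
  expect_error(read_hbm_csv(file.path(dir, "bad.csv")), ">= 0")
})

test_that("the pipeline runs its stages and is reproducible", {
  dir1 <- withr::local_tempdir()
  cfg <- run_config(stages = c("population", "vcba"), output_dir = dir1,
                    seed = 5, n_population = 20)
  suppressMessages(manifest <- run_pipeline(cfg))
  expect_equal(manifest$stage, c("population", "vcba"))
  expect_true(all(file.exists(file.path(dir1, c("population.csv",
                                                "free_concentrations.csv")))))
  free <- readr::read_csv(file.path(dir1, "free_concentrations.csv"),
                          show_col_types = FALSE)
  expect_true(all(free$ratio > 0.48 & free$ratio < 0.51))

  # deterministic stages reproduce byte-identical outputs under one seed
  dir2 <- withr::local_tempdir()
  cfg2 <- run_config(stages = c("population", "vcba"), output_dir = dir2,
                     seed = 5, n_population = 20)
  suppressMessages(run_pipeline(cfg2))
  for (f in c("population.csv", "free_concentrations.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("chains and dose posteriors persist with metadata sidecars", {
  dir <- withr::local_tempdir()
  fake_fit <- structure(list(
    draws = list(matrix(1:6 / 7, 3, 2, dimnames = list(NULL, c("a", "b"))),
                 matrix(6:1 / 7, 3, 2, dimnames = list(NULL, c("a", "b")))),
    param_table = tibble::tibble(parameter = c("a", "b"),
                                 individual = NA_character_),
    burn_in = 5, iterations = 3, seed = 9, use_likelihood = TRUE),
    class = "pbk_mcmc")
  paths <- write_mcmc_tsv(fake_fit, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(back$a, c(1, 2, 3) / 7)
  meta <- jsonlite::read_json(file.path(dir, "chains_meta.json"))
  expect_equal(meta$seed, 9)

  fake_post <- structure(list(target = 0.1, samples = tibble::tibble(),
                              mean = 2, q2.5 = 1, q97.5 = 3,
                              acceptance_phase1 = 0.1,
                              acceptance_phase2 = c(0.2, 0.3),
                              config = abc_config()),
                         class = "dose_posterior")
  p2 <- write_dose_posteriors(list(fake_post), file.path(dir, "pd.csv"))
  expect_true(all(file.exists(p2)))
  tab <- readr::read_csv(file.path(dir, "pd.csv"), show_col_types = FALSE)
  expect_equal(tab$mean, 2)
})
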