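#' Read a ToxCast-dashboard-style assay CSV
#'
#' @param path CSV with columns `conc_um` (uM), `response`, `response_type`
#'   (and optionally `assay`, `log10_conc_um`).
#' @return Validated assay tibble.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("conc_um", "response", "response_type")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("assay CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!tab$response_type %in% c("log2_fold_induction",
                                         "percentage_activity"))
  if (length(bad) > 0) {
    stop("unknown response_type in row(s): ", paste(bad, collapse = ", "))
  }
  tab
}

#' Read a long-format plasma biomonitoring CSV
#'
#' @param path CSV with columns `individual`, `time`, `analyte`, `conc`
#'   (and optionally `bw`, `dose`, `unit`).
#' @return Validated tibble.
#' @export
read_hbm_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("individual", "time", "analyte", "conc")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("HBM CSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(tab$time < 0) || any(tab$conc < 0)) {
    stop("times and concentrations must be >= 0")
  }
  tab
}

#' Write result tables
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a simulation as tab-separated values
#'
#' Time column plus the named output series, in TSV form.
#'
#' @param sim A `pbk_sim`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_sim_tsv <- function(sim, path) {
  readr::write_tsv(sim$series, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param stages Character vector of stages to run, in order, from
#'   `"population"`, `"calibration"`, `"gsa"`, `"vcba"`, `"abc"`, `"bmd"`.
#' @param output_dir Directory for stage outputs.
#' @param seed Master seed; each stage derives an independent stream.
#' @param n_population Virtual-population size.
#' @param assays Assay table ([bpa_assays()] layout).
#' @param calibration Settings list for [run_mcmc()] (`calibrate`,
#'   `iterations`, `chains`); `NULL` skips the stage even if listed.
#' @param gsa Settings list: `parameters` (ranges source), `samples`,
#'   `output`.
#' @param abc Settings list: an [abc_config()] plus `targets` (free
#'   concentrations, mg/L) and `ranges`.
#' @param bmd Settings list: `replicates`.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("population", "vcba", "gsa", "abc", "bmd"),
                       output_dir = tempfile("qivive-run-"), seed = 1,
                       n_population = 100, assays = bpa_assays(),
                       calibration = NULL,
                       gsa = list(samples = 129, output = "CVli"),
                       abc = list(config = abc_config(phase1_n = 200,
                                                      phase2_chains = 2,
                                                      phase2_iters = 200),
                                  targets = NULL),
                       bmd = list(replicates = 200)) {
  structure(list(stages = stages, output_dir = output_dir, seed = seed,
                 n_population = n_population, assays = assays,
                 calibration = calibration, gsa = gsa, abc = abc,
                 bmd = bmd),
            class = "run_config")
}

#' Run the QIVIVE pipeline
#'
#' Executes the enabled stages in order -- virtual population, calibration,
#' global sensitivity analysis, in vitro free-concentration estimation, ABC
#' reverse dosimetry and benchmark-dose estimation -- persisting each
#' stage's outputs as CSV and returning a manifest of what ran.
#'
#' Stage defaults here are sized for smoke runs; production settings are
#' passed through [run_config()].
#'
#' @param config A [run_config()].
#' @return Tibble manifest: one row per completed stage with its output
#'   paths, seed and runtime.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage_seed <- function(i) config$seed + 1000 * i
  log_line <- function(...) message("[qivive] ", ...)
  t_all <- Sys.time()
  state <- new.env()

  run_stage <- function(stage, i, fn) {
    t0 <- Sys.time()
    paths <- fn(stage_seed(i))
    manifest[[stage]] <<- tibble::tibble(
      stage = stage, seed = stage_seed(i),
      runtime_s = as.numeric(Sys.time() - t0, units = "secs"),
      outputs = paste(paths, collapse = ";"))
    log_line(stage, " done (", round(manifest[[stage]]$runtime_s, 1),
             " s)")
  }

  for (i in seq_along(config$stages)) {
    stage <- config$stages[i]
    switch(stage,
      population = run_stage(stage, i, function(sd) {
        pop <- sample_population(config$n_population, seed = sd)
        state$population <- pop
        write_results(list(population = pop), config$output_dir)
      }),
      calibration = {
        if (is.null(config$calibration)) {
          log_line("calibration: no settings supplied, skipped")
        } else {
          run_stage(stage, i, function(sd) {
            cal <- config$calibration
            fit <- run_mcmc(cal$data, cal$calibrate,
                            chains = cal$chains %||% 2,
                            iterations = cal$iterations %||% 200,
                            predictor = cal$predictor %||% pbk_predictor(),
                            seed = sd)
            state$calibration <- fit
            write_results(list(posterior = summarize_chains(fit)),
                          config$output_dir)
          })
        }
      },
      gsa = run_stage(stage, i, function(sd) {
        rk <- bpa_sensitivity_ranking()
        out <- config$gsa$output %||% "CVli"
        pars <- rk$parameter[rk$output == out]
        ranges <- posterior_ranges(pars)
        res <- efast(pbk_output_fn(out), ranges,
                     samples_per_param = config$gsa$samples %||% 129,
                     seed = sd)
        state$gsa <- res
        write_results(list(efast = res,
                           lowry = lowry_bounds(res)), config$output_dir)
      }),
      vcba = run_stage(stage, i, function(sd) {
        free <- dplyr::bind_rows(lapply(split(config$assays,
                                              config$assays$assay),
          function(tab) {
            setup <- assay_setup(
              if (grepl("^OT_", tab$assay[1])) "384-well" else "24-well")
            transform_assay_table(tab, bpa_physchem(), setup)
          }))
        state$free <- free
        write_results(list(free_concentrations = free), config$output_dir)
      }),
      abc = run_stage(stage, i, function(sd) {
        targets <- config$abc$targets
        if (is.null(targets)) {
          # default: the three lowest free concentrations of the first assay
          free <- state$free %||% transform_assay_table(config$assays)
          targets <- utils::head(sort(unique(free$free_mgl)), 3)
        }
        rk <- bpa_sensitivity_ranking()
        pars <- utils::head(rk$parameter[rk$output == "CVli"], 8)
        ranges <- config$abc$ranges %||% posterior_ranges(pars)
        cfg <- config$abc$config
        cfg$seed <- sd
        posts <- lapply(targets, reverse_dosimetry, ranges = ranges,
                        cfg = cfg)
        state$posteriors <- dplyr::bind_rows(lapply(posts, tidy))
        write_results(list(poraldose = state$posteriors),
                      config$output_dir)
      }),
      bmd = run_stage(stage, i, function(sd) {
        # consume either this run's ABC output or the packaged dose table
        if (!is.null(state$posteriors)) {
          post <- dplyr::rename(state$posteriors, free_conc = "target")
          free <- state$free %||% transform_assay_table(config$assays)
          resp <- free[match(round(post$free_conc, 6),
                             round(free$free_mgl, 6)), ]
          responses <- preprocess_response(resp$response,
                                           resp$response_type[1])
        } else {
          stop("bmd stage needs the abc stage (or packaged dose table)")
        }
        dr <- assemble_dose_response(post, responses)
        drm <- dr[dr$set == "mean", ]
        res <- tryCatch(
          bootstrap_bmdl(dose_response_set(drm$dose, drm$response),
                         replicates = config$bmd$replicates %||% 200,
                         seed = sd),
          error = function(e) e)
        if (inherits(res, "error")) {
          log_line("bmd: ", conditionMessage(res))
          tab <- tibble::tibble(note = conditionMessage(res))
        } else {
          state$bmd <- res
          tab <- glance(res)
        }
        write_results(list(bmd = tab), config$output_dir)
      }),
      stop("unknown stage: ", stage)
    )
  }
  out <- dplyr::bind_rows(manifest)
  log_line("pipeline finished in ",
           round(as.numeric(Sys.time() - t_all, units = "secs"), 1), " s")
  out
}

#' Persist MCMC chains as TSV with a metadata sidecar
#'
#' One TSV per chain (iteration column plus one column per monitored
#' component) and a JSON sidecar recording seed, iterations and burn-in.
#'
#' @param fit A `pbk_mcmc` object.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_mcmc_tsv <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in seq_along(fit$draws)) {
    p <- file.path(dir, sprintf("chain%02d.tsv", ch))
    d <- tibble::as_tibble(fit$draws[[ch]])
    d <- dplyr::bind_cols(tibble::tibble(iteration = seq_len(nrow(d))), d)
    readr::write_tsv(d, p)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, "chains_meta.json")
  jsonlite::write_json(list(seed = fit$seed, chains = length(fit$draws),
                            iterations = fit$iterations,
                            burn_in = fit$burn_in,
                            use_likelihood = fit$use_likelihood),
                       meta, auto_unbox = TRUE)
  invisible(c(paths, meta))
}

#' Write dose posteriors as CSV with a metadata sidecar
#'
#' One row per target free concentration (mean, 2.5% and 97.5% dose), with
#' seeds, tolerances and acceptance rates in a JSON sidecar.
#'
#' @param posteriors List of `dose_posterior` objects.
#' @param path Output CSV path; the sidecar gets extension `.meta.json`.
#' @return Invisibly, the written paths.
#' @export
write_dose_posteriors <- function(posteriors, path) {
  tab <- dplyr::bind_rows(lapply(posteriors, tidy))
  names(tab)[names(tab) == "target"] <- "free_conc_mgl"
  readr::write_csv(tab, path)
  meta <- sub("\\.csv$", ".meta.json", path)
  cfg <- posteriors[[1]]$config
  jsonlite::write_json(list(
    seed = cfg$seed, target_tissue = cfg$target_tissue,
    statistic = cfg$statistic,
    phase1_tol = cfg$phase1_tol, phase2_tol = cfg$phase2_tol,
    acceptance_phase1 = vapply(posteriors, `[[`, numeric(1),
                               "acceptance_phase1"),
    acceptance_phase2 = lapply(posteriors, `[[`, "acceptance_phase2")
  ), meta, auto_unbox = TRUE)
  invisible(c(path, meta))
}
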