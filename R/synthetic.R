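#' Sample a virtual population of parameter sets
#'
#' Draws body weight, fractional tissue volumes and fractional blood flows
#' from their prior families truncated at the tabulated bounds (a surrogate
#' for a virtual-population generator; organ-mass covariance is not
#' reproduced, draws are independent before renormalisation).  Every row is
#' passed through [build_parameter_set()], so flows are renormalised and all
#' mass-balance invariants hold; non-physiological parameters stay at their
#' defaults.
#'
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param priors Prior table.
#' @return Tibble with `n` rows and one column per model parameter (flows
#'   renormalised).
#' @export
sample_population <- function(n, seed = 1, priors = bpa_priors()) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  phys <- c("BW", .volume_params, "QCC", .flow_params)
  draws <- sample_priors(n, priors, parameters = phys)
  base <- default_parameters(priors)
  rows <- lapply(seq_len(n), function(i) {
    p <- base
    p[phys] <- as.list(unlist(draws[i, phys]))
    ps <- build_parameter_set(p, on_volume_overflow = "rescale")
    tibble::as_tibble(unclass(ps)[pbk_parameter_names()])
  })
  dplyr::bind_rows(rows)
}

#' Specification of a synthetic biomonitoring study
#'
#' The design emulated: `n_individuals` healthy volunteers each receiving a
#' single oral dose, with plasma BPA, BPAG and BPAS sampled on a grid
#' densified over the absorption phase, and independent Gaussian measurement
#' error per analyte (truncated at zero).  Noise defaults are scaled to the
#' calibrated posterior error-SD magnitudes (ug/L).
#'
#' @param n_individuals Number of virtual volunteers.
#' @param dose Oral dose, ug/kg BW.
#' @param sampling_times Sampling grid, h (strictly increasing, >= 0).
#' @param sigma Named per-analyte noise SDs, ug/L.
#' @param true_parameters `"table_means"` (defaults) or
#'   `"sampled_from_priors"`.
#' @param seed Integer seed.
#' @return A `synthetic_study_spec` list.
#' @export
synthetic_study_spec <- function(n_individuals = 14, dose = 100,
                                 sampling_times = c(0.25, 0.5, 0.75, 1,
                                                    1.25, 1.5, 1.75, 2, 2.5,
                                                    3, 3.5, 4, 5, 6, 8, 12,
                                                    24),
                                 sigma = c(BPA = 0.6, BPAG = 199,
                                           BPAS = 23),
                                 true_parameters = c("table_means",
                                                     "sampled_from_priors"),
                                 seed = 1) {
  true_parameters <- match.arg(true_parameters)
  if (any(diff(sampling_times) <= 0) || any(sampling_times < 0)) {
    stop("sampling_times must be strictly increasing and >= 0")
  }
  structure(list(n_individuals = n_individuals, dose = dose,
                 sampling_times = sampling_times, sigma = sigma,
                 true_parameters = true_parameters, seed = seed),
            class = "synthetic_study_spec")
}

#' Generate a synthetic plasma biomonitoring dataset
#'
#' Forward-simulates each virtual individual with the PBK model, samples the
#' three analytes at the specified times and adds zero-truncated Gaussian
#' noise.  The generating (true) parameters are returned alongside the data
#' for parameter-recovery tests.
#'
#' @param spec A [synthetic_study_spec()].
#' @param base Baseline parameter list for non-sampled parameters.
#' @param individual_params Optional tibble (one row per individual) of
#'   parameter overrides, e.g. from [sample_population()]; when absent and
#'   `true_parameters = "sampled_from_priors"`, physiology and the
#'   individual-scope kinetic parameters are drawn from their priors.
#' @param step Simulation output step, h.
#' @return List with `data` (tibble `individual`, `bw`, `dose`, `time`,
#'   `analyte`, `conc`) and `parameters` (tibble of generating parameters).
#' @export
generate_hbm <- function(spec = synthetic_study_spec(),
                         base = default_parameters(),
                         individual_params = NULL, step = 0.05) {
  set.seed(spec$seed)
  n <- spec$n_individuals
  if (is.null(individual_params)) {
    if (spec$true_parameters == "sampled_from_priors") {
      phys <- c("BW", .volume_params, "QCC", .flow_params,
                "FracDOSEHep", "FracDOSELymph", "Lymphlag", "MPY")
      individual_params <- sample_priors(n, parameters = phys)
    } else {
      individual_params <- tibble::as_tibble(base[intersect(
        names(base), pbk_parameter_names())])[rep(1, n), ]
    }
  }
  rows <- list()
  params_out <- list()
  for (i in seq_len(n)) {
    p <- base
    p[names(individual_params)] <- as.list(unlist(individual_params[i, ]))
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      sim <- tryCatch(
        simulate_pbk(build_parameter_set(p, "rescale"), dose_event(spec$dose),
                     duration = max(spec$sampling_times), step = step,
                     rtol = 1e-6, atol = 1e-8),
        error = function(e) NULL)
      if (!is.null(sim) || attempt >= 5L) break
      # re-draw this individual and note the retry
      message("re-drawing individual ", i, " after a simulation failure")
      redraw <- sample_priors(1, parameters = names(individual_params))
      p[names(redraw)] <- as.list(unlist(redraw[1, ]))
    }
    if (is.null(sim)) stop("simulation failed for individual ", i)
    for (an in c("BPA", "BPAG", "BPAS")) {
      pred <- stats::approx(sim$series$time,
                            sim$series[[paste0("plasma_", an)]],
                            xout = spec$sampling_times)$y
      noise <- spec$sigma[[an]]
      conc <- if (noise > 0) rnorm_trunc0(pred, noise) else pred
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = i, bw = p$BW, dose = spec$dose,
        time = spec$sampling_times, analyte = an, conc = conc)
    }
    params_out[[i]] <- tibble::as_tibble(
      c(list(individual = i), unclass(build_parameter_set(p, "rescale"))))
  }
  list(data = dplyr::bind_rows(rows),
       parameters = dplyr::bind_rows(params_out))
}

# Gaussian noise truncated at zero (redrawn, not censored)
rnorm_trunc0 <- function(mean, sd) {
  out <- stats::rnorm(length(mean), mean, sd)
  bad <- which(out < 0)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] < 0]
    tries <- tries + 1L
  }
  out[out < 0] <- 0
  out
}

#' Specification of a synthetic concentration-response assay
#'
#' @param ac50 Concentration at half-maximal activity, uM.
#' @param top Maximal response (response units of `response_type`'s natural
#'   scale; for log2 fold induction this is the natural-scale plateau fold
#'   change minus 1).
#' @param hill_slope Hill coefficient.
#' @param concentrations Tested concentrations, uM.
#' @param replicates Replicates per concentration.
#' @param sigma Noise SD on the natural response scale.
#' @param response_type `"log2_fold_induction"` or `"percentage_activity"`.
#' @param seed Integer seed.
#' @return A `synthetic_assay_spec` list.
#' @export
synthetic_assay_spec <- function(ac50 = 0.72, top = 6, hill_slope = 1.2,
                                 concentrations = c(0.01, 0.03, 0.09, 0.3,
                                                    0.8, 2, 7, 20, 70),
                                 replicates = 1, sigma = 0,
                                 response_type = c("log2_fold_induction",
                                                   "percentage_activity"),
                                 seed = 1) {
  response_type <- match.arg(response_type)
  if (ac50 <= 0) stop("ac50 must be > 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  structure(list(ac50 = ac50, top = top, hill_slope = hill_slope,
                 concentrations = concentrations, replicates = replicates,
                 sigma = sigma, response_type = response_type, seed = seed),
            class = "synthetic_assay_spec")
}

#' Generate a synthetic assay table
#'
#' Hill-curve responses `top * C^h / (AC50^h + C^h)` plus Gaussian noise,
#' encoded in the requested dashboard response type: percentage activity is
#' reported directly; log2 fold induction encodes `log2(1 + response)` so a
#' zero Hill response maps to a fold change of one.
#'
#' @param spec A [synthetic_assay_spec()].
#' @return Tibble in the packaged assay-table layout (`conc_um`,
#'   `log10_conc_um`, `response`, `response_type`).
#' @export
generate_assay <- function(spec = synthetic_assay_spec()) {
  set.seed(spec$seed)
  conc <- rep(spec$concentrations, each = spec$replicates)
  hill <- spec$top * conc^spec$hill_slope /
    (spec$ac50^spec$hill_slope + conc^spec$hill_slope)
  natural <- hill + stats::rnorm(length(conc), 0, spec$sigma)
  response <- switch(spec$response_type,
    percentage_activity = natural,
    log2_fold_induction = log2(pmax(1 + natural, 1e-9))
  )
  tibble::tibble(
    assay = "synthetic",
    conc_um = conc,
    log10_conc_um = log10(conc),
    response = response,
    response_type = spec$response_type
  )
}

#' Fit a Hill curve to an assay table
#'
#' Least-squares fit of `top * C^h / (AC50^h + C^h)` on the natural response
#' scale; used for round-trip checks of the assay generator.
#'
#' @param table Assay tibble (`conc_um`, `response`, `response_type`).
#' @return Named vector `ac50`, `top`, `hill_slope`.
#' @export
fit_hill <- function(table) {
  natural <- switch(unique(table$response_type),
    percentage_activity = table$response,
    log2_fold_induction = 2^table$response - 1
  )
  conc <- table$conc_um
  obj <- function(lpar) {
    p <- exp(lpar)
    mu <- p[2] * conc^p[3] / (p[1]^p[3] + conc^p[3])
    sum((natural - mu)^2)
  }
  start <- log(c(stats::median(conc), max(natural), 1))
  fit <- stats::nlminb(start, obj)
  stats::setNames(exp(fit$par), c("ac50", "top", "hill_slope"))
}
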