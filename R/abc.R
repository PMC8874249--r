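#' ABC configuration
#'
#' Defaults for the two-phase ABC reverse dosimetry: 5000 rejection-phase
#' draws within a relative tolerance of 7.5%, then four ABC-MCMC chains of
#' 50,000 iterations within 5%.
#'
#' @param target_tissue `"CVli"` or `"CVki"`.
#' @param phase1_n Rejection-phase sample size.
#' @param phase1_tol Rejection-phase relative tolerance.
#' @param phase2_chains,phase2_iters ABC-MCMC chains and iterations.
#' @param phase2_tol ABC-MCMC relative tolerance (must be < `phase1_tol`).
#' @param statistic Matched summary of the tissue series: `"peak"`
#'   (maximum over the simulation window, default) or `"auc_mean"`
#'   (time-averaged AUC over `window`).
#' @param window Summary window, h.
#' @param seed Integer seed.
#' @return An `abc_config` list.
#' @export
abc_config <- function(target_tissue = c("CVli", "CVki"), phase1_n = 5000,
                       phase1_tol = 0.075, phase2_chains = 4,
                       phase2_iters = 50000, phase2_tol = 0.05,
                       statistic = c("peak", "auc_mean"),
                       window = NULL, seed = 1) {
  target_tissue <- match.arg(target_tissue)
  statistic <- match.arg(statistic)
  if (!(phase2_tol > 0 && phase2_tol < phase1_tol && phase1_tol < 1)) {
    stop("need 0 < phase2_tol < phase1_tol < 1")
  }
  window <- window %||% if (statistic == "peak") c(0, 24) else c(0, 3)
  structure(list(target_tissue = target_tissue, phase1_n = phase1_n,
                 phase1_tol = phase1_tol, phase2_chains = phase2_chains,
                 phase2_iters = phase2_iters, phase2_tol = phase2_tol,
                 statistic = statistic, window = window, seed = seed),
            class = "abc_config")
}

#' Matched tissue-concentration summary of a simulation
#'
#' The scalar summary of the target-tissue concentration that is compared
#' against the free in vitro target concentration: by default the maximum
#' tissue concentration over the window, alternatively the time-averaged
#' AUC.
#'
#' @param sim A `pbk_sim` object.
#' @param target_tissue `"CVli"` or `"CVki"`.
#' @param statistic `"peak"` or `"auc_mean"`.
#' @param window Summary window, h.
#' @return Scalar summary, mg/L.
#' @export
match_summary <- function(sim, target_tissue = "CVli",
                          statistic = c("peak", "auc_mean"),
                          window = NULL) {
  statistic <- match.arg(statistic)
  window <- window %||% if (statistic == "peak") range(sim$times) else c(0, 3)
  y <- sim$series[[target_tissue]]
  keep <- sim$times >= window[1] & sim$times <= window[2]
  out <- if (statistic == "peak") {
    max(y[keep])
  } else {
    auc_trapz(sim$times, y, window) / diff(window)
  }
  if (out == 0 && sim$dose$dose_per_bw > 0 && max(sim$times) > 1) {
    stop("integrity error: zero tissue series despite a non-zero dose")
  }
  out
}

#' PBK summary closure for ABC
#'
#' Builds the simulator used by the ABC phases: a function of a named draw
#' containing `PORALDOSE` (ug/kg BW/day, administered as a single daily
#' bolus) and any sensitive parameters, returning the matched
#' tissue-concentration summary.  Non-sensitive parameters are fixed at
#' `base` (typically posterior medians).
#'
#' @param cfg An [abc_config()].
#' @param base Baseline parameter list.
#' @param step Simulation output step, h.
#' @return `function(draw) -> mg/L`.
#' @export
pbk_summary_fn <- function(cfg = abc_config(), base = default_parameters(),
                           step = 0.05) {
  force(base)
  function(draw) {
    p <- base
    pnames <- setdiff(names(draw), "PORALDOSE")
    p[pnames] <- as.list(unname(draw[pnames]))
    sim <- simulate_pbk(build_parameter_set(p, "rescale"),
                        dose_event(draw[["PORALDOSE"]]),
                        duration = cfg$window[2], step = step,
                        rtol = 1e-6, atol = 1e-9)
    match_summary(sim, cfg$target_tissue, cfg$statistic, cfg$window)
  }
}

#' Bracket the dose range for a target concentration
#'
#' Logarithmic pre-scan of the dose axis (other parameters at their range
#' midpoints) to find doses whose summary brackets the target; the returned
#' range is widened by a safety factor to leave room for parameter
#' variability.
#'
#' @param sim_fn Summary closure ([pbk_summary_fn()] layout).
#' @param target Target concentration (same units as the summary).
#' @param ranges Sensitive-parameter ranges (tibble `parameter`, `lower`,
#'   `upper`; no `PORALDOSE` row needed).
#' @param dose_limits Outer search limits, ug/kg.
#' @param n_points Scan points.
#' @param widen Multiplicative safety factor applied to the bracket.
#' @return Two-element dose range.
#' @export
bracket_dose <- function(sim_fn, target, ranges,
                         dose_limits = c(1e-4, 1e6), n_points = 20,
                         widen = 5) {
  ranges <- as_ranges(ranges)
  mid <- stats::setNames((ranges$lower + ranges$upper) / 2,
                         ranges$parameter)
  doses <- exp(seq(log(dose_limits[1]), log(dose_limits[2]),
                   length.out = n_points))
  vals <- vapply(doses, function(d) sim_fn(c(mid, PORALDOSE = d)),
                 numeric(1))
  if (all(vals < target) || all(vals > target)) {
    stop("bracketing error: target ", target, " outside the summary range [",
         signif(min(vals), 3), ", ", signif(max(vals), 3),
         "]; widen dose_limits")
  }
  i <- which(vals >= target)[1]
  lo <- doses[max(i - 1, 1)] / widen
  hi <- doses[min(i, length(doses))] * widen
  pmax(pmin(c(lo, hi), dose_limits[2]), dose_limits[1])
}

#' ABC rejection phase
#'
#' Independent uniform draws of the sensitive parameters and the dose;
#' draws whose matched summary falls within `phase1_tol` of the target are
#' retained, and their empirical covariance is returned for the MCMC phase.
#'
#' @param sim_fn Summary closure.
#' @param target Target free concentration (> 0).
#' @param ranges Sensitive-parameter ranges (tibble).
#' @param dose_range Dose range, ug/kg (e.g. from [bracket_dose()]).
#' @param cfg An [abc_config()].
#' @return List with `retained` (tibble of accepted draws and summaries),
#'   `covariance`, `acceptance`.
#' @export
rejection_phase <- function(sim_fn, target, ranges, dose_range,
                            cfg = abc_config()) {
  if (target <= 0) stop("relative tolerance undefined at target <= 0")
  ranges <- as_ranges(ranges)
  set.seed(cfg$seed)
  n <- cfg$phase1_n
  draws <- sample_uniform_ranges(n, ranges, dose_range)
  summaries <- vapply(seq_len(n),
                      function(i) sim_fn(unlist(draws[i, ])), numeric(1))
  ok <- abs(summaries - target) / target <= cfg$phase1_tol
  if (!any(ok)) {
    stop("bracketing error: no draws within the tolerance band; ",
         "widen dose_range or check the target")
  }
  retained <- dplyr::mutate(draws[ok, ], summary = summaries[ok])
  cov_mat <- stats::cov(as.matrix(retained[, setdiff(names(retained),
                                                     "summary")]))
  list(retained = retained, covariance = cov_mat,
       acceptance = mean(ok))
}

sample_uniform_ranges <- function(n, ranges, dose_range) {
  cols <- lapply(seq_len(nrow(ranges)), function(i) {
    stats::runif(n, ranges$lower[i], ranges$upper[i])
  })
  names(cols) <- ranges$parameter
  cols$PORALDOSE <- stats::runif(n, dose_range[1], dose_range[2])
  tibble::as_tibble(cols)
}

#' ABC MCMC phase
#'
#' Chains started at random retained points from the rejection phase, with
#' multivariate Gaussian proposals scaled from the phase-1 covariance.  A
#' proposal is accepted iff all parameters stay within their ranges and the
#' matched summary lies within `phase2_tol` of the target.  Pooled accepted
#' samples are summarised as the mean and the central 95% interval of the
#' dose.
#'
#' @param sim_fn Summary closure.
#' @param target Target free concentration.
#' @param phase1 Output of [rejection_phase()].
#' @param ranges Sensitive-parameter ranges.
#' @param dose_range Dose range, ug/kg.
#' @param cfg An [abc_config()].
#' @return A `dose_posterior` object.
#' @export
abc_mcmc <- function(sim_fn, target, phase1, ranges, dose_range,
                     cfg = abc_config()) {
  ranges <- as_ranges(ranges)
  in_band <- abs(phase1$retained$summary - target) / target <= cfg$phase2_tol
  if (!any(in_band)) {
    stop("phase-1 retained set has no point within the MCMC tolerance; ",
         "increase phase1_n")
  }
  ret <- phase1$retained[in_band, setdiff(names(phase1$retained), "summary")]
  if (nrow(ret) == 0) stop("phase-1 output is empty")
  d <- ncol(ret)
  lower <- c(stats::setNames(ranges$lower, ranges$parameter),
             PORALDOSE = dose_range[1])[names(ret)]
  upper <- c(stats::setNames(ranges$upper, ranges$parameter),
             PORALDOSE = dose_range[2])[names(ret)]
  sigma <- phase1$covariance * (2.38^2 / d)
  sigma <- sigma + diag(1e-12 * pmax(diag(sigma), 1e-12), d)

  run_chain <- function(chain) {
    set.seed(cfg$seed + 1000 + chain)
    scale_fac <- 1
    repeat {
      x <- unlist(ret[sample.int(nrow(ret), 1), ])
      acc <- 0L
      out <- matrix(NA_real_, cfg$phase2_iters, d,
                    dimnames = list(NULL, names(ret)))
      for (it in seq_len(cfg$phase2_iters)) {
        prop <- x + MASS::mvrnorm(1, rep(0, d), sigma * scale_fac^2)
        if (all(prop >= lower & prop <= upper)) {
          s <- sim_fn(prop)
          if (abs(s - target) / target <= cfg$phase2_tol) {
            x <- prop
            acc <- acc + 1L
          }
        }
        out[it, ] <- x
      }
      rate <- acc / cfg$phase2_iters
      if (rate >= 0.01 || scale_fac < 0.2) {
        return(list(draws = out, acceptance = rate))
      }
      warning("chain ", chain, " acceptance ", signif(rate, 2),
              " < 1%; shrinking the proposal scale")
      scale_fac <- scale_fac / 2
    }
  }

  chains <- lapply(seq_len(cfg$phase2_chains), run_chain)
  pooled <- do.call(rbind, lapply(chains, `[[`, "draws"))
  dose <- pooled[, "PORALDOSE"]
  structure(list(
    target = target,
    samples = tibble::as_tibble(pooled),
    mean = mean(dose),
    q2.5 = stats::quantile(dose, 0.025, names = FALSE),
    q97.5 = stats::quantile(dose, 0.975, names = FALSE),
    acceptance_phase1 = phase1$acceptance,
    acceptance_phase2 = vapply(chains, `[[`, numeric(1), "acceptance"),
    config = cfg
  ), class = "dose_posterior")
}

#' @export
print.dose_posterior <- function(x, ...) {
  cat("<dose_posterior> target ", x$target, ": mean ", signif(x$mean, 4),
      " (", signif(x$q2.5, 4), ", ", signif(x$q97.5, 4), ") ug/kg/day\n",
      sep = "")
  invisible(x)
}

#' @method tidy dose_posterior
#' @export
tidy.dose_posterior <- function(x, ...) {
  tibble::tibble(target = x$target, mean = x$mean, q2.5 = x$q2.5,
                 q97.5 = x$q97.5)
}

#' @method glance dose_posterior
#' @export
glance.dose_posterior <- function(x, ...) {
  tibble::tibble(target = x$target, n_samples = nrow(x$samples),
                 acceptance_phase1 = x$acceptance_phase1,
                 acceptance_phase2 = mean(x$acceptance_phase2))
}

#' Two-phase ABC reverse dosimetry for one target concentration
#'
#' Convenience wrapper: brackets the dose range, runs the rejection phase
#' and then ABC MCMC.
#'
#' @param target Target free concentration, mg/L.
#' @param ranges Sensitive-parameter ranges.
#' @param cfg An [abc_config()].
#' @param base Baseline parameters for the non-sensitive set.
#' @param dose_range Optional explicit dose range (skips bracketing).
#' @param step Simulation output step.
#' @return A `dose_posterior`.
#' @export
reverse_dosimetry <- function(target, ranges, cfg = abc_config(),
                              base = default_parameters(),
                              dose_range = NULL, step = 0.05) {
  sim_fn <- pbk_summary_fn(cfg, base, step = step)
  dose_range <- dose_range %||% bracket_dose(sim_fn, target, ranges)
  phase1 <- rejection_phase(sim_fn, target, ranges, dose_range, cfg)
  abc_mcmc(sim_fn, target, phase1, ranges, dose_range, cfg)
}

#' Convert raw assay responses to the natural scale
#'
#' Log2 fold inductions are exponentiated (`2^x`).  Percentage activities
#' follow the published clamp-and-shift rule: negative values (and any
#' explicitly flagged measurement anomalies) are set to zero, then a
#' constant of one is added to the whole series so responses are strictly
#' positive for lognormal benchmark-dose analysis.
#'
#' @param response Numeric responses.
#' @param response_type `"log2_fold_induction"` or `"percentage_activity"`.
#' @param anomalies Integer indices of responses to clamp to zero before
#'   the shift (the published anomaly rule is an explicit per-assay
#'   exclusion list, not an automatic filter).
#' @return Natural-scale responses.
#' @examples
#' preprocess_response(2.711, "log2_fold_induction")      # 6.55
#' preprocess_response(c(-6.989, 26.914), "percentage_activity")
#' @export
preprocess_response <- function(response,
                                response_type = c("log2_fold_induction",
                                                  "percentage_activity"),
                                anomalies = integer(0)) {
  response_type <- match.arg(response_type)
  if (response_type == "log2_fold_induction") {
    2^response
  } else {
    out <- response
    out[out < 0] <- 0
    out[anomalies] <- 0
    out + 1
  }
}

#' Assemble in vivo dose-response sets
#'
#' Pairs the dose posterior summaries (one per in vitro concentration) with
#' the natural-scale responses into the three dose-response sets used for
#' benchmark-dose analysis: posterior mean, 2.5% and 97.5% doses.
#'
#' @param posteriors Tibble with one row per concentration: `free_conc`,
#'   `mean`, `q2.5`, `q97.5` (a list of `dose_posterior` objects is also
#'   accepted).
#' @param responses Natural-scale responses aligned with the rows of
#'   `posteriors`.
#' @return Tibble with columns `set` (`"mean"`, `"lower"`, `"upper"`),
#'   `free_conc`, `dose`, `response`, sorted by concentration within set.
#' @export
assemble_dose_response <- function(posteriors, responses) {
  if (is.list(posteriors) && !is.data.frame(posteriors) &&
      inherits(posteriors[[1]], "dose_posterior")) {
    posteriors <- dplyr::bind_rows(lapply(posteriors, function(p) {
      tibble::tibble(free_conc = p$target, mean = p$mean, q2.5 = p$q2.5,
                     q97.5 = p$q97.5)
    }))
  }
  if (nrow(posteriors) != length(responses)) {
    stop("alignment error: ", nrow(posteriors), " posteriors vs ",
         length(responses), " responses")
  }
  df <- dplyr::mutate(posteriors, response = responses)
  df <- dplyr::arrange(df, .data$free_conc)
  dplyr::bind_rows(
    tibble::tibble(set = "mean", free_conc = df$free_conc, dose = df$mean,
                   response = df$response),
    tibble::tibble(set = "lower", free_conc = df$free_conc, dose = df$q2.5,
                   response = df$response),
    tibble::tibble(set = "upper", free_conc = df$free_conc, dose = df$q97.5,
                   response = df$response)
  )
}
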