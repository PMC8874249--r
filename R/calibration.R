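#' PBK predictor for calibration
#'
#' Returns a closure that maps a named parameter draw and a per-individual
#' observation table (columns `time`, `analyte`) onto predicted plasma
#' concentrations (ug/L), by forward-simulating the PBK model with the draw
#' overriding the baseline parameter values.
#'
#' @param base Baseline parameter list.
#' @param dose A [dose_event()] (the study design's single oral dose).
#' @param step Simulation output step, h.
#' @param rtol,atol Solver tolerances.
#' @return `function(params, obs)` returning a numeric vector aligned with
#'   the rows of `obs`.
#' @export
pbk_predictor <- function(base = default_parameters(), dose = dose_event(100),
                          step = 0.05, rtol = 1e-6, atol = 1e-8) {
  force(base)
  function(params, obs) {
    p <- base
    p[names(params)] <- as.list(unname(params))
    sim <- simulate_pbk(build_parameter_set(p, "rescale"), dose,
                        duration = max(obs$time) + step, step = step,
                        rtol = rtol, atol = atol)
    series <- paste0("plasma_", obs$analyte)
    vapply(seq_len(nrow(obs)), function(i) {
      stats::approx(sim$series$time, sim$series[[series[i]]],
                    xout = obs$time[i])$y
    }, numeric(1))
  }
}

#' Gaussian log-likelihood of plasma observations
#'
#' Sum over all observations of the Gaussian log-density of the observed
#' concentration given the model prediction at that time and the analyte's
#' error standard deviation.  The error model operates on the natural
#' concentration scale by default; `log_scale = TRUE` applies it to
#' log-concentrations instead.
#'
#' @param globals Named vector of global parameter values.
#' @param individuals Named list (by individual id) of named vectors of
#'   individual-specific parameter values.
#' @param sigmas Named vector of per-analyte error SDs
#'   (`c(BPA = , BPAG = , BPAS = )`).
#' @param data HBM dataset: tibble with `individual`, `time`, `analyte`,
#'   `conc`.
#' @param predictor A predictor closure such as [pbk_predictor()].
#' @param log_scale Apply the Gaussian error on the log-concentration scale.
#' @return Scalar log-likelihood; `-Inf` if a simulation fails.
#' @export
hbm_log_likelihood <- function(globals, individuals, sigmas, data,
                               predictor = pbk_predictor(),
                               log_scale = FALSE) {
  total <- 0
  for (id in unique(data$individual)) {
    obs <- data[data$individual == id, ]
    pred <- tryCatch(
      predictor(c(globals, individuals[[as.character(id)]]), obs),
      error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(-Inf)
    s <- sigmas[obs$analyte]
    total <- total + if (log_scale) {
      sum(stats::dnorm(log(pmax(obs$conc, 1e-12)), log(pmax(pred, 1e-12)),
                       s, log = TRUE))
    } else {
      sum(stats::dnorm(obs$conc, pred, s, log = TRUE))
    }
  }
  total
}

#' Hierarchical Bayesian calibration by Metropolis-within-Gibbs
#'
#' Component-wise adaptive random-walk Metropolis over the hierarchical
#' parameter vector: global parameters (shared across individuals),
#' individual-specific parameters (independent truncated priors per
#' individual, no hyper-distribution), and per-analyte error SDs.  Proposal
#' scales adapt during burn-in towards a 0.23-0.44 acceptance window.
#' Updating an individual-specific parameter re-simulates only that
#' individual; per-individual likelihood contributions are cached.
#'
#' @param data HBM dataset (`individual`, `time`, `analyte`, `conc`).
#' @param calibrate Character vector of parameter names to calibrate; their
#'   prior family, bounds and scope come from `priors`.
#' @param priors Prior table ([bpa_priors()] layout).
#' @param sigma_priors Tibble `analyte`, `lower`, `upper` for the uniform
#'   error-SD priors; defaults to the packaged prior 95% spans.
#' @param predictor Predictor closure ([pbk_predictor()] layout).  Ignored
#'   when `use_likelihood = FALSE`.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations Post-burn-in iterations per chain.
#' @param burn_in Burn-in iterations per chain (adaptation window).
#' @param seed Integer seed.
#' @param use_likelihood `FALSE` runs the sampler against the prior only
#'   (a prior-recovery diagnostic).
#' @param log_scale Passed to the error model.
#' @return A `pbk_mcmc` object: `draws` (list of iteration x parameter
#'   matrices, burn-in removed), `param_table`, `acceptance`, `seed`.
#' @export
run_mcmc <- function(data, calibrate, priors = bpa_priors(),
                     sigma_priors = NULL, predictor = pbk_predictor(),
                     chains = 2, iterations = 1000, burn_in = iterations %/% 2,
                     seed = 1, use_likelihood = TRUE, log_scale = FALSE) {
  if (chains < 2) stop("chains must be >= 2")
  ids <- as.character(unique(data$individual))
  analytes <- unique(data$analyte)
  if (is.null(sigma_priors)) {
    ps <- bpa_posterior_sigma()
    sigma_priors <- tibble::tibble(analyte = ps$analyte,
                                   lower = ps$prior_q2.5,
                                   upper = ps$prior_q97.5)
  }
  sigma_priors <- sigma_priors[sigma_priors$analyte %in% analytes, ]

  ptab <- priors[match(calibrate, priors$parameter), ]
  if (anyNA(ptab$parameter)) {
    stop("parameter(s) not in the prior table: ",
         paste(calibrate[is.na(ptab$parameter)], collapse = ", "))
  }
  # expand: one sampler component per global parameter, per (individual x
  # individual-scope parameter), and per analyte sigma
  comp <- dplyr::bind_rows(
    dplyr::mutate(ptab[ptab$scope == "global", ], individual = NA_character_),
    tidyr::crossing(ptab[ptab$scope == "individual", ],
                    individual = ids),
    tibble::tibble(parameter = paste0("sigma_", sigma_priors$analyte),
                   unit = "conc", distribution = "uniform",
                   mean = NA, sd = NA,
                   lower = sigma_priors$lower, upper = sigma_priors$upper,
                   scope = "sigma", individual = NA_character_)
  )
  comp$label <- ifelse(is.na(comp$individual), comp$parameter,
                       paste0(comp$parameter, "[", comp$individual, "]"))
  npar <- nrow(comp)

  obs_by_id <- lapply(ids, function(id) data[data$individual == id, ])
  names(obs_by_id) <- ids

  point_ll <- function(obs, pred, sig) {
    s <- sig[obs$analyte]
    if (log_scale) {
      sum(stats::dnorm(log(pmax(obs$conc, 1e-12)), log(pmax(pred, 1e-12)),
                       s, log = TRUE))
    } else {
      sum(stats::dnorm(obs$conc, pred, s, log = TRUE))
    }
  }

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    theta <- vapply(seq_len(npar), function(j) {
      lo <- comp$lower[j]; up <- comp$upper[j]
      stats::runif(1, lo + 0.25 * (up - lo), up - 0.25 * (up - lo))
    }, numeric(1))
    names(theta) <- comp$label
    step <- 0.15 * (comp$upper - comp$lower)

    pred_cache <- stats::setNames(vector("list", length(ids)), ids)
    predict_id <- function(th, id) {
      pars <- theta_for_individual(th, comp, id)
      pred <- tryCatch(predictor(pars, obs_by_id[[id]]),
                       error = function(e) NULL)
      if (!is.null(pred) && anyNA(pred)) pred <- NULL
      pred
    }

    ll_by_id <- stats::setNames(numeric(length(ids)), ids)
    if (use_likelihood) {
      sig <- theta_sigmas(theta, comp)
      for (id in ids) {
        pred_cache[[id]] <- predict_id(theta, id)
        if (is.null(pred_cache[[id]])) {
          stop("initial state simulation failed for individual ", id)
        }
        ll_by_id[id] <- point_ll(obs_by_id[[id]], pred_cache[[id]], sig)
      }
    }

    n_total <- burn_in + iterations
    draws <- matrix(NA_real_, n_total, npar,
                    dimnames = list(NULL, comp$label))
    acc <- att <- numeric(npar)
    acc_win <- att_win <- numeric(npar)
    for (it in seq_len(n_total)) {
      for (j in sample.int(npar)) {
        prop <- theta
        prop[j] <- theta[j] + stats::rnorm(1, 0, step[j])
        att[j] <- att[j] + 1; att_win[j] <- att_win[j] + 1
        lp_cur <- dprior(theta[j], comp$distribution[j], comp$mean[j],
                         comp$sd[j], comp$lower[j], comp$upper[j])
        lp_prop <- dprior(prop[j], comp$distribution[j], comp$mean[j],
                          comp$sd[j], comp$lower[j], comp$upper[j])
        if (!is.finite(lp_prop)) next
        new_pred <- list()
        if (use_likelihood) {
          ll_prop <- ll_by_id
          sig_prop <- theta_sigmas(prop, comp)
          if (comp$scope[j] == "sigma") {
            for (id in ids) {
              ll_prop[id] <- point_ll(obs_by_id[[id]], pred_cache[[id]],
                                      sig_prop)
            }
          } else {
            for (id in affected_ids(comp, j, ids)) {
              pred <- predict_id(prop, id)
              if (is.null(pred)) { ll_prop[id] <- -Inf; break }
              new_pred[[id]] <- pred
              ll_prop[id] <- point_ll(obs_by_id[[id]], pred, sig_prop)
            }
          }
          log_ratio <- sum(ll_prop) - sum(ll_by_id) + lp_prop - lp_cur
        } else {
          log_ratio <- lp_prop - lp_cur
        }
        if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
          theta <- prop
          if (use_likelihood) {
            for (id in names(new_pred)) pred_cache[[id]] <- new_pred[[id]]
            ll_by_id <- ll_prop
          }
          acc[j] <- acc[j] + 1; acc_win[j] <- acc_win[j] + 1
        }
      }
      # adapt proposal scales towards the 0.23-0.44 acceptance window
      if (it <= burn_in && it %% 25 == 0) {
        rate <- ifelse(att_win > 0, acc_win / att_win, 0)
        step <- step * ifelse(rate > 0.44, 1.4, ifelse(rate < 0.23, 0.7, 1))
        acc_win[] <- 0; att_win[] <- 0
      }
      draws[it, ] <- theta
    }
    if (use_likelihood && all(acc == 0)) {
      stop("adaptation failure: zero acceptance over the whole run")
    }
    list(draws = draws[(burn_in + 1):n_total, , drop = FALSE],
         acceptance = ifelse(att > 0, acc / att, NA_real_))
  }

  results <- lapply(seq_len(chains), function(ch) run_chain(seed + ch - 1))
  structure(list(
    draws = lapply(results, `[[`, "draws"),
    acceptance = do.call(rbind, lapply(results, `[[`, "acceptance")),
    param_table = comp, burn_in = burn_in, iterations = iterations,
    seed = seed, use_likelihood = use_likelihood
  ), class = "pbk_mcmc")
}

theta_sigmas <- function(theta, comp) {
  j <- comp$scope == "sigma"
  stats::setNames(theta[j], sub("^sigma_", "", comp$parameter[j]))
}

theta_for_individual <- function(theta, comp, id) {
  keep <- comp$scope == "global" |
    (comp$scope == "individual" & comp$individual == id)
  keep[is.na(keep)] <- FALSE
  stats::setNames(theta[keep], comp$parameter[keep])
}

affected_ids <- function(comp, j, ids) {
  if (comp$scope[j] == "individual") comp$individual[j] else ids
}

#' @export
print.pbk_mcmc <- function(x, ...) {
  cat("<pbk_mcmc> ", length(x$draws), " chains x ", x$iterations,
      " iterations (", nrow(x$param_table), " components)\n", sep = "")
  invisible(x)
}

#' Posterior summary of an MCMC fit
#'
#' Pooled-chain medians and central 95% intervals (burn-in already removed
#' by [run_mcmc()]).
#'
#' @param fit A `pbk_mcmc` object.
#' @return Tibble with `parameter`, `individual`, `median`, `q2.5`, `q97.5`.
#' @export
summarize_chains <- function(fit) {
  pooled <- do.call(rbind, fit$draws)
  if (nrow(pooled) == 0) stop("empty chains")
  qs <- t(apply(pooled, 2, stats::quantile, c(0.025, 0.5, 0.975),
                names = FALSE))
  tibble::tibble(parameter = fit$param_table$parameter,
                 individual = fit$param_table$individual,
                 median = as.numeric(qs[, 2]), q2.5 = as.numeric(qs[, 1]),
                 q97.5 = as.numeric(qs[, 3]))
}

#' @method tidy pbk_mcmc
#' @export
tidy.pbk_mcmc <- function(x, ...) summarize_chains(x)

#' @method glance pbk_mcmc
#' @export
glance.pbk_mcmc <- function(x, ...) {
  tibble::tibble(chains = length(x$draws), iterations = x$iterations,
                 burn_in = x$burn_in,
                 max_rhat = max(gelman_rubin(x)$rhat),
                 mean_acceptance = mean(x$acceptance, na.rm = TRUE))
}

#' Potential scale reduction diagnostic
#'
#' Gelman-Rubin statistic computed across chains for each monitored
#' component.
#'
#' @param fit A `pbk_mcmc` object.
#' @return Tibble with `parameter`, `individual`, `rhat`.
#' @export
gelman_rubin <- function(fit) {
  m <- length(fit$draws)
  n <- nrow(fit$draws[[1]])
  rhat <- vapply(seq_len(ncol(fit$draws[[1]])), function(j) {
    ch <- vapply(fit$draws, function(d) d[, j], numeric(n))
    means <- colMeans(ch)
    vars <- apply(ch, 2, stats::var)
    w <- mean(vars)
    b <- n * stats::var(means)
    if (w < .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))
  tibble::tibble(parameter = fit$param_table$parameter,
                 individual = fit$param_table$individual, rhat = rhat)
}

#' Chemical-specific adjustment factor
#'
#' Ratio of the 97.5% posterior quantile to the posterior median of a
#' parameter, used as a chemical-specific adjustment factor (CSAF) for
#' inter-individual kinetic variability.
#'
#' @param samples Posterior samples of one parameter, or `NULL` when
#'   `median` and `q97.5` are given directly (summary-table input).
#' @param median,q97.5 Posterior summary values (used when `samples` is
#'   `NULL`).
#' @return Dimensionless ratio `q97.5 / median`.
#' @examples
#' csaf(median = 0.119, q97.5 = 0.300)  # 2.52 for the binding fraction
#' @export
csaf <- function(samples = NULL, median = NULL, q97.5 = NULL) {
  if (!is.null(samples)) {
    if (length(samples) == 0) stop("empty sample")
    median <- stats::median(samples)
    q97.5 <- stats::quantile(samples, 0.975, names = FALSE)
  }
  if (is.null(median) || is.null(q97.5)) {
    stop("provide samples or both median and q97.5")
  }
  if (median == 0) stop("median is zero; CSAF undefined")
  q97.5 / median
}
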